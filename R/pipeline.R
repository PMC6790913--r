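#' Run the full differential-abundance pipeline
#'
#' Filter decoys/contaminants, subtract blank-run keratin background,
#' normalize to the lowest total protein abundance, compute QC
#' (technical-replicate Pearson correlations, per-sample log2-iBAQ
#' histograms), call consistently up-/down-regulated proteins, and — when
#' gene sets are supplied — run over-representation analysis of the DOWN
#' and UP lists against the quantified-proteome universe.
#'
#' @param table a [protein_quant] as read by [read_protein_groups()].
#' @param design the sample design (see [read_design()]).
#' @param blank optional blank-run table (`protein_group_id`,
#'   `blank_intensity`).
#' @param gene_sets optional `gene_set_collection` for enrichment.
#' @param config a [diff_config()].
#' @param out_dir optional directory; when given, all result tables are
#'   written there as TSV (`calls.tsv`, `volcano.tsv`, `qc_correlation.tsv`,
#'   `qc_histogram.tsv`, `removal_report.tsv`, `enrichment_down.tsv`,
#'   `enrichment_up.tsv`) plus the thresholds in `run_config.tsv`.
#' @return List with elements `normalized` ([protein_quant]), `calls`,
#'   `volcano`, `qc_correlation`, `qc_histogram`, `removal_report`,
#'   `enrichment` (list with `DOWN`/`UP` tibbles or `NULL`).
#' @export
run_pipeline <- function(table, design, blank = NULL, gene_sets = NULL,
                         config = diff_config(), out_dir = NULL) {
  design <- validate_design(design)
  filt <- filter_contaminants_decoys(table)
  if (!is.null(blank)) {
    # blank runs are measured against the unfiltered search output; entries
    # for rows the filter just removed are expected, not suspicious
    blank <- blank[blank$protein_group_id %in%
                     filt$table$meta$protein_group_id, , drop = FALSE]
  }
  clean <- subtract_keratin_blank(filt$table, blank)
  norm <- normalize_total(clean)
  qc_r <- replicate_correlation(norm, design)
  qc_h <- intensity_histogram(norm)
  dm <- aggregate_technical(norm, design)
  calls <- differential_calls(norm, design, config)
  volc <- volcano_table(dm, config)

  enrich <- NULL
  if (!is.null(gene_sets)) {
    universe <- first_symbol(norm$meta$gene_name)
    universe <- unique(universe[nzchar(universe)])
    enrich <- list()
    for (cl in c("DOWN", "UP")) {
      q <- first_symbol(calls$gene_name[calls$class == cl])
      q <- unique(q[nzchar(q)])
      enrich[[cl]] <- if (length(q) > 0) ora(q, gene_sets, universe) else NULL
    }
  }

  res <- list(normalized = norm, calls = calls, volcano = volc,
              qc_correlation = qc_r, qc_histogram = qc_h,
              removal_report = filt$report, enrichment = enrich)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) write_table(x, file.path(out_dir, f))
    w(calls, "calls.tsv")
    w(volc, "volcano.tsv")
    w(data.frame(sample_label = rownames(qc_r), qc_r, check.names = FALSE),
      "qc_correlation.tsv")
    w(qc_h, "qc_histogram.tsv")
    w(data.frame(reason = c("reverse", "contaminant", "kept"),
                 n = c(filt$report$reverse, filt$report$contaminant,
                       filt$report$kept)),
      "removal_report.tsv")
    w(data.frame(parameter = names(unclass(config)),
                 value = unlist(unclass(config))),
      "run_config.tsv")
    if (!is.null(enrich)) {
      for (cl in names(enrich)) {
        if (!is.null(enrich[[cl]])) {
          w(enrich[[cl]], paste0("enrichment_", tolower(cl), ".tsv"))
        }
      }
    }
  }
  res
}

first_symbol <- function(gene_names) {
  toupper(vapply(strsplit(as.character(gene_names), ";", fixed = TRUE),
                 function(g) if (length(g)) trimws(g[[1]]) else "",
                 character(1)))
}
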