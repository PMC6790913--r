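#' Remove reversed-sequence decoys and contaminants
#'
#' Rows flagged `is_reverse` (matches to the reversed decoy database,
#' removed at the search's 1% FDR) or `is_contaminant` (trypsin and other
#' lab-originating proteins) are dropped. Keratin rows that are *not*
#' contaminant-flagged are retained: genuine epidermal keratins are handled
#' by blank-run subtraction, not removal. A row flagged both reverse and
#' contaminant is counted once, under reverse.
#'
#' @param table a [protein_quant].
#' @return List with `table` (filtered [protein_quant]) and `report`
#'   (list with counts `reverse`, `contaminant`, `kept`).
#' @export
filter_contaminants_decoys <- function(table) {
  stopifnot(inherits(table, "protein_quant"))
  rev <- table$meta$is_reverse
  con <- table$meta$is_contaminant & !rev
  keep <- !rev & !con
  list(
    table = pq_subset(table, keep),
    report = list(reverse = sum(rev), contaminant = sum(con),
                  kept = sum(keep))
  )
}

#' Subtract blank-run keratin background
#'
#' Instrument blank runs estimate how much keratin signal is ambient
#' contamination rather than sample protein. For every keratin-flagged
#' row with a blank entry, the blank intensity is subtracted from each
#' sample's intensity, flooring at 0; non-keratin rows are never touched.
#' Apply before [normalize_total()], so background keratin mass does not
#' distort the scale factors.
#'
#' @param table a [protein_quant].
#' @param blank data frame with columns `protein_group_id` and
#'   `blank_intensity` (one value per protein, applied to all samples), or
#'   `NULL` for a no-op. Blank entries for ids absent from the table are
#'   ignored with a warning.
#' @return The adjusted [protein_quant].
#' @export
subtract_keratin_blank <- function(table, blank) {
  stopifnot(inherits(table, "protein_quant"))
  if (is.null(blank) || nrow(blank) == 0) return(table)
  idx <- match(blank$protein_group_id, table$meta$protein_group_id)
  if (anyNA(idx)) {
    warning("blank entries for ", sum(is.na(idx)),
            " protein id(s) absent from the table were ignored")
  }
  hit <- which(!is.na(idx))
  rows <- idx[hit]
  target <- rows[table$meta$is_keratin[rows] & blank$blank_intensity[hit] > 0]
  bvals <- blank$blank_intensity[hit][table$meta$is_keratin[rows] &
                                        blank$blank_intensity[hit] > 0]
  if (length(target) > 0) {
    table$intensity[target, ] <-
      pmax(0, table$intensity[target, , drop = FALSE] - bvals)
    if (!is.null(table$ibaq)) {
      # keep iBAQ consistent with the adjusted intensities
      n <- table$meta$n_theoretical_peptides[target]
      table$ibaq[target, ] <-
        sweep(table$intensity[target, , drop = FALSE], 1,
              ifelse(n > 0, n, NA_real_), "/")
    }
  }
  table
}

#' Normalize to total protein abundance
#'
#' Every sample's intensities are rescaled so that its total intensity
#' equals the lowest per-sample total in the table ("adjustment to the
#' lowest total protein yield"). iBAQ values are scaled by the same
#' per-sample factor so both quantities stay mutually consistent. All
#' scale factors are therefore <= 1.
#'
#' @param table a [protein_quant] (post filter and blank subtraction).
#' @return The normalized [protein_quant], with attributes
#'   `scale_factors` (named per-sample vector) and `normalization_target`
#'   (the lowest pre-normalization total).
#' @export
normalize_total <- function(table) {
  stopifnot(inherits(table, "protein_quant"))
  totals <- colSums(table$intensity)
  if (any(totals <= 0)) {
    stop("sample(s) with zero total intensity: ",
         paste(names(totals)[totals <= 0], collapse = ", "))
  }
  target <- min(totals)
  factors <- target / totals
  table$intensity <- sweep(table$intensity, 2, factors, "*")
  if (!is.null(table$ibaq)) {
    table$ibaq <- sweep(table$ibaq, 2, factors, "*")
  }
  attr(table, "scale_factors") <- factors
  attr(table, "normalization_target") <- target
  class(table) <- unique(c("normalized_quant", class(table)))
  table
}

#' Intensity-based absolute quantification (iBAQ)
#'
#' iBAQ is the summed intensity of a protein's tryptic peptides divided by
#' its number of theoretically observable peptides, giving an abundance
#' measure comparable across proteins of different length.
#'
#' @param peptide_intensity_sum summed peptide intensity (vectorised).
#' @param n_theoretical_peptides number of theoretically observable
#'   tryptic peptides; 0 yields `NaN` with a warning.
#' @return `peptide_intensity_sum / n_theoretical_peptides`.
#' @export
compute_ibaq <- function(peptide_intensity_sum, n_theoretical_peptides) {
  stopifnot(all(n_theoretical_peptides >= 0))
  if (any(n_theoretical_peptides == 0)) {
    warning("iBAQ undefined for ", sum(n_theoretical_peptides == 0),
            " protein(s) with 0 theoretical peptides")
  }
  out <- peptide_intensity_sum / n_theoretical_peptides
  out[n_theoretical_peptides == 0] <- NaN
  out
}

#' Pairwise Pearson correlation of samples
#'
#' Technical reproducibility QC: for every pair of samples, the Pearson
#' correlation of log2 quantitation over proteins detected (> 0) in both
#' members of the pair (complete-case; 0 means undetected, not zero
#' abundance). Uses log2 iBAQ when available, otherwise log2 intensity.
#'
#' @param table a [protein_quant].
#' @param design optional design; when given, columns are restricted to
#'   its non-BLANK samples.
#' @param use `"ibaq"` (default, falls back to intensity if absent) or
#'   `"intensity"`.
#' @param min_common minimum common detected proteins for a defined r;
#'   below it `NA` is reported. Default 3.
#' @return Symmetric matrix of Pearson r with unit diagonal.
#' @export
replicate_correlation <- function(table, design = NULL, use = c("ibaq", "intensity"),
                                  min_common = 3) {
  stopifnot(inherits(table, "protein_quant"))
  use <- match.arg(use)
  m <- if (use == "ibaq" && !is.null(table$ibaq)) table$ibaq else table$intensity
  if (!is.null(design)) {
    keep <- as.character(design$sample_label[design$condition != "BLANK"])
    m <- m[, keep, drop = FALSE]
  }
  s <- ncol(m)
  r <- diag(1, s)
  dimnames(r) <- list(colnames(m), colnames(m))
  lg <- log2(m)
  lg[m <= 0] <- NA
  for (i in seq_len(s)) {
    for (j in seq_len(s)) {
      if (j <= i) next
      ok <- !is.na(lg[, i]) & !is.na(lg[, j])
      r[i, j] <- r[j, i] <- if (sum(ok) < min_common) NA_real_ else
        stats::cor(lg[ok, i], lg[ok, j])
    }
  }
  r
}

#' Per-sample histogram of log2 quantitation
#'
#' Distribution of detected proteins per sample on the log2-iBAQ scale
#' (fallback log2 intensity), as drawn in proteome-coverage QC figures.
#' Zero (undetected) values are excluded; every detected protein falls in
#' exactly one bin, so per-sample histogram mass equals the number of
#' detected proteins.
#'
#' @param table a [protein_quant].
#' @param bin_width bin width in log2 units. Default 1.
#' @param use `"ibaq"` (default, falls back to intensity) or `"intensity"`.
#' @param normalise if `TRUE`, counts are divided by the sample's number
#'   of detected proteins.
#' @return Tibble with columns `sample_label`, `bin_lower`, `bin_upper`,
#'   `count` (and `fraction` when `normalise`).
#' @export
intensity_histogram <- function(table, bin_width = 1, use = c("ibaq", "intensity"),
                                normalise = FALSE) {
  stopifnot(bin_width > 0)
  use <- match.arg(use)
  m <- if (use == "ibaq" && !is.null(table$ibaq)) table$ibaq else table$intensity
  out <- list()
  for (s in colnames(m)) {
    v <- m[, s]
    v <- v[v > 0]
    if (length(v) == 0) next
    b <- floor(log2(v) / bin_width)
    tab <- base::table(b)
    lower <- as.numeric(names(tab)) * bin_width
    df <- tibble::tibble(
      sample_label = s, bin_lower = lower, bin_upper = lower + bin_width,
      count = as.integer(tab)
    )
    if (normalise) df$fraction <- df$count / length(v)
    out[[s]] <- df
  }
  if (length(out) == 0) {
    return(tibble::tibble(sample_label = character(), bin_lower = numeric(),
                          bin_upper = numeric(), count = integer()))
  }
  do.call(rbind, out)
}
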