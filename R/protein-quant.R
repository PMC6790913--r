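#' Protein-group quantitation container
#'
#' Lightweight container pairing per-protein-group annotation with
#' per-sample intensity (and optionally iBAQ) matrices. A zero intensity
#' encodes "not detected" throughout the pipeline, matching the MaxQuant
#' proteinGroups convention.
#'
#' @param meta data frame with one row per protein group and columns
#'   `protein_group_id`, `gene_name`, `is_reverse`, `is_contaminant`,
#'   `is_keratin`, `n_theoretical_peptides`.
#' @param intensity numeric matrix, proteins x samples; rownames must equal
#'   `meta$protein_group_id`, colnames are sample labels. Non-negative;
#'   0 means undetected.
#' @param ibaq optional numeric matrix with the same dimnames as
#'   `intensity`, holding iBAQ values.
#'
#' @return An object of class `protein_quant`.
#' @export
protein_quant <- function(meta, intensity, ibaq = NULL) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("protein_group_id", "gene_name", "is_reverse",
                "is_contaminant", "is_keratin", "n_theoretical_peptides")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    stop("meta is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$protein_group_id)) {
    dup <- unique(meta$protein_group_id[duplicated(meta$protein_group_id)])
    stop("duplicate protein_group_id: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (nrow(intensity) != nrow(meta)) {
    stop("intensity has ", nrow(intensity), " rows but meta has ", nrow(meta))
  }
  if (is.null(rownames(intensity))) rownames(intensity) <- meta$protein_group_id
  if (!identical(rownames(intensity), meta$protein_group_id)) {
    stop("rownames(intensity) must equal meta$protein_group_id")
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("intensity must be finite and non-negative (0 = not detected)")
  }
  if (!is.null(ibaq)) {
    ibaq <- as.matrix(ibaq)
    storage.mode(ibaq) <- "double"
    if (!identical(dim(ibaq), dim(intensity))) {
      stop("ibaq must have the same dimensions as intensity")
    }
    dimnames(ibaq) <- dimnames(intensity)
  }
  structure(
    list(meta = meta, intensity = intensity, ibaq = ibaq),
    class = "protein_quant"
  )
}

#' @export
print.protein_quant <- function(x, ...) {
  cat("<protein_quant> ", nrow(x$meta), " protein groups x ",
      ncol(x$intensity), " samples\n", sep = "")
  cat("  reverse: ", sum(x$meta$is_reverse),
      " | contaminant: ", sum(x$meta$is_contaminant),
      " | keratin: ", sum(x$meta$is_keratin), "\n", sep = "")
  if (!is.null(x$ibaq)) cat("  iBAQ matrix present\n")
  sf <- attr(x, "scale_factors")
  if (!is.null(sf)) {
    cat("  normalized to total ", format(attr(x, "normalization_target")),
        " (scale factors ", format(min(sf), digits = 4), "-",
        format(max(sf), digits = 4), ")\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.protein_quant <- function(x) dim(x$intensity)

#' Subset a protein_quant by protein rows
#'
#' @param x a `protein_quant`.
#' @param keep logical or integer index over protein rows.
#' @return A `protein_quant` with the selected rows; normalization
#'   attributes, if present, are preserved.
#' @export
pq_subset <- function(x, keep) {
  out <- protein_quant(
    x$meta[keep, , drop = FALSE],
    x$intensity[keep, , drop = FALSE],
    if (!is.null(x$ibaq)) x$ibaq[keep, , drop = FALSE]
  )
  for (a in c("scale_factors", "normalization_target")) {
    if (!is.null(attr(x, a))) attr(out, a) <- attr(x, a)
  }
  class(out) <- class(x)
  out
}

#' Sample labels of a protein_quant
#' @param x a `protein_quant`.
#' @return Character vector of sample labels (intensity column names).
#' @export
pq_samples <- function(x) colnames(x$intensity)
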