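#' Thresholds for the consistency-based classifier
#'
#' The classifier calls a protein consistently down-regulated when the
#' knockdown/control ratio shows a reduction in every donor with evidence,
#' is <= `down_ratio` in at least `min_qualifying` donors (a knockdown
#' value reduced to undetectable while the control is detected counts as a
#' qualifying reduction), and at most `max_undetectable` donors have the
#' protein undetectable in the knockdown. Up-regulation is symmetric with
#' `up_ratio`, except that an undetected side never qualifies a donor for
#' UP. Proteins detected in fewer than `min_detected_donors` donors are
#' ineligible.
#'
#' @param down_ratio qualifying fold-ratio for DOWN (KD/NT <= this).
#'   Default 0.5.
#' @param up_ratio qualifying fold-ratio for UP (KD/NT >= this).
#'   Default 1.2.
#' @param max_undetectable maximum donors with the protein undetectable in
#'   the knockdown for a DOWN call. Default 2.
#' @param min_detected_donors donors (either condition) a protein must be
#'   detected in to be eligible. Default 3.
#' @param min_qualifying donors that must meet the fold-ratio threshold.
#'   Default 3.
#' @return List of class `diff_config`.
#' @export
diff_config <- function(down_ratio = 0.5, up_ratio = 1.2,
                        max_undetectable = 2, min_detected_donors = 3,
                        min_qualifying = 3) {
  stopifnot(down_ratio > 0, down_ratio < 1, up_ratio > 1,
            max_undetectable >= 0, min_detected_donors >= 1,
            min_qualifying >= 1)
  structure(list(down_ratio = down_ratio, up_ratio = up_ratio,
                 max_undetectable = max_undetectable,
                 min_detected_donors = min_detected_donors,
                 min_qualifying = min_qualifying),
            class = "diff_config")
}

#' Aggregate technical replicates to donor level
#'
#' Per (protein, donor, condition): the arithmetic mean of normalized
#' intensity over the technical runs in which the protein was detected
#' (> 0), or 0 if detected in none. The number of detecting runs is kept
#' alongside. MOCK and BLANK samples are ignored.
#'
#' @param table a [protein_quant] (normally normalized).
#' @param design the sample design.
#' @return List of class `donor_matrix` with elements `kd`, `nt` (protein
#'   x donor matrices of aggregated values), `kd_n`, `nt_n` (detection
#'   counts), `donors`, and `protein_group_id`.
#' @export
aggregate_technical <- function(table, design) {
  stopifnot(inherits(table, "protein_quant"))
  design <- validate_design(design)
  agg_one <- function(cond) {
    d <- design[design$condition == cond, , drop = FALSE]
    donors <- unique(d$donor)
    val <- matrix(0, nrow(table$intensity), length(donors),
                  dimnames = list(rownames(table$intensity), donors))
    n <- val
    for (dn in donors) {
      cols <- d$sample_label[d$donor == dn]
      sub <- table$intensity[, cols, drop = FALSE]
      det <- sub > 0
      cnt <- rowSums(det)
      val[, dn] <- ifelse(cnt > 0, rowSums(sub) / pmax(cnt, 1), 0)
      n[, dn] <- cnt
    }
    list(val = val, n = n, donors = donors)
  }
  kd <- agg_one("KD")
  nt <- agg_one("NT")
  donors <- intersect(kd$donors, nt$donors)
  dropped <- setdiff(union(kd$donors, nt$donors), donors)
  if (length(dropped) > 0) {
    warning("donor(s) missing one condition excluded from differential ",
            "analysis: ", paste(dropped, collapse = ", "))
  }
  if (length(donors) == 0) stop("no donor has both KD and NT samples")
  structure(list(
    kd = kd$val[, donors, drop = FALSE],
    nt = nt$val[, donors, drop = FALSE],
    kd_n = kd$n[, donors, drop = FALSE],
    nt_n = nt$n[, donors, drop = FALSE],
    donors = donors,
    protein_group_id = rownames(table$intensity)
  ), class = "donor_matrix")
}

#' Per-donor knockdown/control ratios
#'
#' @param donor_matrix output of [aggregate_technical()].
#' @return Tibble with one row per (protein, donor): `kd_value`,
#'   `nt_value`, `ratio` (KD/NT; `NA` when either side is undetected) and
#'   detection flags.
#' @export
donor_ratios <- function(donor_matrix) {
  stopifnot(inherits(donor_matrix, "donor_matrix"))
  kd <- donor_matrix$kd
  nt <- donor_matrix$nt
  ratio <- ifelse(kd > 0 & nt > 0, kd / nt, NA_real_)
  tibble::tibble(
    protein_group_id = rep(donor_matrix$protein_group_id, length(donor_matrix$donors)),
    donor = rep(donor_matrix$donors, each = nrow(kd)),
    kd_value = as.vector(kd),
    nt_value = as.vector(nt),
    ratio = as.vector(ratio),
    detected_kd = as.vector(kd > 0),
    detected_nt = as.vector(nt > 0)
  )
}

#' Eligibility for the volcano and the consistency classifier
#'
#' A protein is eligible when it is detected — in at least one condition —
#' in at least `min_detected_donors` donors.
#'
#' @param donor_matrix output of [aggregate_technical()].
#' @param min_detected_donors default 3.
#' @return Named logical vector over proteins.
#' @export
eligibility_filter <- function(donor_matrix, min_detected_donors = 3) {
  stopifnot(inherits(donor_matrix, "donor_matrix"))
  detected <- donor_matrix$kd > 0 | donor_matrix$nt > 0
  n <- rowSums(detected)
  stats::setNames(n >= min_detected_donors, donor_matrix$protein_group_id)
}

#' Classify one protein's per-donor ratios as DOWN, UP or NS
#'
#' Implements the consistency rule on a single protein. Donor evidence is
#' read as: a defined ratio (both sides detected); a reduction to
#' undetectable (KD undetected, NT detected — counts as a qualifying
#' reduction, capped by `max_undetectable`); an apparent appearance (KD
#' detected, NT undetected — increase-direction evidence that can never
#' qualify a donor for UP); or no evidence (neither detected).
#'
#' DOWN: no increase-direction evidence in any donor (all defined ratios
#' < 1 and no KD-only donor); qualifying reductions (defined ratio <=
#' `down_ratio`, plus KD-undetectable donors) >= `min_qualifying`;
#' KD-undetectable donors <= `max_undetectable`. UP: no
#' reduction-direction evidence (all defined ratios > 1, no NT-only
#' donor); defined ratios >= `up_ratio` in >= `min_qualifying` donors.
#' Otherwise NS.
#'
#' @param ratio numeric vector of per-donor KD/NT ratios (`NA` where
#'   undefined).
#' @param detected_kd,detected_nt logical vectors: was the protein
#'   detected in that donor's knockdown / control? Default: inferred from
#'   `ratio` assuming undefined ratios are KD-undetectable.
#' @param config a [diff_config()].
#' @return One of `"DOWN"`, `"UP"`, `"NS"`, `"INELIGIBLE"`.
#' @export
classify_consistency <- function(ratio,
                                 detected_kd = !is.na(ratio),
                                 detected_nt = rep(TRUE, length(ratio)),
                                 config = diff_config()) {
  m <- function(x) matrix(x, nrow = 1)
  drop(classify_consistency_matrix(m(ratio), m(detected_kd),
                                   m(detected_nt), config))
}

#' Vectorised consistency classification
#'
#' Matrix form of [classify_consistency()] over proteins x donors; used by
#' [differential_calls()] for whole-proteome tables.
#'
#' @param ratio proteins x donors matrix of ratios (`NA` = undefined).
#' @param detected_kd,detected_nt logical matrices of the same shape.
#' @param config a [diff_config()].
#' @return Character vector of classes, one per row.
#' @export
classify_consistency_matrix <- function(ratio, detected_kd, detected_nt,
                                        config = diff_config()) {
  stopifnot(identical(dim(ratio), dim(detected_kd)),
            identical(dim(ratio), dim(detected_nt)))
  defined <- detected_kd & detected_nt
  if (any(defined & is.na(ratio))) {
    stop("ratio must be defined wherever both conditions are detected")
  }
  nt_only <- detected_nt & !detected_kd   # reduced to undetectable
  kd_only <- detected_kd & !detected_nt   # apparent appearance

  n_detected <- rowSums(detected_kd | detected_nt)
  eligible <- n_detected >= config$min_detected_donors

  rs <- function(m) rowSums(m, na.rm = TRUE)
  increase_evidence <- rs(kd_only) + rs(defined & ratio >= 1)
  reduction_evidence <- rs(nt_only) + rs(defined & ratio <= 1)
  n_undetectable <- rs(nt_only)
  qual_down <- rs(defined & ratio <= config$down_ratio) + n_undetectable
  qual_up <- rs(defined & ratio >= config$up_ratio)

  down <- eligible & increase_evidence == 0 &
    qual_down >= config$min_qualifying &
    n_undetectable <= config$max_undetectable
  up <- eligible & reduction_evidence == 0 &
    qual_up >= config$min_qualifying

  out <- rep("NS", nrow(ratio))
  out[!eligible] <- "INELIGIBLE"
  out[down] <- "DOWN"
  out[up] <- "UP"
  out
}

#' Paired t-test on log10-transformed values
#'
#' Two-sided paired t-test over usable pairs (both members > 0) of
#' log10-transformed quantitation, as used for the volcano p-values.
#' P-values are reported unadjusted; the classifier does not use them.
#'
#' @param kd_values,nt_values equal-length paired vectors of (normalized)
#'   intensities; a pair contributes only when both entries are > 0.
#' @return List with `t`, `df`, `p`, `n_pairs` and `flag` (`"ok"`,
#'   `"insufficient_pairs"` for < 2 usable pairs, or `"zero_variance"`
#'   when all paired differences are identical; both give `p = NA`).
#' @export
paired_t_log10 <- function(kd_values, nt_values) {
  stopifnot(length(kd_values) == length(nt_values))
  ok <- kd_values > 0 & nt_values > 0 &
    is.finite(kd_values) & is.finite(nt_values)
  n <- sum(ok)
  if (n < 2) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                n_pairs = n, flag = "insufficient_pairs"))
  }
  d <- log10(kd_values[ok]) - log10(nt_values[ok])
  # constant differences (within floating-point) carry no paired evidence
  if (stats::sd(d) / sqrt(n) <= 10 * .Machine$double.eps * max(1, abs(mean(d)))) {
    return(list(t = NA_real_, df = n - 1, p = NA_real_,
                n_pairs = n, flag = "zero_variance"))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n_pairs = n, flag = "ok")
}

#' Volcano table: mean log2 ratio and paired-t p-value per protein
#'
#' For each eligible protein, the log2 KD/NT ratio is computed per donor
#' and averaged over donors with a defined ratio; the p-value comes from
#' [paired_t_log10()] on the donor-level aggregated values.
#'
#' @param donor_matrix output of [aggregate_technical()].
#' @param config a [diff_config()] (supplies `min_detected_donors`).
#' @return Tibble with `protein_group_id`, `n_donors_detected`,
#'   `n_ratios_defined`, `mean_log2_ratio`, `t`, `df`, `p`, `t_flag`,
#'   restricted to eligible proteins.
#' @export
volcano_table <- function(donor_matrix, config = diff_config()) {
  stopifnot(inherits(donor_matrix, "donor_matrix"))
  eligible <- eligibility_filter(donor_matrix, config$min_detected_donors)
  kd <- donor_matrix$kd[eligible, , drop = FALSE]
  nt <- donor_matrix$nt[eligible, , drop = FALSE]
  defined <- kd > 0 & nt > 0
  l2r <- ifelse(defined, log2(kd) - log2(nt), NA_real_)
  mean_l2r <- rowMeans(l2r, na.rm = TRUE)
  mean_l2r[rowSums(defined) == 0] <- NA_real_
  tests <- lapply(seq_len(nrow(kd)), function(i) paired_t_log10(kd[i, ], nt[i, ]))
  tibble::tibble(
    protein_group_id = rownames(kd),
    n_donors_detected = unname(rowSums(kd > 0 | nt > 0)),
    n_ratios_defined = unname(rowSums(defined)),
    mean_log2_ratio = unname(mean_l2r),
    t = vapply(tests, `[[`, numeric(1), "t"),
    df = vapply(tests, `[[`, numeric(1), "df"),
    p = vapply(tests, `[[`, numeric(1), "p"),
    t_flag = vapply(tests, `[[`, character(1), "flag")
  )
}

#' Full differential-abundance calls
#'
#' Runs aggregation, eligibility, the consistency classifier and the
#' volcano statistics, and joins them into one table per protein.
#'
#' @param table a normalized [protein_quant] (decoys/contaminants
#'   removed).
#' @param design the sample design.
#' @param config a [diff_config()].
#' @return Tibble with one row per protein: `protein_group_id`,
#'   `gene_name`, `class`, `n_donors_detected`, one `ratio_<donor>`
#'   column per donor, `mean_log2_ratio`, `p`, `t_flag`.
#' @export
differential_calls <- function(table, design, config = diff_config()) {
  dm <- aggregate_technical(table, design)
  cls <- classify_consistency_matrix(
    ifelse(dm$kd > 0 & dm$nt > 0, dm$kd / dm$nt, NA_real_),
    dm$kd > 0, dm$nt > 0, config
  )
  volc <- volcano_table(dm, config)
  idx <- match(dm$protein_group_id, volc$protein_group_id)
  ratios <- ifelse(dm$kd > 0 & dm$nt > 0, dm$kd / dm$nt, NA_real_)
  out <- tibble::tibble(
    protein_group_id = dm$protein_group_id,
    gene_name = table$meta$gene_name[match(dm$protein_group_id,
                                           table$meta$protein_group_id)],
    class = cls,
    n_donors_detected = unname(rowSums(dm$kd > 0 | dm$nt > 0))
  )
  for (dn in dm$donors) out[[paste0("ratio_", dn)]] <- unname(ratios[, dn])
  out$mean_log2_ratio <- volc$mean_log2_ratio[idx]
  out$p <- volc$p[idx]
  out$t_flag <- ifelse(is.na(idx), "ineligible", volc$t_flag[idx])
  out
}

#' Volcano plot
#'
#' Mean log2 KD/NT ratio against -log10 unadjusted paired-t p-value,
#' coloured by consistency class.
#'
#' @param calls output of [differential_calls()].
#' @return A ggplot object.
#' @export
plot_volcano <- function(calls) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_volcano requires the ggplot2 package")
  }
  d <- calls[!is.na(calls$mean_log2_ratio) & !is.na(calls$p), , drop = FALSE]
  mean_log2_ratio <- p <- class <- NULL # aes columns; silence R CMD check
  ggplot2::ggplot(d, ggplot2::aes(
    x = mean_log2_ratio, y = -log10(p), colour = class)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      DOWN = "#2166ac", UP = "#b2182b", NS = "grey60", INELIGIBLE = "grey85")) +
    ggplot2::labs(x = "mean log2 (KD / NT)",
                  y = "-log10 p (paired t, unadjusted)",
                  colour = "class") +
    ggplot2::theme_minimal()
}
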