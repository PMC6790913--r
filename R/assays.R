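#' Fold change by the 2^-ddCt method
#'
#' Relative expression of a target gene in knockdown versus control,
#' normalized to a reference gene: dCt = Ct_target - Ct_reference per
#' condition, ddCt = dCt_KD - dCt_NT, fold = 2^-ddCt.
#'
#' @param kd,nt matched replicate records: lists or one-row data frames
#'   with fields `ct_target` and `ct_reference` (cycles).
#' @return The fold change (vectorised over equal-length inputs).
#' @export
ddct_fold_change <- function(kd, nt) {
  ct <- function(x, f) {
    v <- x[[f]]
    if (is.null(v)) stop("record lacks field ", f)
    v
  }
  dct_kd <- ct(kd, "ct_target") - ct(kd, "ct_reference")
  dct_nt <- ct(nt, "ct_target") - ct(nt, "ct_reference")
  stopifnot(all(is.finite(dct_kd)), all(is.finite(dct_nt)))
  2^-(dct_kd - dct_nt)
}

#' Summarise a paired qPCR Ct table
#'
#' Computes per-replicate 2^-ddCt fold changes from a long Ct table and
#' summarises them (mean, SEM), with a paired t-test on the per-replicate
#' dCt values. Per-replicate folds are computed first and then averaged
#' (the geometric alternative — averaging ddCt before exponentiation — is
#' available via `average`).
#'
#' @param ct_table tibble with columns `replicate_id`, `condition`
#'   (KD/NT), `ct_target`, `ct_reference`; each replicate must appear in
#'   both conditions.
#' @param average `"fold"` (default; arithmetic mean of per-replicate
#'   folds) or `"ddct"` (2^-mean(ddCt)).
#' @return List with `per_replicate` (tibble of ddCt and fold per
#'   replicate), `mean_fold`, `sem_fold`, and `t_test` (paired t on dCt).
#' @export
qpcr_summary <- function(ct_table, average = c("fold", "ddct")) {
  average <- match.arg(average)
  kd <- ct_table[toupper(ct_table$condition) == "KD", , drop = FALSE]
  nt <- ct_table[toupper(ct_table$condition) == "NT", , drop = FALSE]
  common <- intersect(kd$replicate_id, nt$replicate_id)
  dropped <- setdiff(union(kd$replicate_id, nt$replicate_id), common)
  if (length(dropped) > 0) {
    warning("replicate(s) without a matched pair excluded: ",
            paste(dropped, collapse = ", "))
  }
  kd <- kd[match(common, kd$replicate_id), ]
  nt <- nt[match(common, nt$replicate_id), ]
  dct_kd <- kd$ct_target - kd$ct_reference
  dct_nt <- nt$ct_target - nt$ct_reference
  ddct <- dct_kd - dct_nt
  fold <- 2^-ddct
  per_rep <- tibble::tibble(replicate_id = common, ddct = ddct, fold = fold)
  mean_fold <- if (average == "fold") mean(fold) else 2^-mean(ddct)
  tt <- if (length(common) >= 2 && stats::sd(ddct) > 0) {
    stats::t.test(dct_kd, dct_nt, paired = TRUE)
  } else NULL
  list(per_replicate = per_rep,
       mean_fold = mean_fold,
       sem_fold = stats::sd(fold) / sqrt(length(fold)),
       t_test = tt)
}

#' Summarise histology thickness measurements
#'
#' Each section is measured at three points (right side, middle, left);
#' the per-section value is their mean. For every replicate and layer the
#' KD/NT thickness ratio is formed from the paired section means, and per
#' layer the ratios are summarised as mean +/- SEM (sd/sqrt(n), sample
#' SD) with a paired t-test on the per-replicate means.
#'
#' @param records tibble with columns `replicate_id`, `condition` (KD/NT),
#'   `layer` (e.g. VCL for viable cell layers, SC for stratum corneum),
#'   and the three positions `right_um`, `middle_um`, `left_um`
#'   (micrometres). Replicates missing either condition for a layer are
#'   excluded with a warning.
#' @return List with `per_section` (section means), `ratios` (per
#'   replicate and layer) and `summary` (per layer: n, `mean_ratio`,
#'   `sem_ratio`, paired-t `t` and `p`).
#' @export
thickness_summary <- function(records) {
  pos <- c("right_um", "middle_um", "left_um")
  stopifnot(all(c("replicate_id", "condition", "layer", pos) %in% names(records)))
  if (any(as.matrix(records[, pos]) <= 0)) {
    stop("thickness positions must be > 0")
  }
  per_section <- tibble::tibble(
    replicate_id = records$replicate_id,
    condition = toupper(records$condition),
    layer = records$layer,
    mean_um = rowMeans(records[, pos])
  )
  ratios <- list()
  for (ly in unique(per_section$layer)) {
    sub <- per_section[per_section$layer == ly, ]
    kd <- sub[sub$condition == "KD", ]
    nt <- sub[sub$condition == "NT", ]
    common <- intersect(kd$replicate_id, nt$replicate_id)
    dropped <- setdiff(union(kd$replicate_id, nt$replicate_id), common)
    if (length(dropped) > 0) {
      warning("layer ", ly, ": unpaired replicate(s) excluded: ",
              paste(dropped, collapse = ", "))
    }
    kd <- kd[match(common, kd$replicate_id), ]
    nt <- nt[match(common, nt$replicate_id), ]
    ratios[[ly]] <- tibble::tibble(
      replicate_id = common, layer = ly,
      kd_um = kd$mean_um, nt_um = nt$mean_um,
      ratio = kd$mean_um / nt$mean_um
    )
  }
  ratios <- do.call(rbind, ratios)
  summ <- lapply(split(ratios, ratios$layer), function(g) {
    n <- nrow(g)
    tt <- if (n >= 2 && stats::sd(g$kd_um - g$nt_um) > 0) {
      stats::t.test(g$kd_um, g$nt_um, paired = TRUE)
    } else NULL
    tibble::tibble(
      layer = g$layer[1], n = n,
      mean_ratio = mean(g$ratio),
      sem_ratio = stats::sd(g$ratio) / sqrt(n),
      t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      p = if (is.null(tt)) NA_real_ else tt$p.value
    )
  })
  list(per_section = per_section, ratios = ratios,
       summary = do.call(rbind, summ))
}

#' Mean of exactly k measurements
#'
#' Guard-railed arithmetic mean for protocols that prescribe a fixed
#' number of measurements per unit (e.g. three per organoid).
#'
#' @param values numeric vector.
#' @param k required count.
#' @return The arithmetic mean.
#' @export
mean_of_k <- function(values, k = 3) {
  if (length(values) != k) {
    stop("expected exactly ", k, " values, got ", length(values))
  }
  mean(values)
}

#' Per-replicate knockdown/control ratios with a t-based CI
#'
#' Element-wise KD/NT ratios for paired positive measurements (for
#' example per-replicate ceramide concentrations in pmol/mg), summarised
#' by their mean and a 95% t-interval on the untransformed ratios.
#' Replicates with a non-positive denominator are excluded with a
#' warning. Set `log_scale = TRUE` to summarise on the log2 scale
#' instead (geometric mean and back-transformed CI).
#'
#' @param values_kd,values_nt equal-length paired positive vectors.
#' @param conf_level confidence level. Default 0.95.
#' @param log_scale summarise log2 ratios instead. Default FALSE.
#' @return List with `ratios`, `n`, `mean`, `ci_lower`, `ci_upper`.
#' @export
condition_ratio <- function(values_kd, values_nt, conf_level = 0.95,
                            log_scale = FALSE) {
  stopifnot(length(values_kd) == length(values_nt))
  ok <- values_nt > 0 & is.finite(values_nt) &
    values_kd > 0 & is.finite(values_kd)
  if (any(!ok)) {
    warning(sum(!ok), " replicate(s) with non-positive values excluded")
  }
  r <- values_kd[ok] / values_nt[ok]
  n <- length(r)
  x <- if (log_scale) log2(r) else r
  m <- mean(x)
  half <- if (n >= 2 && stats::sd(x) > 0) {
    stats::qt(1 - (1 - conf_level) / 2, n - 1) * stats::sd(x) / sqrt(n)
  } else NA_real_
  back <- if (log_scale) function(v) 2^v else identity
  list(ratios = r, n = n, mean = back(m),
       ci_lower = back(m - half), ci_upper = back(m + half))
}
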