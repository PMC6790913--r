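test_that("decoy/contaminant filtering counts and precedence", {
  meta <- tibble::tibble(
    protein_group_id = paste0("P", 1:10),
    gene_name = c("KRT1", rep("G", 9)),
    is_reverse = c(rep(TRUE, 2), rep(FALSE, 8)),
    is_contaminant = c(TRUE, FALSE, TRUE, rep(FALSE, 7)),
    is_keratin = c(TRUE, rep(FALSE, 9)),
    n_theoretical_peptides = 5L
  )
  m <- matrix(1, 10, 2, dimnames = list(meta$protein_group_id, c("S1", "S2")))
  filt <- filter_contaminants_decoys(protein_quant(meta, m))
  # P1 is both reverse and contaminant: counted once, under reverse
  expect_equal(filt$report$reverse, 2)
  expect_equal(filt$report$contaminant, 1)
  expect_equal(filt$report$kept, 7)
  expect_equal(nrow(filt$table$meta), 7)
  # rows_in = rows_out + removals
  expect_equal(10, filt$report$kept + filt$report$reverse +
                 filt$report$contaminant)
})

test_that("non-contaminant keratins survive the filter", {
  ds <- generate_dataset(tiny_config(seed = 21))
  filt <- filter_contaminants_decoys(ds$table)
  expect_equal(filt$report$reverse, sum(ds$truth$truth_class == "DECOY"))
  expect_equal(filt$report$contaminant,
               sum(ds$truth$truth_class == "CONTAMINANT"))
  expect_true(any(filt$table$meta$is_keratin))
})

test_that("blank subtraction floors at zero and only touches keratins", {
  h <- hand_quant()
  blank <- tibble::tibble(protein_group_id = c("P1", "P2"),
                          blank_intensity = c(30, 30))
  out <- subtract_keratin_blank(h$table, blank)
  # P1 (AKT1, not keratin) untouched despite a listed blank
  expect_equal(out$intensity["P1", ], h$table$intensity["P1", ])
  # P2 (KRT10) reduced by 30 in every sample
  expect_equal(out$intensity["P2", ], h$table$intensity["P2", ] - 30)

  big <- tibble::tibble(protein_group_id = "P2", blank_intensity = 1e6)
  out2 <- subtract_keratin_blank(h$table, big)
  expect_true(all(out2$intensity["P2", ] == 0))

  expect_warning(
    subtract_keratin_blank(h$table, tibble::tibble(
      protein_group_id = "NOPE", blank_intensity = 5)),
    "absent")
})

test_that("larger blanks never increase downstream intensities", {
  ds <- generate_dataset(tiny_config(seed = 22))
  cfg_lo <- tiny_config(seed = 22, blank_fraction = 0.2)
  cfg_hi <- tiny_config(seed = 22, blank_fraction = 0.8)
  lo <- subtract_keratin_blank(ds$table, generate_blank_run(cfg_lo, ds$table))
  hi <- subtract_keratin_blank(ds$table, generate_blank_run(cfg_hi, ds$table))
  expect_true(all(hi$intensity <= lo$intensity + 1e-12))
})

test_that("normalization scales every sample to the lowest total", {
  meta <- tibble::tibble(protein_group_id = c("P1", "P2"), gene_name = "G",
                         is_reverse = FALSE, is_contaminant = FALSE,
                         is_keratin = FALSE, n_theoretical_peptides = 4L)
  m <- matrix(c(60, 40, 150, 50, 300, 100), 2,
              dimnames = list(c("P1", "P2"), c("S1", "S2", "S3")))
  pq <- protein_quant(meta, m, ibaq = m / 4)
  norm <- normalize_total(pq)
  expect_equal(unname(attr(norm, "scale_factors")), c(1, 0.5, 0.25))
  expect_equal(unname(colSums(norm$intensity)), rep(100, 3))
  expect_equal(attr(norm, "normalization_target"), 100)
  # iBAQ scaled by the same factor
  expect_equal(norm$ibaq, sweep(pq$ibaq, 2, attr(norm, "scale_factors"), "*"))
  # within-sample ratios preserved exactly
  expect_equal(norm$intensity["P1", ] / norm$intensity["P2", ],
               pq$intensity["P1", ] / pq$intensity["P2", ])

  single <- protein_quant(meta, m[, 1, drop = FALSE])
  expect_equal(normalize_total(single)$intensity, m[, 1, drop = FALSE])

  m0 <- m; m0[, 2] <- 0
  expect_error(normalize_total(protein_quant(meta, m0)), "S2")
})

test_that("normalized totals agree to 1e-9 relative on random tables", {
  for (s in 1:5) {
    ds <- generate_dataset(tiny_config(seed = 100 + s, n_proteins = 150))
    norm <- normalize_total(ds$table)
    totals <- colSums(norm$intensity)
    expect_lt(max(abs(totals - min(totals))) / min(totals), 1e-9)
    expect_true(all(attr(norm, "scale_factors") <= 1 + 1e-15))
  }
})

test_that("iBAQ divides summed intensity by theoretical peptide count", {
  expect_equal(compute_ibaq(60, 3), 20)
  expect_equal(compute_ibaq(0, 5), 0)
  expect_warning(v <- compute_ibaq(10, 0), "0 theoretical")
  expect_true(is.nan(v))
})

test_that("replicate correlation is complete-case Pearson on log2 scale", {
  meta <- tibble::tibble(protein_group_id = paste0("P", 1:4), gene_name = "G",
                         is_reverse = FALSE, is_contaminant = FALSE,
                         is_keratin = FALSE, n_theoretical_peptides = 1L)
  m <- cbind(S1 = 2^c(1, 2, 3, 5), S2 = 2^c(3, 2, 1, 5),
             S3 = 2^c(1, 2, 3, 5))
  rownames(m) <- meta$protein_group_id
  r <- replicate_correlation(protein_quant(meta, m), use = "intensity")
  expect_equal(diag(r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(r["S1", "S3"], 1.0)
  expect_lt(r["S1", "S2"], 1.0)

  # perfect anticorrelation on the first three proteins only
  m2 <- m; m2[4, ] <- 0
  r2 <- replicate_correlation(protein_quant(meta, m2), use = "intensity")
  expect_equal(r2["S1", "S2"], -1.0)

  # too few common detected proteins -> NA
  m3 <- m
  m3[1:2, 1] <- 0
  r3 <- replicate_correlation(protein_quant(meta, m3), use = "intensity")
  expect_true(is.na(r3["S1", "S2"]))
})

test_that("synthetic technical quadruplicates are tightly correlated", {
  ds <- generate_dataset(tiny_config(seed = 30, n_proteins = 800))
  norm <- normalize_total(filter_contaminants_decoys(ds$table)$table)
  r <- replicate_correlation(norm, ds$design)
  d <- ds$design
  for (g in split(d$sample_label, paste(d$donor, d$condition))) {
    if (length(g) < 2) next
    sub <- r[g, g]
    expect_true(all(sub[upper.tri(sub)] > 0.95))
  }
})

test_that("intensity histogram conserves detected-protein counts", {
  meta <- tibble::tibble(protein_group_id = c("P1", "P2"), gene_name = "G",
                         is_reverse = FALSE, is_contaminant = FALSE,
                         is_keratin = FALSE, n_theoretical_peptides = 1L)
  m <- cbind(S1 = c(2^21.5, 0))
  rownames(m) <- meta$protein_group_id
  h <- intensity_histogram(protein_quant(meta, m), bin_width = 1)
  expect_equal(nrow(h), 1)
  expect_equal(h$bin_lower, 21)
  expect_equal(h$bin_upper, 22)
  expect_equal(h$count, 1L)

  ds <- generate_dataset(tiny_config(seed = 31))
  hh <- intensity_histogram(ds$table)
  mass <- tapply(hh$count, hh$sample_label, sum)
  detected <- colSums(ds$table$ibaq > 0)
  expect_equal(as.vector(mass[names(detected)]), unname(detected),
               ignore_attr = TRUE)
})

test_that("pipeline results are invariant to protein row order", {
  ds <- generate_dataset(tiny_config(seed = 32, n_proteins = 120))
  blank <- generate_blank_run(tiny_config(seed = 32), ds$table)
  res1 <- run_pipeline(ds$table, ds$design, blank)
  perm <- sample(nrow(ds$table$meta))
  shuffled <- pq_subset(ds$table, perm)
  res2 <- run_pipeline(shuffled, ds$design, blank)
  c1 <- res1$calls[order(res1$calls$protein_group_id), ]
  c2 <- res2$calls[order(res2$calls$protein_group_id), ]
  expect_equal(c1, c2, ignore_attr = TRUE)
})
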