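test_that("technical aggregation averages over detected runs only", {
  design <- tibble::tibble(
    sample_label = paste0("S", 1:4), donor = "A", condition = "KD",
    tech_rep = 1:4)
  design <- rbind(design, tibble::tibble(
    sample_label = "S5", donor = "A", condition = "NT", tech_rep = 1))
  meta <- tibble::tibble(protein_group_id = c("P1", "P2"), gene_name = "G",
                         is_reverse = FALSE, is_contaminant = FALSE,
                         is_keratin = FALSE, n_theoretical_peptides = 1L)
  m <- rbind(P1 = c(100, 110, 0, 90, 50),
             P2 = c(0, 0, 0, 0, 10))
  colnames(m) <- design$sample_label
  dm <- aggregate_technical(protein_quant(meta, m), design)
  expect_equal(dm$kd["P1", "A"], 100)   # mean of detected runs
  expect_equal(dm$kd_n["P1", "A"], 3)
  expect_equal(dm$kd["P2", "A"], 0)     # detected in none
  expect_equal(dm$kd_n["P2", "A"], 0)
  expect_equal(dm$nt["P1", "A"], 50)    # single run is identity
})

test_that("donors missing one condition are excluded with a warning", {
  h <- hand_quant()
  lop <- h$design[!(h$design$donor == "B" & h$design$condition == "NT"), ]
  expect_warning(dm <- aggregate_technical(h$table, lop), "B")
  expect_equal(dm$donors, "A")
})

test_that("donor ratios follow the undefined-when-undetected convention", {
  h <- hand_quant()
  dr <- donor_ratios(aggregate_technical(h$table, h$design))
  get <- function(p, d) dr[dr$protein_group_id == p & dr$donor == d, ]
  expect_equal(get("P1", "A")$ratio, 0.5)
  expect_equal(get("P2", "A")$ratio, 2.0)
  r3 <- get("P3", "A")
  expect_true(is.na(r3$ratio))
  expect_false(r3$detected_kd)
  expect_true(r3$detected_nt)
})

test_that("eligibility needs detection in at least 3 donors", {
  mk <- function(det) {
    # det: logical per donor, detected in NT
    structure(list(
      kd = matrix(0, 1, 4, dimnames = list("P", paste0("D", 1:4))),
      nt = matrix(ifelse(det, 10, 0), 1, 4,
                  dimnames = list("P", paste0("D", 1:4))),
      kd_n = matrix(0, 1, 4), nt_n = matrix(as.numeric(det), 1, 4),
      donors = paste0("D", 1:4), protein_group_id = "P"
    ), class = "donor_matrix")
  }
  expect_true(eligibility_filter(mk(c(TRUE, TRUE, TRUE, FALSE)))[[1]])
  expect_false(eligibility_filter(mk(c(TRUE, TRUE, FALSE, FALSE)))[[1]])
  expect_true(eligibility_filter(mk(rep(TRUE, 4)))[[1]])
})

test_that("the consistency classifier reproduces the quoted rule on hand cases", {
  expect_equal(classify_consistency(c(0.4, 0.45, 0.5, 0.9)), "DOWN")
  expect_equal(classify_consistency(c(0.4, 0.4, 0.4, 1.1)), "NS")
  expect_equal(classify_consistency(c(1.3, 1.25, 1.2, 1.05)), "UP")
  # two donors reduced to undetectable still permit DOWN (cap is 2)
  expect_equal(classify_consistency(c(0.3, 0.3, NA, NA)), "DOWN")
  # three undetectable exceed the cap
  expect_equal(classify_consistency(c(0.3, NA, NA, NA)), "NS")
  # boundary: ratio exactly 1 is neither a reduction nor an increase
  expect_equal(classify_consistency(c(0.4, 0.4, 0.4, 1.0)), "NS")
  expect_equal(classify_consistency(c(1.3, 1.3, 1.2, 1.0)), "NS")
  # an apparent appearance (KD detected, NT not) cannot qualify for UP
  expect_equal(classify_consistency(
    c(1.3, 1.3, NA, NA),
    detected_kd = c(TRUE, TRUE, TRUE, TRUE),
    detected_nt = c(TRUE, TRUE, FALSE, FALSE)), "NS")
  # detected in only two donors -> ineligible
  expect_equal(classify_consistency(
    c(0.3, 0.3, NA, NA),
    detected_kd = c(TRUE, TRUE, FALSE, FALSE),
    detected_nt = c(TRUE, TRUE, FALSE, FALSE)), "INELIGIBLE")
})

test_that("no threshold configuration can call a protein both UP and DOWN", {
  set.seed(77)
  vals <- c(0.2, 0.5, 0.9, 1, 1.1, 1.2, 2, NA)
  for (i in 1:200) {
    ratio <- sample(vals, 4, replace = TRUE)
    cfg <- diff_config(down_ratio = runif(1, 0.1, 0.9),
                       up_ratio = runif(1, 1.05, 3),
                       max_undetectable = sample(0:3, 1),
                       min_qualifying = sample(1:4, 1))
    cls <- classify_consistency(ratio, config = cfg)
    expect_true(cls %in% c("DOWN", "UP", "NS", "INELIGIBLE"))
  }
  # directly: DOWN requires all defined ratios < 1, UP all > 1
  cfg <- diff_config(min_qualifying = 1)
  expect_equal(classify_consistency(c(0.4, 0.4, 0.4, 0.4), config = cfg), "DOWN")
  expect_equal(classify_consistency(c(1.3, 1.3, 1.3, 1.3), config = cfg), "UP")
})

test_that("threshold tightening is monotone in the calls it admits", {
  set.seed(123)
  ratios <- lapply(1:300, function(i) {
    r <- exp(rnorm(4, 0, 0.7))
    r[sample(c(TRUE, FALSE), 4, replace = TRUE, prob = c(0.15, 0.85))] <- NA
    r
  })
  for (pair in list(c(0.5, 0.4), c(0.7, 0.5))) {
    loose <- vapply(ratios, classify_consistency,
                    character(1), config = diff_config(down_ratio = pair[1]))
    tight <- vapply(ratios, classify_consistency,
                    character(1), config = diff_config(down_ratio = pair[2]))
    expect_true(all(loose[tight == "DOWN"] == "DOWN"))
  }
  for (pair in list(c(1.2, 1.5), c(1.1, 1.2))) {
    loose <- vapply(ratios, classify_consistency,
                    character(1), config = diff_config(up_ratio = pair[1]))
    tight <- vapply(ratios, classify_consistency,
                    character(1), config = diff_config(up_ratio = pair[2]))
    expect_true(all(loose[tight == "UP"] == "UP"))
  }
})

test_that("paired t on log10 data matches the closed form", {
  # log10 differences 1, 2, 3: t = 2 / (1/sqrt(3)), df = 2
  kd <- c(10, 100, 1000)
  nt <- c(1, 1, 1)
  res <- paired_t_log10(kd, nt)
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(res$t, 3.4641, tolerance = 1e-4)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * stats::pt(res$t, 2, lower.tail = FALSE))
  expect_equal(res$p, 0.0742, tolerance = 1e-3)
  expect_equal(res$flag, "ok")

  same <- paired_t_log10(c(5, 7, 9), c(5, 7, 9))
  expect_true(is.na(same$p))
  expect_equal(same$flag, "zero_variance")

  two <- paired_t_log10(c(10, 20), c(1, 2))
  expect_equal(two$flag, "zero_variance")

  few <- paired_t_log10(c(10, 0), c(1, 5))
  expect_equal(few$flag, "insufficient_pairs")
  expect_true(is.na(few$p))
  # pairs with an undetected member do not contribute
  res2 <- paired_t_log10(c(10, 100, 1000, 0), c(1, 1, 1, 50))
  expect_equal(res2$n_pairs, 3)
  expect_equal(res2$t, res$t)
})

test_that("volcano averages log2 ratios over donors with defined ratios", {
  mk <- function(kd, nt) {
    structure(list(
      kd = matrix(kd, 1, 4, dimnames = list("P", paste0("D", 1:4))),
      nt = matrix(nt, 1, 4, dimnames = list("P", paste0("D", 1:4))),
      kd_n = matrix(1, 1, 4), nt_n = matrix(1, 1, 4),
      donors = paste0("D", 1:4), protein_group_id = "P"
    ), class = "donor_matrix")
  }
  v <- volcano_table(mk(c(50, 50, 50, 50), c(100, 100, 100, 100)))
  expect_equal(v$mean_log2_ratio, -1)
  v2 <- volcano_table(mk(c(200, 50, 10, 10), c(100, 100, 0, 10)))
  expect_equal(v2$mean_log2_ratio, mean(c(1, -1, 0)))  # undefined donor skipped
})

test_that("calls are invariant to a global intensity rescaling", {
  ds <- generate_dataset(tiny_config(seed = 40, n_proteins = 150))
  res1 <- run_pipeline(ds$table, ds$design)
  scaled <- ds$table
  scaled$intensity <- scaled$intensity * 7.3
  scaled$ibaq <- scaled$ibaq * 7.3
  res2 <- run_pipeline(scaled, ds$design)
  expect_equal(res1$calls$class, res2$calls$class)
  expect_equal(res1$calls$mean_log2_ratio, res2$calls$mean_log2_ratio,
               tolerance = 1e-10)
  expect_equal(res1$calls$p, res2$calls$p, tolerance = 1e-10)
})

test_that("differential_calls recovers strong planted effects on a small study", {
  ds <- generate_dataset(tiny_config(seed = 41, n_proteins = 500,
                                     tech_sd = 0.1, donor_sd = 0.3))
  norm <- normalize_total(filter_contaminants_decoys(ds$table)$table)
  calls <- differential_calls(norm, ds$design)
  tr <- ds$truth$truth_class[match(calls$protein_group_id,
                                   ds$truth$protein_group_id)]
  down_called <- calls$class[tr == "DOWN_TRUE"] == "DOWN"
  expect_gt(mean(down_called), 0.7)
  expect_lt(mean(calls$class[tr == "NULL_TRUE"] %in% c("DOWN", "UP")), 0.02)
  # planted -2 effects are recovered in the volcano means
  planted <- calls$mean_log2_ratio[tr == "DOWN_TRUE" & calls$class == "DOWN"]
  expect_lt(abs(median(planted) - -2), 0.2)
})
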