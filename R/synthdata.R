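#' Configuration for the synthetic proteomics generator
#'
#' The generator emulates the study design the pipeline was built for:
#' paired knockdown (KD) and non-targeting-control (NT) organoid samples
#' from several donors, each protein extract run in technical
#' quadruplicate, with log-normal protein intensities, per-(protein,
#' donor) biological variability, planted knockdown effects on known
#' protein subsets, left-censoring at a detection limit, keratin
#' contaminant rows and reversed-sequence decoy rows.
#'
#' The generative model for the log2 intensity of protein p in sample
#' (donor d, condition c, run t) is
#' `mu_p + delta_{p,d} + beta_p * 1[c == KD] + eps`, with
#' `mu_p ~ Uniform(base_mean_range)`, `delta_{p,d} ~ Normal(0, donor_sd)`,
#' `eps ~ Normal(0, tech_sd)` and `beta_p` equal to `effect_log2_down`,
#' `effect_log2_up` or 0 according to the protein's truth class. Values
#' whose log2 intensity falls below `detect_limit` are censored to 0
#' (undetected). Keratin contaminants have condition- and donor-independent
#' means; decoys follow the null model and are flagged `is_reverse`.
#'
#' @param seed integer seed; the generator is a pure function of the
#'   config, so identical configs give bit-identical output.
#' @param n_donors number of donors (biological replicates). Default 4.
#' @param n_tech_reps technical runs per (donor, condition). Default 4.
#' @param n_proteins number of genuine (non-contaminant, non-decoy)
#'   protein groups. Default 9000.
#' @param frac_down,frac_up fraction of genuine proteins with a planted
#'   down-/up-regulation effect. Defaults 0.05 each.
#' @param effect_log2_down,effect_log2_up planted log2 knockdown effects.
#'   Defaults -2.0 and +0.5.
#' @param donor_sd SD of the per-(protein, donor) random effect, log2
#'   units. Default 0.5.
#' @param tech_sd SD of per-run technical noise, log2 units. Default 0.25.
#' @param detect_limit detection limit on the log2-intensity scale; cells
#'   below it are censored to 0. `NULL` (default) uses the 2nd percentile
#'   of the genuine proteins' baseline means.
#' @param n_keratin_contaminants keratin contaminant rows (flagged both
#'   contaminant and keratin). Default 10.
#' @param n_genuine_keratins genuine (non-contaminant) keratin proteins
#'   drawn from the null class, so blank subtraction has real targets.
#'   Default 10.
#' @param n_decoys reversed-sequence decoy rows. Default 100.
#' @param base_mean_range range of baseline log2 means. Default c(20, 30).
#' @param blank_fraction fraction of a keratin row's mean intensity seen
#'   in the blank run. Default 0.3.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_donors = 4L,
                         n_tech_reps = 4L,
                         n_proteins = 9000L,
                         frac_down = 0.05,
                         frac_up = 0.05,
                         effect_log2_down = -2.0,
                         effect_log2_up = 0.5,
                         donor_sd = 0.5,
                         tech_sd = 0.25,
                         detect_limit = NULL,
                         n_keratin_contaminants = 10L,
                         n_genuine_keratins = 10L,
                         n_decoys = 100L,
                         base_mean_range = c(20, 30),
                         blank_fraction = 0.3) {
  stopifnot(frac_down >= 0, frac_up >= 0, frac_down + frac_up < 1,
            donor_sd >= 0, tech_sd >= 0,
            n_donors >= 1, n_tech_reps >= 1, n_proteins >= 1,
            length(base_mean_range) == 2,
            base_mean_range[1] <= base_mean_range[2])
  structure(list(
    seed = as.integer(seed), n_donors = as.integer(n_donors),
    n_tech_reps = as.integer(n_tech_reps),
    n_proteins = as.integer(n_proteins),
    frac_down = frac_down, frac_up = frac_up,
    effect_log2_down = effect_log2_down, effect_log2_up = effect_log2_up,
    donor_sd = donor_sd, tech_sd = tech_sd, detect_limit = detect_limit,
    n_keratin_contaminants = as.integer(n_keratin_contaminants),
    n_genuine_keratins = as.integer(n_genuine_keratins),
    n_decoys = as.integer(n_decoys),
    base_mean_range = as.numeric(base_mean_range),
    blank_fraction = blank_fraction
  ), class = "synth_config")
}

default_donor_names <- function(n) {
  if (n == 4) c("MS2", "MS3", "MS5", "MS6") else paste0("D", seq_len(n))
}

#' Generate a synthetic protein-groups dataset with known ground truth
#'
#' @param config a [synth_config()].
#' @return A list with elements `table` (a [protein_quant] including an
#'   iBAQ matrix), `design` (sample-design tibble) and `truth` (tibble
#'   mapping `protein_group_id` to truth class: DOWN_TRUE, UP_TRUE,
#'   NULL_TRUE, CONTAMINANT or DECOY).
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  donors <- default_donor_names(config$n_donors)
  design <- expand.grid(
    tech_rep = seq_len(config$n_tech_reps),
    condition = c("KD", "NT"),
    donor = donors,
    stringsAsFactors = FALSE
  )
  design <- tibble::tibble(
    sample_label = sprintf("%s_%s_r%d", design$donor, design$condition,
                           design$tech_rep),
    donor = design$donor,
    condition = factor(design$condition,
                       levels = c("KD", "NT", "MOCK", "BLANK")),
    tech_rep = as.integer(design$tech_rep)
  )

  np <- config$n_proteins
  n_down <- round(config$frac_down * np)
  n_up <- round(config$frac_up * np)
  cls <- rep("NULL_TRUE", np)
  planted <- sample.int(np, n_down + n_up)
  cls[planted[seq_len(n_down)]] <- "DOWN_TRUE"
  cls[planted[n_down + seq_len(n_up)]] <- "UP_TRUE"

  ids <- sprintf("P%05d", seq_len(np))
  genes <- sprintf("GENE%05d", seq_len(np))
  # give some null proteins genuine keratin identities (not contaminants):
  # these are real epidermal keratins, the targets of blank subtraction
  nk <- min(config$n_genuine_keratins, sum(cls == "NULL_TRUE"))
  keratin_rows <- sample(which(cls == "NULL_TRUE"), nk)
  genes[keratin_rows] <- sprintf("KRT%d", seq_len(nk))

  beta <- ifelse(cls == "DOWN_TRUE", config$effect_log2_down,
                 ifelse(cls == "UP_TRUE", config$effect_log2_up, 0))
  mu <- stats::runif(np, config$base_mean_range[1], config$base_mean_range[2])
  detect_limit <- config$detect_limit
  if (is.null(detect_limit)) {
    detect_limit <- stats::quantile(mu, 0.02, names = FALSE)
  }

  ns <- nrow(design)
  delta <- matrix(stats::rnorm(np * config$n_donors, 0, config$donor_sd),
                  nrow = np, dimnames = list(NULL, donors))
  is_kd <- design$condition == "KD"
  log2i <- matrix(mu, np, ns) +
    delta[, design$donor, drop = FALSE] +
    outer(beta, as.numeric(is_kd)) +
    matrix(stats::rnorm(np * ns, 0, config$tech_sd), np, ns)

  # contaminant keratins: flat instrument background, no donor/condition term
  nc <- config$n_keratin_contaminants
  if (nc > 0) {
    mu_c <- stats::runif(nc, config$base_mean_range[1], config$base_mean_range[2])
    log2c <- matrix(mu_c, nc, ns) +
      matrix(stats::rnorm(nc * ns, 0, config$tech_sd), nc, ns)
    log2i <- rbind(log2i, log2c)
    ids <- c(ids, sprintf("CON__KRTC%02d", seq_len(nc)))
    genes <- c(genes, sprintf("KRT%d", nk + seq_len(nc)))
    cls <- c(cls, rep("CONTAMINANT", nc))
  }

  nd <- config$n_decoys
  if (nd > 0) {
    mu_d <- stats::runif(nd, config$base_mean_range[1], config$base_mean_range[2])
    delta_d <- matrix(stats::rnorm(nd * config$n_donors, 0, config$donor_sd),
                      nrow = nd, dimnames = list(NULL, donors))
    log2d <- matrix(mu_d, nd, ns) + delta_d[, design$donor, drop = FALSE] +
      matrix(stats::rnorm(nd * ns, 0, config$tech_sd), nd, ns)
    log2i <- rbind(log2i, log2d)
    ids <- c(ids, sprintf("REV__P%05d", seq_len(nd)))
    genes <- c(genes, rep("", nd))
    cls <- c(cls, rep("DECOY", nd))
  }

  intensity <- 2^log2i
  intensity[log2i < detect_limit] <- 0
  dimnames(intensity) <- list(ids, design$sample_label)

  n_theo <- pmax(1L, stats::rpois(length(ids), 15))
  ibaq <- sweep(intensity, 1, n_theo, "/")

  meta <- tibble::tibble(
    protein_group_id = ids,
    gene_name = genes,
    is_reverse = cls == "DECOY",
    is_contaminant = cls == "CONTAMINANT",
    is_keratin = grepl("^KRT[0-9]+$", genes, ignore.case = TRUE),
    n_theoretical_peptides = n_theo
  )

  list(
    table = protein_quant(meta, intensity, ibaq),
    design = design,
    truth = tibble::tibble(protein_group_id = ids, truth_class = cls),
    detect_limit = detect_limit
  )
}

#' Generate a blank-run keratin intensity table
#'
#' Emulates an instrument blank run used to estimate background keratin
#' contamination: every keratin-flagged row gets a positive blank
#' intensity equal to `blank_fraction` of its across-sample mean;
#' non-keratin rows get 0.
#'
#' @param config a [synth_config()] (supplies `blank_fraction`).
#' @param table a [protein_quant] from [generate_dataset()].
#' @return Tibble with columns `protein_group_id`, `blank_intensity`.
#' @export
generate_blank_run <- function(config, table) {
  stopifnot(inherits(table, "protein_quant"))
  blank <- ifelse(table$meta$is_keratin,
                  config$blank_fraction * rowMeans(table$intensity), 0)
  tibble::tibble(protein_group_id = table$meta$protein_group_id,
                 blank_intensity = blank)
}

#' Generate gene sets with planted enrichment
#'
#' Emits one set enriched in genes of planted down-regulated proteins, one
#' enriched in up-regulated ones, and `n_null_sets` sets drawn uniformly
#' from all genes — a fixture for over-representation analysis with known
#' positives.
#'
#' @param dataset output of [generate_dataset()].
#' @param purity fraction of each enriched set drawn from its truth class
#'   (remainder drawn from other genes). Default 0.8.
#' @param set_size members per set. Default 50.
#' @param n_null_sets number of random null sets. Default 20.
#' @param seed seed for set sampling. Default: the dataset config seed is
#'   not consulted; pass one explicitly for reproducibility.
#' @return A `gene_set_collection` (see [read_gmt()]).
#' @export
generate_gene_sets <- function(dataset, purity = 0.8, set_size = 50,
                               n_null_sets = 20, seed = 1L) {
  stopifnot(purity >= 0, purity <= 1, set_size >= 1)
  set.seed(seed)
  truth <- dataset$truth
  meta <- dataset$table$meta
  genuine <- !meta$is_reverse & !meta$is_contaminant & nzchar(meta$gene_name)
  genes <- meta$gene_name[genuine]
  cls <- truth$truth_class[genuine]

  planted_set <- function(target_class, nm) {
    pool_in <- genes[cls == target_class]
    pool_out <- genes[cls != target_class]
    k_in <- min(round(purity * set_size), length(pool_in))
    members <- c(sample(pool_in, k_in),
                 sample(pool_out, set_size - k_in))
    attr(members, "description") <- paste("planted", target_class, "set")
    members
  }
  sets <- list(
    DOWN_ENRICHED = planted_set("DOWN_TRUE"),
    UP_ENRICHED = planted_set("UP_TRUE")
  )
  for (i in seq_len(n_null_sets)) {
    members <- sample(genes, set_size)
    attr(members, "description") <- "random null set"
    sets[[sprintf("NULL_SET_%02d", i)]] <- members
  }
  structure(sets, class = "gene_set_collection")
}

#' Generate paired qPCR and histology assay tables
#'
#' Builds the two small-assay fixtures: a qPCR cycle-threshold table
#' (target and reference gene Cts for paired KD/NT organoids, with a
#' planted delta-delta-Ct) and a histology thickness table (three measured
#' positions per section, viable cell layers and stratum corneum, with a
#' planted KD/NT stratum-corneum thickness ratio).
#'
#' @param seed integer seed.
#' @param n_replicates biological replicates for each assay. Defaults:
#'   8 for qPCR, 10 for histology (the organoid study's sample sizes).
#' @param planted_ddct planted delta-delta-Ct of the knockdown (target
#'   vs reference gene). Default 3, i.e. a 2^-3 = 0.125 fold change.
#' @param ct_sd per-well Ct noise SD in cycles. Default 0.2.
#' @param planted_sc_ratio planted stratum-corneum KD/NT thickness ratio.
#'   Default 0.83.
#' @param sc_ratio_sd between-replicate SD of the SC ratio. Default 0.16
#'   (so SEM across 10 replicates is about 0.05).
#' @param position_sd within-section SD of the three position
#'   measurements, micrometres. Default 1.5.
#' @param n_qpcr_replicates,n_histology_replicates override `n_replicates`
#'   per assay.
#' @return List with tibbles `qpcr` (replicate_id, condition, ct_target,
#'   ct_reference) and `histology` (replicate_id, condition, layer,
#'   right_um, middle_um, left_um).
#' @export
generate_assay_tables <- function(seed = 1L,
                                  n_replicates = NULL,
                                  planted_ddct = 3,
                                  ct_sd = 0.2,
                                  planted_sc_ratio = 0.83,
                                  sc_ratio_sd = 0.16,
                                  position_sd = 1.5,
                                  n_qpcr_replicates = 8L,
                                  n_histology_replicates = 10L) {
  set.seed(seed)
  if (!is.null(n_replicates)) {
    n_qpcr_replicates <- n_histology_replicates <- as.integer(n_replicates)
  }

  # qPCR: reference gene Ct ~ 15 cycles, target ~ 22 in control; the
  # knockdown raises the target Ct by planted_ddct cycles
  nq <- n_qpcr_replicates
  base_ref <- stats::rnorm(nq, 15, 0.5)
  base_tgt <- stats::rnorm(nq, 22, 0.5)
  qpcr <- tibble::tibble(
    replicate_id = rep(sprintf("R%02d", seq_len(nq)), 2),
    condition = rep(c("KD", "NT"), each = nq),
    ct_target = c(base_tgt + planted_ddct + stats::rnorm(nq, 0, ct_sd),
                  base_tgt + stats::rnorm(nq, 0, ct_sd)),
    ct_reference = c(base_ref + stats::rnorm(nq, 0, ct_sd),
                     base_ref + stats::rnorm(nq, 0, ct_sd))
  )

  # histology: viable cell layers ~60 um (no planted effect), stratum
  # corneum ~20 um scaled by a per-replicate ratio around planted_sc_ratio
  nh <- n_histology_replicates
  rep_ids <- sprintf("R%02d", seq_len(nh))
  vcl_nt <- stats::rnorm(nh, 60, 6)
  sc_nt <- stats::rnorm(nh, 20, 2)
  sc_ratio <- planted_sc_ratio + stats::rnorm(nh, 0, sc_ratio_sd)
  rows <- list()
  for (i in seq_len(nh)) {
    means <- c(VCL_NT = vcl_nt[i], VCL_KD = vcl_nt[i],
               SC_NT = sc_nt[i], SC_KD = sc_nt[i] * sc_ratio[i])
    for (nm in names(means)) {
      parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
      pos <- pmax(0.1, means[[nm]] + stats::rnorm(3, 0, position_sd))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        replicate_id = rep_ids[i], condition = parts[2], layer = parts[1],
        right_um = pos[1], middle_um = pos[2], left_um = pos[3]
      )
    }
  }
  histology <- do.call(rbind, rows)
  list(qpcr = qpcr, histology = histology)
}
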