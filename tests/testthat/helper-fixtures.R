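# Small in-code fixtures shared across test files.

# a compact synthetic study: 4 donors x 2 conditions x 4 runs, few proteins
tiny_config <- function(seed = 42, n_proteins = 400, ...) {
  synth_config(seed = seed, n_proteins = n_proteins,
               n_keratin_contaminants = 3, n_genuine_keratins = 3,
               n_decoys = 10, ...)
}

# a deterministic 2-donor, 2-run protein_quant built by hand
hand_quant <- function() {
  design <- tibble::tibble(
    sample_label = c("A_KD_r1", "A_KD_r2", "A_NT_r1", "A_NT_r2",
                     "B_KD_r1", "B_KD_r2", "B_NT_r1", "B_NT_r2"),
    donor = rep(c("A", "B"), each = 4),
    condition = factor(rep(c("KD", "KD", "NT", "NT"), 2),
                       levels = c("KD", "NT", "MOCK", "BLANK")),
    tech_rep = rep(c(1L, 2L), 4)
  )
  intensity <- matrix(
    c(50, 50, 100, 100, 40, 60, 100, 100,   # P1: ratio 0.5 both donors
      200, 200, 100, 100, 150, 150, 100, 100, # P2: up 2.0 / 1.5
      0, 0, 80, 80, 0, 0, 60, 60),            # P3: KD undetected
    nrow = 3, byrow = TRUE,
    dimnames = list(c("P1", "P2", "P3"), design$sample_label)
  )
  meta <- tibble::tibble(
    protein_group_id = c("P1", "P2", "P3"),
    gene_name = c("AKT1", "KRT10", "FLG"),
    is_reverse = FALSE, is_contaminant = FALSE,
    is_keratin = c(FALSE, TRUE, FALSE),
    n_theoretical_peptides = c(10L, 5L, 8L)
  )
  list(table = protein_quant(meta, intensity), design = design)
}

write_design_file <- function(design, path = tempfile(fileext = ".tsv")) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}
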