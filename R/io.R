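#' Read a sample-design table
#'
#' The design maps each mass-spectrometry sample label to its donor,
#' condition and technical-run index. It is the pairing backbone of the
#' whole analysis: knockdown/control ratios are formed within donors, and
#' technical replicates are aggregated within (donor, condition).
#'
#' @param path tab-separated file with header columns `sample_label`,
#'   `donor`, `condition`, `tech_rep`. Conditions are parsed
#'   case-insensitively into KD, NT, MOCK or BLANK.
#' @return A tibble with columns `sample_label`, `donor`, `condition`
#'   (factor with levels KD, NT, MOCK, BLANK) and integer `tech_rep`.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  required <- c("sample_label", "donor", "condition", "tech_rep")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("design file is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  validate_design(tibble::tibble(
    sample_label = df$sample_label,
    donor = df$donor,
    condition = df$condition,
    tech_rep = df$tech_rep
  ))
}

#' Validate (and normalise) a sample design
#'
#' @param design data frame with columns `sample_label`, `donor`,
#'   `condition`, `tech_rep`.
#' @return The validated design as a tibble with canonical condition
#'   levels and integer `tech_rep`.
#' @export
validate_design <- function(design) {
  design <- tibble::as_tibble(design)
  if (anyDuplicated(design$sample_label)) {
    dup <- unique(design$sample_label[duplicated(design$sample_label)])
    stop("duplicate sample_label in design: ",
         paste(dup, collapse = ", "))
  }
  cond <- toupper(trimws(as.character(design$condition)))
  known <- c("KD", "NT", "MOCK", "BLANK")
  bad <- which(!cond %in% known)
  if (length(bad) > 0) {
    stop("unknown condition token \"", design$condition[bad[1]],
         "\" on design row ", bad[1],
         " (expected KD, NT, MOCK or BLANK)")
  }
  tech_rep <- suppressWarnings(as.integer(as.character(design$tech_rep)))
  if (any(is.na(tech_rep)) || any(tech_rep < 1)) {
    stop("tech_rep must be an integer >= 1 for every sample")
  }
  out <- tibble::tibble(
    sample_label = as.character(design$sample_label),
    donor = as.character(design$donor),
    condition = factor(cond, levels = known),
    tech_rep = tech_rep
  )
  # tech_rep indices must be contiguous from 1 within (donor, condition)
  grp <- split(out$tech_rep, paste(out$donor, out$condition, sep = "\r"))
  for (g in names(grp)) {
    reps <- sort(grp[[g]])
    if (!identical(reps, seq_along(reps))) {
      stop("tech_rep indices not contiguous from 1 for (donor, condition) = (",
           gsub("\r", ", ", g), ")")
    }
  }
  out
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses the tab-separated proteinGroups dialect: one row per protein
#' group, per-sample quantitation in columns named `"Intensity <label>"`
#' (and optionally `"iBAQ <label>"`), and `"Reverse"` /
#' `"Potential contaminant"` flag columns using `"+"` for true. Missing or
#' empty numeric cells are read as 0, the dialect's encoding of "not
#' detected".
#'
#' @param path path to the tab-separated file.
#' @param design a validated sample design; every non-BLANK
#'   `sample_label` must have a matching intensity column.
#' @param keratin_pattern regular expression applied (case-insensitively)
#'   to gene names to flag keratins for blank subtraction. The default
#'   matches gene symbols "KRT" followed by digits (KRT1, KRT10, ...).
#' @param keratin_genes optional explicit character vector of gene symbols
#'   to flag as keratins instead of the pattern.
#' @return A [protein_quant] object.
#' @export
read_protein_groups <- function(path, design,
                                keratin_pattern = "^KRT[0-9]+$",
                                keratin_genes = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  labels <- as.character(design$sample_label[design$condition != "BLANK"])
  int_cols <- paste("Intensity", labels)
  missing <- labels[!int_cols %in% names(df)]
  if (length(missing) > 0) {
    stop("no Intensity column for design sample label(s): ",
         paste(missing, collapse = ", "))
  }
  id <- column_or(df, c("Protein IDs", "protein_group_id", "Majority protein IDs"))
  if (is.null(id)) stop("no protein group identifier column found ",
                        "(expected \"Protein IDs\")")
  gene <- column_or(df, c("Gene names", "gene_name"))
  if (is.null(gene)) gene <- rep("", nrow(df))
  npep <- column_or(df, c("Number of theoretical peptides",
                          "n_theoretical_peptides"))
  npep <- if (is.null(npep)) rep(0L, nrow(df)) else
    parse_numeric_col(npep, "n_theoretical_peptides", integer = TRUE)

  flag <- function(nm) {
    v <- column_or(df, nm)
    if (is.null(v)) rep(FALSE, nrow(df)) else trimws(v) == "+"
  }
  is_reverse <- flag(c("Reverse", "is_reverse"))
  is_contam <- flag(c("Potential contaminant", "Contaminant", "is_contaminant"))

  first_gene <- toupper(vapply(strsplit(gene, ";", fixed = TRUE),
                               function(g) if (length(g)) trimws(g[[1]]) else "",
                               character(1)))
  is_keratin <- if (!is.null(keratin_genes)) {
    first_gene %in% toupper(keratin_genes)
  } else {
    grepl(keratin_pattern, first_gene, ignore.case = TRUE)
  }

  intensity <- vapply(seq_along(labels), function(j) {
    parse_numeric_col(df[[int_cols[j]]], int_cols[j])
  }, numeric(nrow(df)))
  intensity <- matrix(intensity, nrow = nrow(df),
                      dimnames = list(id, labels))

  ibaq_cols <- paste("iBAQ", labels)
  ibaq <- NULL
  if (all(ibaq_cols %in% names(df))) {
    ibaq <- vapply(seq_along(labels), function(j) {
      parse_numeric_col(df[[ibaq_cols[j]]], ibaq_cols[j])
    }, numeric(nrow(df)))
    ibaq <- matrix(ibaq, nrow = nrow(df), dimnames = list(id, labels))
  }

  protein_quant(
    meta = tibble::tibble(
      protein_group_id = id,
      gene_name = gene,
      is_reverse = is_reverse,
      is_contaminant = is_contam,
      is_keratin = is_keratin,
      n_theoretical_peptides = npep
    ),
    intensity = intensity,
    ibaq = ibaq
  )
}

column_or <- function(df, names) {
  for (nm in names) if (nm %in% colnames(df)) return(df[[nm]])
  NULL
}

parse_numeric_col <- function(x, colname, integer = FALSE) {
  x <- trimws(x)
  x[x == "" | is.na(x) | toupper(x) == "NA" | toupper(x) == "NAN"] <- "0"
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v))) {
    bad <- which(is.na(v))[1]
    stop("non-numeric value \"", x[bad], "\" in column \"", colname,
         "\", row ", bad)
  }
  if (integer) as.integer(round(v)) else v
}

#' Write a protein_quant as a proteinGroups-dialect TSV
#'
#' Inverse of [read_protein_groups()]: writes identifier, gene name, flag
#' ("+" / empty) and per-sample `Intensity`/`iBAQ` columns so that the
#' table round-trips losslessly.
#'
#' @param x a [protein_quant].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_protein_groups <- function(x, path) {
  df <- data.frame(
    `Protein IDs` = x$meta$protein_group_id,
    `Gene names` = x$meta$gene_name,
    Reverse = ifelse(x$meta$is_reverse, "+", ""),
    `Potential contaminant` = ifelse(x$meta$is_contaminant, "+", ""),
    `Number of theoretical peptides` = x$meta$n_theoretical_peptides,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  int <- as.data.frame(x$intensity)
  names(int) <- paste("Intensity", colnames(x$intensity))
  df <- cbind(df, int)
  if (!is.null(x$ibaq)) {
    ib <- as.data.frame(x$ibaq)
    names(ib) <- paste("iBAQ", colnames(x$ibaq))
    df <- cbind(df, ib)
  }
  write_table(df, path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name`, `description`, then member gene symbols. Duplicate members
#' within a line are dropped.
#'
#' @param path path to the GMT file.
#' @return A named list of class `gene_set_collection`; each element is a
#'   character vector of members with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT line ", i, " has fewer than 3 fields")
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      stop("GMT line ", i, " (set \"", fields[1], "\") has no members")
    }
    if (fields[1] %in% names(sets)) {
      stop("duplicate set name \"", fields[1], "\" at GMT line ", i)
    }
    attr(members, "description") <- fields[2]
    sets[[fields[1]]] <- members
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#'
#' @param sets a `gene_set_collection` (named list of member vectors, each
#'   optionally carrying a `description` attribute).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- ""
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a tabular result as TSV
#'
#' Tab-separated, header row, UTF-8, "." decimal separator, no row-name
#' column, `NA` for missing values. Written with enough digits that finite
#' numerics round-trip through [read_table_tsv()] exactly.
#'
#' @param rows a data frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  con <- tryCatch(file(path, open = "wb", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  # format numerics at full precision so write/read is an identity
  fmt <- rows
  for (j in seq_along(fmt)) {
    if (is.numeric(fmt[[j]]) && !is.integer(fmt[[j]])) {
      fmt[[j]] <- vapply(fmt[[j]], function(v) {
        if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = NA)
      }, character(1))
    }
  }
  utils::write.table(fmt, con, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "")
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path input path.
#' @return A tibble; columns are type-converted, `"NA"` cells become `NA`.
#' @export
read_table_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA")
  tibble::as_tibble(df)
}
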