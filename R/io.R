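#' Read a MAF-like mutation table
#'
#' Parses a tab-separated mutation annotation file. Only three columns are
#' consumed — `Hugo_Symbol`, `Tumor_Sample_Barcode`, `Variant_Classification` —
#' and column order is irrelevant; all other columns are ignored. Lines
#' beginning with `#` (e.g. `#version 2.4`) are skipped.
#'
#' @param path Path to a tab-separated MAF-like file.
#' @return A tibble with columns `sample`, `gene`, `variant_classification`,
#'   one row per mutation record. Records whose classification is outside the
#'   recognised MAF vocabulary are retained but flagged in the logical
#'   `known_class` column (a warning summarises them).
#' @export
read_maf <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) format_error(sprintf("MAF file '%s' is empty", path))
  tab <- utils::read.delim(
    text = paste(lines, collapse = "\n"),
    sep = "\t", header = TRUE, check.names = FALSE,
    colClasses = "character", quote = ""
  )
  req <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing <- setdiff(req, names(tab))
  if (length(missing) > 0) {
    format_error(sprintf(
      "MAF file '%s' lacks required column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  out <- tibble(
    sample = trimws(tab$Tumor_Sample_Barcode),
    gene = trimws(tab$Hugo_Symbol),
    variant_classification = trimws(tab$Variant_Classification)
  )
  if (any(!nzchar(out$sample)) || any(!nzchar(out$gene))) {
    format_error("MAF records with empty sample or gene identifiers")
  }
  out$known_class <- out$variant_classification %in% MAF_VOCABULARY
  if (any(!out$known_class)) {
    warn(sprintf(
      "%d MAF record(s) carry variant classifications outside the known vocabulary (e.g. '%s'); retained but flagged",
      sum(!out$known_class), out$variant_classification[!out$known_class][1]
    ))
  }
  out
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' First column holds gene identifiers, remaining columns one sample each.
#' Duplicate gene rows are collapsed by taking the per-sample maximum (a
#' warning reports how many were collapsed).
#'
#' @param path Path to a tab-separated expression file.
#' @return A wide expression tibble: `gene` column plus numeric sample columns.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           na.strings = character(0))
  if (ncol(tab) < 2 || nrow(tab) == 0) {
    format_error(sprintf("expression file '%s' has no data body", path))
  }
  genes <- trimws(tab[[1]])
  body <- as.matrix(tab[-1])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    format_error(sprintf(
      "expression file '%s': non-numeric cell '%s' at row %d, column '%s'",
      path, body[bad[1, 1], bad[1, 2]], bad[1, 1], colnames(body)[bad[1, 2]]
    ))
  }
  if (any(is.na(num))) {
    format_error(sprintf("expression file '%s' contains missing (NA) cells", path))
  }
  colnames(num) <- trimws(colnames(tab)[-1])
  if (anyDuplicated(colnames(num))) {
    format_error(sprintf("expression file '%s' has duplicated sample columns", path))
  }
  if (anyDuplicated(genes)) {
    ndup <- sum(duplicated(genes))
    warn(sprintf("collapsing %d duplicated gene row(s) by per-sample maximum", ndup))
    num <- do.call(rbind, lapply(split(seq_along(genes), genes), function(i) {
      apply(num[i, , drop = FALSE], 2, max)
    }))
    # split() sorts; restore first-appearance order
    first <- genes[!duplicated(genes)]
    num <- num[first, , drop = FALSE]
    genes <- first
  }
  rownames(num) <- genes
  expr_tibble(num)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line — name, description, then member genes,
#' tab-separated. Duplicate members within a line are dropped.
#'
#' @param path Path to a `.gmt` file.
#' @return A long tibble with columns `set`, `description`, `gene`
#'   (one row per set member).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) format_error(sprintf("GMT file '%s' is empty", path))
  rows <- imap(lines, function(line, i) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    if (length(parts) < 3) {
      format_error(sprintf("GMT file '%s': line %d has fewer than 3 fields", path, i))
    }
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      format_error(sprintf("GMT file '%s': line %d defines an empty set", path, i))
    }
    tibble(set = parts[1], description = parts[2], gene = members)
  })
  out <- list_rbind(rows)
  if (anyDuplicated(vapply(rows, function(r) r$set[1], character(1)))) {
    format_error(sprintf("GMT file '%s' has duplicated set names", path))
  }
  out
}

#' Read a clinical table
#'
#' Expects a TSV with a `sample` and `sex` column; recognised optional columns
#' are `age`, `stage`, `os_time`, `os_event`, `response`, `immune_infiltrated`.
#' Sex is matched case-insensitively to male/female; rows with unparseable
#' sample or sex are dropped with a warning. Unparseable optional fields
#' become `NA`.
#'
#' @param path Path to a tab-separated clinical file.
#' @return A tibble with typed columns `sample`, `sex` (factor male/female),
#'   `age`, `stage`, `os_time`, `os_event`, `response`, `immune_infiltrated`.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "")
  names(tab) <- tolower(trimws(names(tab)))
  if (!all(c("sample", "sex") %in% names(tab))) {
    format_error(sprintf("clinical file '%s' lacks 'sample' and/or 'sex' columns", path))
  }
  sample <- trimws(tab$sample)
  sex <- tolower(trimws(tab$sex))
  sex[!sex %in% c("male", "female")] <- NA_character_
  keep <- nzchar(sample) & !is.na(sex)
  if (any(!keep)) {
    warn(sprintf("dropping %d clinical row(s) with missing sample or unrecognised sex", sum(!keep)))
  }
  tab <- tab[keep, , drop = FALSE]
  sample <- sample[keep]
  sex <- sex[keep]
  if (anyDuplicated(sample)) {
    format_error(sprintf("clinical file '%s' has duplicated sample ids", path))
  }
  num_col <- function(name) {
    if (!name %in% names(tab)) return(rep(NA_real_, nrow(tab)))
    suppressWarnings(as.numeric(tab[[name]]))
  }
  chr_col <- function(name) {
    if (!name %in% names(tab)) return(rep(NA_character_, nrow(tab)))
    v <- trimws(tab[[name]])
    v[!nzchar(v)] <- NA_character_
    v
  }
  ev <- num_col("os_event")
  ev[!ev %in% c(0, 1)] <- NA_real_
  resp <- tolower(chr_col("response"))
  resp[!resp %in% c("responder", "nonresponder")] <- NA_character_
  inf <- tolower(chr_col("immune_infiltrated"))
  infl <- inf %in% c("true", "1", "yes")
  infl[is.na(inf)] <- NA
  if (all(is.na(infl))) {
    if ("immune_infiltrated" %in% names(tab)) {
      infl <- rep(NA, nrow(tab))
    } else {
      infl <- rep(TRUE, nrow(tab))
    }
  }
  tibble(
    sample = sample,
    sex = factor(sex, levels = c("male", "female")),
    age = num_col("age"),
    stage = chr_col("stage"),
    os_time = num_col("os_time"),
    os_event = as.integer(ev),
    response = resp,
    immune_infiltrated = infl
  )
}

#' Write package tables back to TSV
#'
#' Writers mirroring the readers, so any in-memory table round-trips exactly.
#'
#' @param x The table to write (wide expression tibble, mutation tibble,
#'   clinical tibble, or long gene-set tibble).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_expression
#' @export
write_maf <- function(x, path) {
  out <- tibble(
    Hugo_Symbol = x$gene,
    Tumor_Sample_Barcode = x$sample,
    Variant_Classification = x$variant_classification
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_expression
#' @export
write_clinical <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_expression
#' @export
write_gmt <- function(x, path) {
  sets <- split(x, factor(x$set, levels = unique(x$set)))
  lines <- vapply(sets, function(s) {
    paste(c(s$set[1], s$description[1], s$gene), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}
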