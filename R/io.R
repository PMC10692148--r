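#' Read a gene-by-sample count matrix from TSV
#'
#' The first column must hold gene identifiers; remaining columns are one
#' sample each, containing non-negative integer counts.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with a `gene_id` character column followed by one integer
#'   column per sample.
#' @export
read_counts_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  validate_counts(x)
  x
}

#' Read a sample sheet from TSV
#'
#' Expects columns `sample_id`, `fraction` (`OL` or `total`), `condition`,
#' and `pair_id`.
#'
#' @param path Path to a tab-separated file.
#' @param conditions Optional ordered condition levels (baseline first). If
#'   `NULL`, levels are taken in order of first appearance.
#' @return A tibble of sample metadata.
#' @export
read_samples_tsv <- function(path, conditions = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("sample_id", "fraction", "condition", "pair_id")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(paste0("sample sheet lacks column(s): ", paste(missing, collapse = ", ")))
  }
  x <- dplyr::mutate(x, dplyr::across(dplyr::all_of(needed), as.character))
  lev <- conditions %||% unique(x$condition)
  x$condition <- factor(x$condition, levels = lev)
  x$fraction <- factor(x$fraction, levels = c("total", "OL"))
  if (anyNA(x$fraction)) abort("fraction must be 'OL' or 'total'")
  x
}

#' Write a count matrix to TSV
#'
#' @param counts Tibble with `gene_id` plus one column per sample.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (set name, description, then member genes,
#'   tab-separated).
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(
    lapply(fields, function(f) unique(f[-(1:2)])),
    vapply(fields, `[[`, character(1), 1)
  )
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("every gene set must be named")
  }
  lines <- vapply(
    names(sets),
    function(nm) paste(c(nm, description, sets[[nm]]), collapse = "\t"),
    character(1)
  )
  writeLines(lines, path)
  invisible(path)
}

## Internal validation of the counts + samples contract -----------------------

validate_counts <- function(counts, samples = NULL) {
  if (!"gene_id" %in% names(counts)) abort("counts must have a gene_id column")
  if (anyDuplicated(counts$gene_id)) abort("duplicate gene ids in counts")
  mat <- counts[setdiff(names(counts), "gene_id")]
  bad <- !vapply(mat, is.numeric, logical(1))
  if (any(bad)) abort("count columns must be numeric")
  m <- as.matrix(mat)
  if (any(m < 0) || any(m != round(m))) abort("counts must be non-negative integers")
  if (!is.null(samples)) {
    if (!setequal(samples$sample_id, colnames(m))) {
      abort("sample sheet and count columns disagree")
    }
    pairing <- dplyr::count(
      dplyr::filter(samples, .data$fraction == "OL"),
      .data$condition, .data$pair_id
    )
    tot <- dplyr::filter(samples, .data$fraction == "total")
    key_ol <- paste(pairing$condition, pairing$pair_id)
    key_tot <- paste(tot$condition, tot$pair_id)
    if (!all(key_ol %in% key_tot)) {
      abort("every OL sample needs a total sample with the same pair_id and condition")
    }
  }
  invisible(counts)
}

counts_matrix <- function(counts) {
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}
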