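#' Read a gene expression matrix from delimited text
#'
#' Reads a TSV or CSV file (dialect auto-detected from the file extension)
#' whose header row holds identifiers and whose first column holds the
#' identifiers of the other axis, and returns the matrix in the canonical
#' genes-in-rows orientation. Values are expected on a CPM (counts per
#' million) or comparable non-negative scale.
#'
#' @param path Path to a delimited text file with a header row; the first
#'   column holds row identifiers.
#' @param orientation Either `"genes_in_rows"` (default; rows are genes,
#'   columns are samples) or `"samples_in_rows"` (the transpose, which is
#'   flipped back so the result is always genes x samples).
#' @return A numeric matrix, genes in rows and samples in columns, with
#'   `rownames` set to gene identifiers and `colnames` to sample identifiers.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g2\t0\t5"), tf)
#' read_expression_matrix(tf)
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_in_rows",
                                                   "samples_in_rows")) {
  orientation <- match.arg(orientation)
  df <- read_delim_auto(path)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  if (orientation == "samples_in_rows") vals <- t(vals)
  validate_expression_matrix(vals, source = path)
  vals
}

read_delim_auto <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

validate_expression_matrix <- function(m, source = "expression matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    abort("expression data must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    abort("expression matrix needs gene rownames and sample colnames")
  if (nrow(m) < 1L || ncol(m) < 2L)
    abort(sprintf("%s: need at least 1 gene and 2 samples", source))
  dup <- rownames(m)[duplicated(rownames(m))]
  if (length(dup) > 0L)
    abort(sprintf("%s: duplicate gene identifier(s): %s",
                  source, paste(unique(dup), collapse = ", ")))
  if (anyDuplicated(colnames(m)))
    abort(sprintf("%s: duplicate sample identifiers", source))
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    abort(sprintf("%s: missing or non-finite value at gene '%s', sample '%s'",
                  source, rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    abort(sprintf("%s: negative value at gene '%s', sample '%s'",
                  source, rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]]))
  invisible(m)
}

#' Min-max normalize an expression matrix to [0, 1]
#'
#' Rescales expression so every value lies in the unit interval, the input
#' scale the gating network expects. The default rescales each gene
#' independently across samples, `out = (x - min) / (max - min)`, so that
#' every non-constant gene attains both 0 and 1 and trained gate weights are
#' comparable across genes. Genes with zero range map to all-zero rows (with
#' a warning): a constant gene carries no class information, and an all-zero
#' input means its gate weight can only decay. A whole-matrix variant is
#' available for comparison via `axis = "global"`.
#'
#' @param m Numeric genes x samples matrix (see [read_expression_matrix()]).
#' @param axis `"gene"` (default) for per-gene scaling, `"global"` to use the
#'   single min and max of the whole matrix.
#' @return A matrix of the same shape and dimnames with values in `[0, 1]`.
#' @examples
#' m <- matrix(c(0, 5, 10, 4, 4, 4), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' suppressWarnings(min_max_normalize(m))
#' @export
min_max_normalize <- function(m, axis = c("gene", "global")) {
  axis <- match.arg(axis)
  validate_expression_matrix(m)
  if (axis == "global") {
    rng <- range(m)
    if (rng[2] == rng[1]) {
      warn("constant matrix: global min-max normalization returns all zeros")
      out <- m * 0
    } else {
      out <- (m - rng[1]) / (rng[2] - rng[1])
    }
    return(out)
  }
  lo <- apply(m, 1L, min)
  hi <- apply(m, 1L, max)
  span <- hi - lo
  constant <- span == 0
  if (any(constant)) {
    warn(sprintf("%d constant gene(s) normalized to all-zero rows", sum(constant)))
    span[constant] <- 1
  }
  out <- (m - lo) / span
  out[constant, ] <- 0
  out
}

#' Read per-sample class labels
#'
#' Reads a two-column delimited file (`sample_id`, `class`). Class names are
#' mapped to 0-based indices in lexicographic order of the distinct names, so
#' one-hot encoding is reproducible; the mapping is recorded in the
#' `class_levels` attribute and as factor levels.
#'
#' @param path Two-column TSV/CSV path.
#' @return A tibble with columns `sample_id`, `class` (factor, levels sorted),
#'   and `class_index` (0-based integer), plus a `class_levels` attribute.
#' @export
read_labels <- function(path) {
  df <- read_delim_auto(path)
  if (ncol(df) < 2L) abort("label file needs two columns: sample_id, class")
  as_label_vector(tibble::tibble(sample_id = as.character(df[[1]]),
                                 class = as.character(df[[2]])))
}

#' Construct a label vector from a data frame
#'
#' @param df Data frame with columns `sample_id` and `class`.
#' @return A tibble as described in [read_labels()].
#' @export
as_label_vector <- function(df) {
  if (!all(c("sample_id", "class") %in% names(df)))
    abort("labels need columns 'sample_id' and 'class'")
  lev <- sort(unique(as.character(df$class)))
  if (length(lev) < 2L)
    abort("labels contain a single class; need at least two")
  cls <- factor(as.character(df$class), levels = lev)
  out <- tibble::tibble(sample_id = as.character(df$sample_id),
                        class = cls,
                        class_index = as.integer(cls) - 1L)
  attr(out, "class_levels") <- lev
  out
}

# Reorder labels to the matrix's column order; error on mismatch.
align_labels <- function(m, labels) {
  if (!setequal(labels$sample_id, colnames(m)))
    abort(paste0("label samples do not match expression matrix samples; ",
                 "missing from labels: ",
                 paste(setdiff(colnames(m), labels$sample_id), collapse = ", ")))
  labels[match(colnames(m), labels$sample_id), , drop = FALSE]
}

#' Write / read a gene ranking table
#'
#' Serializes a final gene ranking (see [final_ranking()]) as TSV with
#' columns `rank`, `gene_id`, `count`, `fraction`; the round trip through
#' [read_ranking()] is lossless. Genes with zero counts are written too.
#'
#' @param r A tibble with columns `rank`, `gene_id`, `count`, `fraction`
#'   (the return type of [final_ranking()]).
#' @param path Output path.
#' @return `r`, invisibly.
#' @export
write_ranking <- function(r, path) {
  stopifnot(all(c("rank", "gene_id", "count", "fraction") %in% names(r)))
  readr::write_tsv(r[, c("rank", "gene_id", "count", "fraction")], path)
  invisible(r)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tibble::tibble(rank = as.integer(df$rank),
                 gene_id = as.character(df$gene_id),
                 count = as.integer(df$count),
                 fraction = as.double(df$fraction))
}

#' Write an expression matrix and labels in the formats this package reads
#'
#' @param m Genes x samples matrix.
#' @param path Output TSV path.
#' @param id_column Name for the gene-identifier column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, id_column = "gene_id") {
  df <- tibble::as_tibble(m, rownames = id_column)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @param labels Label tibble (see [read_labels()]).
#' @rdname write_expression_matrix
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(tibble::tibble(sample_id = labels$sample_id,
                                  class = as.character(labels$class)), path)
  invisible(path)
}
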