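#' Tally top-N appearances over K trial rankings
#'
#' The method's importance statistic: for each gene, the number of training
#' trials in which its gate weight ranked among the `N` largest. Failed
#' trials (`NULL` rankings) are skipped; `K` records the number actually
#' tallied. Every gene is present in the result, zero counts included, and
#' counts conserve `sum(counts) == min(N, k) * K`.
#'
#' @param rankings A `gate_run` (see [run_trials()]) or a plain list of
#'   integer permutations of `1..k`.
#' @param N Top-rank cutoff (>= 1).
#' @param gene_ids Gene identifiers; required when `rankings` is a plain
#'   list.
#' @return An object of class `rank_tally` with `counts` (named integer
#'   vector over all genes), `N`, and `K`.
#' @export
tally_top_n <- function(rankings, N, gene_ids = NULL) {
  N <- as.integer(N)
  if (is.na(N) || N < 1L) abort("N must be >= 1")
  if (inherits(rankings, "gate_run")) {
    gene_ids <- rankings$gene_ids
    rankings <- rankings$rankings
  }
  rankings <- rankings[!vapply(rankings, is.null, logical(1))]
  if (length(rankings) == 0L) abort("no successful trials to tally")
  k <- length(rankings[[1]])
  if (is.null(gene_ids)) gene_ids <- as.character(seq_len(k))
  if (length(gene_ids) != k) abort("gene_ids length does not match rankings")
  counts <- integer(k)
  for (ord in rankings) {
    if (length(ord) != k || !identical(sort(ord), seq_len(k)))
      abort("rankings disagree on the gene set (not permutations of 1..k)")
    top <- ord[seq_len(min(N, k))]
    counts[top] <- counts[top] + 1L
  }
  structure(list(counts = setNames(counts, gene_ids),
                 N = N, K = length(rankings)),
            class = "rank_tally")
}

#' @export
print.rank_tally <- function(x, ...) {
  cat(sprintf("<rank_tally> N = %d over K = %d trials, %d genes\n",
              x$N, x$K, length(x$counts)))
  print(head(final_ranking(x), 5L))
  invisible(x)
}

#' @export
tidy.rank_tally <- function(x, ...) final_ranking(x)

#' @export
glance.rank_tally <- function(x, ...) {
  tibble::tibble(N = x$N, K = x$K, n_genes = length(x$counts),
                 max_count = max(x$counts),
                 total_count = sum(x$counts))
}

#' Final gene ranking from a tally
#'
#' Stable sort by count descending, ties broken lexicographically by gene
#' identifier; a length-`m` truncation is always a prefix of the full
#' ranking.
#'
#' @param t A [tally_top_n()] result.
#' @param m Optional truncation length.
#' @return A tibble with columns `rank`, `gene_id`, `count`, and `fraction`
#'   (`count / K`).
#' @export
final_ranking <- function(t, m = NULL) {
  stopifnot(inherits(t, "rank_tally"))
  ord <- order(-t$counts, names(t$counts), method = "radix")
  out <- tibble::tibble(rank = seq_along(ord),
                        gene_id = names(t$counts)[ord],
                        count = as.integer(unname(t$counts[ord])),
                        fraction = unname(t$counts[ord]) / t$K)
  if (!is.null(m)) out <- out[seq_len(min(m, nrow(out))), , drop = FALSE]
  out
}

#' Frequency table of the most-selected genes
#'
#' The first `top` rows of [final_ranking()] (fewer if the tally has fewer
#' genes), ready for bar-plot rendering via [autoplot.rank_tally()].
#'
#' @inheritParams final_ranking
#' @param top Number of rows to keep (default 25).
#' @return A tibble with columns `gene_id`, `count`, `fraction`.
#' @export
frequency_table <- function(t, top = 25L) {
  final_ranking(t, m = top)[, c("gene_id", "count", "fraction")]
}

#' Side-by-side tally table for several N
#'
#' Computes tallies for each `N` in one pass over the same trial rankings
#' (the study reports N = 10 and N = 50 together) and joins them into a
#' wide table, ordered by the first N's ranking.
#'
#' @param run A `gate_run` or list of rankings.
#' @param N Integer vector of top-rank cutoffs.
#' @param gene_ids Gene identifiers when `run` is a plain list.
#' @return A tibble with `gene_id`, one `count_N<...>` column per cutoff,
#'   and `K`.
#' @export
tally_table <- function(run, N = c(10L, 50L), gene_ids = NULL) {
  tallies <- lapply(N, function(n) tally_top_n(run, n, gene_ids = gene_ids))
  out <- final_ranking(tallies[[1]])[, "gene_id"]
  for (i in seq_along(N)) {
    out[[sprintf("count_N%d", N[i])]] <-
      as.integer(tallies[[i]]$counts[out$gene_id])
  }
  out$K <- tallies[[1]]$K
  out
}

#' Bar plot of top-N selection counts
#'
#' @param object A [tally_top_n()] result.
#' @param top Number of genes to show (default 25).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rank_tally <- function(object, top = 25L, ...) {
  ft <- frequency_table(object, top = top)
  ft$gene_id <- factor(ft$gene_id, levels = rev(ft$gene_id))
  ggplot2::ggplot(ft, ggplot2::aes(x = .data$count, y = .data$gene_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = sprintf("trials ranked in top %d (of %d)", object$N, object$K),
      y = NULL,
      title = sprintf("Top-%d selection counts, N = %d, K = %d",
                      min(top, length(object$counts)), object$N, object$K)) +
    ggplot2::theme_minimal()
}

#' End-to-end gene selection
#'
#' Convenience pipeline: min-max normalize, run `K` seeded training trials,
#' and tally top-`N` membership for each requested `N`.
#'
#' @param expr Genes x samples matrix of non-negative CPM-scale values.
#' @param labels Label tibble (see [read_labels()] / [as_label_vector()]).
#' @param K Number of trials.
#' @param N Integer vector of top-rank cutoffs.
#' @param base_seed First trial seed.
#' @param spec Optional [model_spec()] (defaults to the study architecture).
#' @param train_cfg A [train_config()].
#' @param verbose Print trial progress.
#' @return An object of class `gene_selection` with the `run`, the named
#'   list of `tallies`, and the wide `table` (see [tally_table()]).
#' @export
gene_select <- function(expr, labels, K = 1000L, N = c(10L, 50L),
                        base_seed = 0L, spec = NULL,
                        train_cfg = train_config(), verbose = FALSE) {
  norm <- suppressWarnings(min_max_normalize(expr))
  run <- run_trials(norm, labels, spec = spec, train_cfg = train_cfg,
                    K = K, base_seed = base_seed, verbose = verbose)
  tallies <- setNames(lapply(N, function(n) tally_top_n(run, n)),
                      sprintf("N%d", N))
  structure(list(run = run, tallies = tallies,
                 table = tally_table(run, N = N)),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  print(x$run)
  cat("Top genes:\n")
  print(head(x$table, 10L))
  invisible(x)
}

#' @export
tidy.gene_selection <- function(x, ...) x$table

#' @export
glance.gene_selection <- function(x, ...) glance(x$run)
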