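#' Training configuration
#'
#' Optimizer and schedule settings for one training trial. The study design
#' trains on all samples (cohorts of a dozen samples leave nothing to hold
#' out), full batch, for a fixed number of epochs; the optimizer is Adam.
#'
#' @param epochs Number of full-batch epochs.
#' @param learning_rate Adam step size.
#' @param beta1,beta2,adam_eps Adam moment decays and stabilizer.
#' @param prob_floor Probability floor inside the cross-entropy.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, learning_rate = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         prob_floor = 1e-12) {
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) abort("epochs must be >= 1")
  if (learning_rate <= 0) abort("learning_rate must be positive")
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 prob_floor = prob_floor),
            class = "train_config")
}

# One-hot matrix (n x C) from an aligned label tibble.
one_hot <- function(labels, n_classes) {
  Y <- matrix(0, nrow(labels), n_classes)
  Y[cbind(seq_len(nrow(labels)), labels$class_index + 1L)] <- 1
  Y
}

#' Train one seeded trial of the gating-layer classifier
#'
#' Trains on all samples (no held-out split) and reads out the gating-layer
#' weights at the final epoch. The seed covers weight initialization and the
#' per-epoch dropout masks, so the trial is fully deterministic given
#' `(data, labels, spec, train_cfg, seed)`.
#'
#' @param data Genes x samples matrix of min-max normalized values
#'   (see [min_max_normalize()]).
#' @param labels Label tibble (see [read_labels()]); samples must match the
#'   matrix columns as a set.
#' @param spec A [model_spec()]; defaults to the study architecture with
#'   `k_features` taken from `data`.
#' @param train_cfg A [train_config()].
#' @param seed Integer RNG seed.
#' @param trial_index Index recorded in the result (0-based).
#' @return An object of class `gate_trial` with elements `weights` (named,
#'   non-negative, one per gene), `final_loss`, `final_accuracy`, `seed`,
#'   `trial_index`, `failed`, and the trained `model`.
#' @export
train_trial <- function(data, labels, spec = NULL, train_cfg = train_config(),
                        seed = 0L, trial_index = 0L) {
  validate_normalized(data)
  labels <- align_labels(data, labels)
  n_classes <- length(attr(labels, "class_levels"))
  if (is.null(spec)) spec <- model_spec(k_features = nrow(data),
                                        n_classes = n_classes)
  if (spec$k_features != nrow(data))
    abort("spec$k_features does not match the number of genes in data")
  X <- t(data)                       # samples x genes
  Y <- one_hot(labels, spec$n_classes)

  set.seed(as.integer(seed))
  model <- build_model(spec)
  fit <- cpp_train_gate_mlp(X, Y, model$gate, model$W, model$b,
                            spec$dropout_rate, train_cfg$epochs,
                            train_cfg$learning_rate, train_cfg$beta1,
                            train_cfg$beta2, train_cfg$adam_eps,
                            train_cfg$prob_floor)
  model$gate <- as.numeric(fit$gate)
  model$W <- fit$W
  model$b <- lapply(fit$b, as.numeric)

  structure(list(weights = setNames(as.numeric(fit$gate), rownames(data)),
                 final_loss = fit$final_loss,
                 final_accuracy = fit$final_accuracy,
                 seed = as.integer(seed),
                 trial_index = as.integer(trial_index),
                 failed = isTRUE(fit$failed) || !is.finite(fit$final_loss),
                 model = model),
            class = "gate_trial")
}

validate_normalized <- function(data) {
  if (!is.matrix(data) || !is.numeric(data))
    abort("data must be a numeric genes x samples matrix")
  if (is.null(rownames(data))) abort("data needs gene rownames")
  rng <- range(data)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
    abort("data must be min-max normalized to [0, 1]; see min_max_normalize()")
  invisible(data)
}

#' @export
print.gate_trial <- function(x, ...) {
  cat(sprintf("<gate_trial %d> seed %d, loss %.4g, accuracy %.3f%s\n",
              x$trial_index, x$seed, x$final_loss, x$final_accuracy,
              if (x$failed) " [FAILED]" else ""))
  invisible(x)
}

#' @export
tidy.gate_trial <- function(x, ...) {
  tibble::tibble(gene_id = names(x$weights),
                 weight = unname(x$weights),
                 rank = rank_of(rank_genes_by_weight(x$weights)))
}

#' @export
glance.gate_trial <- function(x, ...) {
  tibble::tibble(trial_index = x$trial_index, seed = x$seed,
                 final_loss = x$final_loss,
                 final_accuracy = x$final_accuracy, failed = x$failed)
}

#' Rank genes by descending gate weight
#'
#' The per-trial ranking: a permutation of gene indices in descending weight
#' order, ties broken by ascending gene index (a stable sort).
#'
#' @param w Numeric gate-weight vector (names optional).
#' @return Integer permutation of `seq_along(w)`; the first element is the
#'   index of the largest weight.
#' @examples
#' rank_genes_by_weight(c(0.1, 0.9, 0.5))  # 2 3 1
#' @export
rank_genes_by_weight <- function(w) {
  if (any(!is.finite(w))) abort("gate weights must be finite")
  order(-w, seq_along(w))
}

# Inverse permutation: rank position (1-based) of each gene.
rank_of <- function(ord) {
  inv <- integer(length(ord))
  inv[ord] <- seq_along(ord)
  inv
}

#' Run K independently seeded training trials
#'
#' Attempts exactly `K` trials with seeds `base_seed, base_seed + 1, ...,
#' base_seed + K - 1` (the schedule covers weight initialization and dropout
#' masks and makes interrupted runs resumable). Each trial's gate weights are
#' converted to a descending-weight gene ranking. Trials whose loss turns
#' non-finite are marked failed, excluded from downstream tallies, and
#' counted in the run metadata.
#'
#' @inheritParams train_trial
#' @param K Number of trials (>= 1).
#' @param base_seed First seed of the schedule.
#' @param checkpoint_dir Optional directory; completed trial rankings are
#'   written there and a `checkpoint.tsv` manifest allows a later call with
#'   the same arguments to resume instead of recomputing.
#' @param verbose Print progress every 10 trials.
#' @return An object of class `gate_run`: `rankings` (list of integer
#'   permutations, failed trials `NULL`), `gene_ids`, `trials` (metadata
#'   tibble), `K`, `base_seed`, `n_failed`.
#' @export
run_trials <- function(data, labels, spec = NULL, train_cfg = train_config(),
                       K = 1000L, base_seed = 0L, checkpoint_dir = NULL,
                       verbose = FALSE) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) abort("K must be >= 1")
  gene_ids <- rownames(data)
  rankings <- vector("list", K)
  meta <- vector("list", K)

  manifest_path <- NULL
  done <- integer(0)
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
    manifest_path <- file.path(checkpoint_dir, "checkpoint.tsv")
    if (file.exists(manifest_path)) {
      man <- readr::read_tsv(manifest_path, show_col_types = FALSE,
                             progress = FALSE)
      for (i in seq_len(nrow(man))) {
        ti <- man$trial_index[i] + 1L
        if (ti >= 1L && ti <= K && file.exists(man$file[i])) {
          rk <- read_ranking(man$file[i])
          rankings[[ti]] <- match(rk$gene_id, gene_ids)
          meta[[ti]] <- tibble::tibble(trial_index = man$trial_index[i],
                                       seed = man$seed[i],
                                       final_loss = man$final_loss[i],
                                       final_accuracy = man$final_accuracy[i],
                                       failed = FALSE)
          done <- c(done, ti)
        }
      }
    }
  }

  for (i in seq_len(K)) {
    if (i %in% done) next
    seed <- as.integer(base_seed) + i - 1L
    tr <- train_trial(data, labels, spec = spec, train_cfg = train_cfg,
                      seed = seed, trial_index = i - 1L)
    meta[[i]] <- glance(tr)
    if (!tr$failed) {
      ord <- rank_genes_by_weight(tr$weights)
      rankings[[i]] <- ord
      if (!is.null(manifest_path)) {
        f <- file.path(checkpoint_dir, sprintf("trial_%05d.tsv", i - 1L))
        write_ranking(tibble::tibble(rank = seq_along(ord),
                                     gene_id = gene_ids[ord],
                                     count = NA_integer_,
                                     fraction = NA_real_), f)
        line <- tibble::tibble(trial_index = i - 1L, seed = seed,
                               final_loss = tr$final_loss,
                               final_accuracy = tr$final_accuracy, file = f)
        readr::write_tsv(line, manifest_path,
                         append = file.exists(manifest_path))
      }
    }
    if (verbose && (i %% 10L == 0L || i == K))
      message(sprintf("trial %d/%d (loss %.4g, acc %.3f)",
                      i, K, tr$final_loss, tr$final_accuracy))
  }

  trials <- dplyr::bind_rows(meta)
  n_failed <- sum(trials$failed)
  if (n_failed == K) abort("all trials failed (non-finite training loss)")
  structure(list(rankings = rankings, gene_ids = gene_ids, trials = trials,
                 K = K, base_seed = as.integer(base_seed),
                 n_failed = n_failed),
            class = "gate_run")
}

#' @export
print.gate_run <- function(x, ...) {
  cat(sprintf("<gate_run> %d trials over %d genes (%d failed), seeds %d..%d\n",
              x$K, length(x$gene_ids), x$n_failed,
              x$base_seed, x$base_seed + x$K - 1L))
  invisible(x)
}

#' @export
tidy.gate_run <- function(x, ...) {
  ok <- which(!vapply(x$rankings, is.null, logical(1)))
  dplyr::bind_rows(lapply(ok, function(i) {
    tibble::tibble(trial_index = i - 1L,
                   rank = seq_along(x$rankings[[i]]),
                   gene_id = x$gene_ids[x$rankings[[i]]])
  }))
}

#' @export
glance.gate_run <- function(x, ...) {
  tibble::tibble(K = x$K, n_genes = length(x$gene_ids),
                 n_failed = x$n_failed, base_seed = x$base_seed,
                 mean_final_loss = mean(x$trials$final_loss[!x$trials$failed]),
                 mean_final_accuracy =
                   mean(x$trials$final_accuracy[!x$trials$failed]))
}
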