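#' Generate a CPM-scale expression matrix with planted informative genes
#'
#' Emulates a small-cohort bulk RNA-seq experiment on the scale the gating
#' method targets: tens of samples, thousands of genes, counts-per-million
#' values. Per gene `g`, log-expression is Normal(`mu_g`, `log_sd`) with
#' `mu_g` drawn uniformly from `baseline_log_mean_range`; the
#' `m_informative` planted genes shift their class-1 mean by
#' `effect_delta * log_sd` on the log scale, with the sign of the shift
#' alternating gene to gene (both up- and down-regulation). Values are
#' exponentiated, so the matrix is strictly positive.
#'
#' @param k_genes Number of genes.
#' @param n_per_class Length-2 integer vector: samples in class 0 and class 1.
#' @param m_informative Number of planted class-informative genes (<= k).
#' @param effect_delta Class mean shift in within-gene SD units on the log
#'   scale; 0 plants nothing.
#' @param baseline_log_mean_range Range for per-gene baseline log means.
#' @param log_sd Within-gene log-scale standard deviation.
#' @param seed Integer seed; the output is a deterministic function of the
#'   arguments.
#' @param class_names Names for classes 0 and 1 (lexicographic order should
#'   match the index order for reproducible one-hot encoding).
#' @return A list with `expression` (genes x samples matrix), `labels`
#'   (tibble, see [as_label_vector()]), and `truth` (character vector of
#'   planted gene ids, with a `sign` attribute of per-gene shift directions).
#' @examples
#' sim <- generate_expression(k_genes = 50, n_per_class = c(5, 5),
#'                            m_informative = 3, effect_delta = 2, seed = 1)
#' dim(sim$expression)
#' sim$truth
#' @export
generate_expression <- function(k_genes, n_per_class, m_informative = 0L,
                                effect_delta = 0,
                                baseline_log_mean_range = c(2, 10),
                                log_sd = 1, seed = 0L,
                                class_names = c("classA", "classB")) {
  k_genes <- as.integer(k_genes)
  n_per_class <- as.integer(n_per_class)
  m_informative <- as.integer(m_informative)
  if (length(n_per_class) != 2L || any(n_per_class < 1L))
    abort("n_per_class must be two positive integers")
  if (m_informative < 0L || m_informative > k_genes)
    abort("m_informative must lie in [0, k_genes]")
  if (effect_delta < 0) abort("effect_delta must be >= 0")
  if (log_sd <= 0) abort("log_sd must be positive")

  set.seed(as.integer(seed))
  n <- sum(n_per_class)
  cls <- rep(0:1, times = n_per_class)
  gene_ids <- sprintf("gene_%04d", seq_len(k_genes))
  sample_ids <- sprintf("sample_%02d", seq_len(n))

  mu <- runif(k_genes, baseline_log_mean_range[1], baseline_log_mean_range[2])
  logx <- matrix(rnorm(k_genes * n, sd = log_sd), k_genes, n) + mu

  truth <- character(0)
  signs <- integer(0)
  if (m_informative > 0L) {
    idx <- sample.int(k_genes, m_informative)
    signs <- rep_len(c(1L, -1L), m_informative)
    shift <- effect_delta * log_sd * signs
    logx[idx, cls == 1L] <- logx[idx, cls == 1L] + shift
    truth <- gene_ids[idx]
  }

  expr <- exp(logx)
  dimnames(expr) <- list(gene_ids, sample_ids)
  labels <- as_label_vector(tibble::tibble(
    sample_id = sample_ids, class = class_names[cls + 1L]))
  attr(truth, "sign") <- signs
  list(expression = expr, labels = labels, truth = truth)
}

#' Study-emulation presets
#'
#' Named presets that reproduce the cohort geometry of the motivating study:
#' `"task1"` is tumor-versus-normal tissue with 12 samples (6 per class) and
#' `"task2"` is better-versus-worse prognosis with 13 samples (6 + 7), both
#' over 11,273 genes.
#'
#' @param task `"task1"` or `"task2"`.
#' @param ... Overrides passed on to [generate_expression()]
#'   (`m_informative`, `effect_delta`, `seed`, ...).
#' @return See [generate_expression()].
#' @export
generate_expression_preset <- function(task = c("task1", "task2"), ...) {
  task <- match.arg(task)
  args <- switch(task,
    task1 = list(k_genes = 11273L, n_per_class = c(6L, 6L),
                 class_names = c("normal", "tumor")),
    task2 = list(k_genes = 11273L, n_per_class = c(6L, 7L),
                 class_names = c("better", "worse")))
  do.call(generate_expression, utils::modifyList(args, list(...)))
}

#' Generate a survival cohort with an expression-threshold hazard
#'
#' Emulates a validation cohort in which a single gene's expression drives
#' hazard through a threshold: event times are exponential with rate
#' `baseline_hazard * hazard_ratio^[x > true_cutpoint]`, and censoring times
#' are uniform on `(0, censoring_horizon]` (an administrative-censoring
#' model). The observed time is the smaller of the two.
#'
#' @param n_subjects Cohort size.
#' @param true_cutpoint Expression threshold at which hazard switches.
#' @param hazard_ratio Hazard multiplier above the threshold (> 0).
#' @param baseline_hazard Event rate per day below the threshold (> 0).
#' @param censoring_horizon Upper bound of the uniform censoring time, days.
#' @param seed Integer seed.
#' @param expression Optional vector of per-subject expression values; drawn
#'   log-normally (meanlog 0, sdlog 1 around the cutpoint's scale) when
#'   omitted.
#' @return A tibble with columns `subject_id`, `time` (days, > 0), `event`
#'   (1 = event, 0 = censored), `expression`.
#' @export
generate_survival <- function(n_subjects, true_cutpoint = 1,
                              hazard_ratio = 2, baseline_hazard = 1 / 500,
                              censoring_horizon = 2000, seed = 0L,
                              expression = NULL) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) abort("n_subjects must be >= 1")
  if (hazard_ratio <= 0) abort("hazard_ratio must be > 0")
  if (baseline_hazard <= 0) abort("baseline_hazard must be > 0")
  if (censoring_horizon <= 0) abort("censoring_horizon must be > 0")

  set.seed(as.integer(seed))
  if (is.null(expression)) {
    expression <- true_cutpoint * exp(rnorm(n_subjects))
  } else if (length(expression) != n_subjects) {
    abort("expression must have one value per subject")
  }
  rate <- baseline_hazard * hazard_ratio^(expression > true_cutpoint)
  t_event <- rexp(n_subjects, rate = rate)
  t_cens <- runif(n_subjects, 0, censoring_horizon)
  tibble::tibble(subject_id = sprintf("subj_%04d", seq_len(n_subjects)),
                 time = pmin(t_event, t_cens),
                 event = as.integer(t_event <= t_cens),
                 expression = as.double(expression))
}
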