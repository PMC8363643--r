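# Independent oracles and small fixture builders shared across test files.

# Brute-force unweighted log-rank: sum O - E and hypergeometric V over the
# distinct event times, independent of survival::survdiff.
logrank_oracle <- function(groupA, groupB) {
  all_t <- c(groupA$time, groupB$time)
  all_e <- c(groupA$event, groupB$event)
  in_a <- c(rep(TRUE, nrow(groupA)), rep(FALSE, nrow(groupB)))
  ts <- sort(unique(all_t[all_e == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at_risk <- all_t >= t
    n1 <- sum(at_risk & in_a)
    n <- sum(at_risk)
    d1 <- sum(all_t == t & all_e == 1 & in_a)
    d <- sum(all_t == t & all_e == 1)
    O1 <- O1 + d1
    E1 <- E1 + n1 * d / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- (O1 - E1)^2 / V
  list(chi_square = chi,
       p_value = stats::pchisq(chi, 1, lower.tail = FALSE))
}

# Hand-rolled product-limit estimator evaluated at the sorted event times.
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  data.frame(time = ts, estimate = out)
}

# Random small survival cohort; resamples until the log-rank variance is
# positive so chi-square is well defined.
random_cohort_pair <- function(n_max = 12L) {
  repeat {
    nA <- sample(2:n_max, 1)
    nB <- sample(2:n_max, 1)
    A <- data.frame(time = round(stats::rexp(nA, 1 / 100) + 1),
                    event = stats::rbinom(nA, 1, 0.7))
    B <- data.frame(time = round(stats::rexp(nB, 1 / 100) + 1),
                    event = stats::rbinom(nB, 1, 0.7))
    if (sum(A$event) + sum(B$event) < 1) next
    or <- logrank_oracle(A, B)
    if (is.finite(or$chi_square)) return(list(A = A, B = B, oracle = or))
  }
}

# Small normalized classification fixture used by the trial-engine tests.
tiny_task <- function(k = 60L, n_per_class = c(5L, 5L), m = 4L,
                      delta = 2, seed = 3L) {
  sim <- generate_expression(k_genes = k, n_per_class = n_per_class,
                             m_informative = m, effect_delta = delta,
                             seed = seed)
  norm <- suppressWarnings(min_max_normalize(sim$expression))
  list(norm = norm, labels = sim$labels, truth = sim$truth)
}

# Fast training configuration for tests where only the mechanics matter.
fast_cfg <- function(epochs = 30L) train_config(epochs = epochs)

# Double-loop top-N recount, independent of tally_top_n's increments.
recount_oracle <- function(rankings, N) {
  k <- length(rankings[[1]])
  counts <- integer(k)
  for (g in seq_len(k)) {
    for (ord in rankings) {
      if (match(g, ord) <= min(N, k)) counts[g] <- counts[g] + 1L
    }
  }
  counts
}
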