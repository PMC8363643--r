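#' Validate a survival cohort table
#'
#' A cohort is a data frame with columns `time` (days, positive and finite)
#' and `event` (1 = event observed, 0 = right-censored), optionally
#' `subject_id` and `expression` (required for cutpoint scanning).
#'
#' @param cohort Data frame.
#' @param need_expression Require the `expression` column.
#' @return The cohort as a tibble, invisibly usable downstream.
#' @export
validate_cohort <- function(cohort, need_expression = FALSE) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    abort("cohort must be a non-empty data frame")
  need <- c("time", "event", if (need_expression) "expression")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0L)
    abort(sprintf("cohort is missing column(s): %s", paste(miss, collapse = ", ")))
  if (any(!is.finite(cohort$time)) || any(cohort$time <= 0))
    abort("cohort times must be positive and finite")
  if (!all(cohort$event %in% c(0, 1)))
    abort("cohort event indicator must be 0 or 1")
  if (need_expression && any(!is.finite(cohort$expression)))
    abort("cohort expression values must be finite")
  tibble::as_tibble(cohort)
}

#' Read a survival cohort from delimited text
#'
#' Expects columns `subject_id`, `time_days` (or `time`), `event`, and
#' optionally `expression`.
#'
#' @param path TSV/CSV path.
#' @return A validated cohort tibble.
#' @export
read_survival_cohort <- function(path) {
  df <- read_delim_auto(path)
  if ("time_days" %in% names(df) && !"time" %in% names(df))
    names(df)[names(df) == "time_days"] <- "time"
  validate_cohort(df)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function: right-continuous,
#' non-increasing, with `S(0) = 1`; censored subjects leave the risk set
#' without producing a step.
#'
#' @param cohort A survival cohort (see [validate_cohort()]).
#' @return A tibble with one row per observed time: `time`, `n_risk`,
#'   `n_event`, `n_censor`, `estimate` (the survival probability just after
#'   `time`).
#' @examples
#' km_estimate(data.frame(time = c(1, 2, 3, 4, 5),
#'                        event = c(1, 0, 1, 1, 0)))
#' @export
km_estimate <- function(cohort) {
  cohort <- validate_cohort(cohort)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = cohort)
  tibble::tibble(time = fit$time,
                 n_risk = as.integer(fit$n.risk),
                 n_event = as.integer(fit$n.event),
                 n_censor = as.integer(fit$n.censor),
                 estimate = fit$surv)
}

#' Two-group log-rank test
#'
#' Unweighted (Mantel-Haenszel) log-rank statistic comparing the survival
#' experience of two cohorts, with the standard hypergeometric variance at
#' tied event times; the statistic is chi-square with 1 degree of freedom.
#'
#' @param groupA,groupB Survival cohorts (see [validate_cohort()]).
#' @return A one-row tibble with `chi_square`, `p_value`, `n_A`, `n_B`,
#'   `events_A`, `events_B`.
#' @export
logrank_test <- function(groupA, groupB) {
  groupA <- validate_cohort(groupA)
  groupB <- validate_cohort(groupB)
  if (sum(groupA$event) + sum(groupB$event) < 1)
    abort("log-rank test needs at least one event overall")
  df <- rbind(
    data.frame(time = groupA$time, event = groupA$event, grp = 0L),
    data.frame(time = groupB$time, event = groupB$event, grp = 1L))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df,
                           rho = 0)
  chi <- unname(sd$chisq)
  tibble::tibble(chi_square = chi,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 n_A = nrow(groupA), n_B = nrow(groupB),
                 events_A = sum(groupA$event), events_B = sum(groupB$event))
}

#' Exhaustive best-cutpoint scan of a gene's expression
#'
#' Scans every admissible threshold of the cohort's `expression` column —
#' candidates are the midpoints between consecutive distinct sorted values —
#' splits subjects into low (`x <= c`) and high (`x > c`) groups, and keeps
#' the split minimizing the log-rank p-value. Only splits with both group
#' sizes at least `min_group` are tested. Because scanning for the minimum p
#' inflates the type-I error, a Bonferroni-adjusted value over the number of
#' tested cutpoints is reported alongside the raw minimum.
#'
#' @param cohort Cohort with an `expression` column.
#' @param min_group Minimum subjects per arm (default 8).
#' @return An object of class `cutpoint_scan`: `best_cutpoint`,
#'   `chi_square`, `p_raw`, `p_adjusted`, `n_cutpoints_tested`,
#'   `group_sizes`, and `scan` (a tibble of every tested cutpoint with its
#'   statistic and p-value).
#' @export
scan_best_cutpoint <- function(cohort, min_group = 8L) {
  cohort <- validate_cohort(cohort, need_expression = TRUE)
  min_group <- as.integer(min_group)
  if (min_group < 1L) abort("min_group must be >= 1")
  if (nrow(cohort) < 2L * min_group)
    abort("cohort smaller than 2 * min_group")
  ux <- sort(unique(cohort$expression))
  if (length(ux) < 2L) abort("expression values are all identical")
  cand <- (ux[-1] + ux[-length(ux)]) / 2

  rows <- lapply(cand, function(cp) {
    lo <- cohort[cohort$expression <= cp, , drop = FALSE]
    hi <- cohort[cohort$expression > cp, , drop = FALSE]
    if (nrow(lo) < min_group || nrow(hi) < min_group) return(NULL)
    if (sum(lo$event) + sum(hi$event) < 1) return(NULL)
    lr <- logrank_test(lo, hi)
    tibble::tibble(cutpoint = cp, chi_square = lr$chi_square,
                   p_value = lr$p_value,
                   n_low = nrow(lo), n_high = nrow(hi))
  })
  scan <- dplyr::bind_rows(rows)
  if (nrow(scan) == 0L)
    abort("no admissible cutpoint (group-size constraint too strict)")
  best <- which.min(scan$p_value)
  structure(list(best_cutpoint = scan$cutpoint[best],
                 chi_square = scan$chi_square[best],
                 p_raw = scan$p_value[best],
                 p_adjusted = min(1, scan$p_value[best] * nrow(scan)),
                 n_cutpoints_tested = nrow(scan),
                 group_sizes = c(low = scan$n_low[best],
                                 high = scan$n_high[best]),
                 min_group = min_group,
                 scan = scan,
                 cohort = cohort),
            class = "cutpoint_scan")
}

#' @export
print.cutpoint_scan <- function(x, ...) {
  cat(sprintf(paste0("<cutpoint_scan> best cutpoint %.4g ",
                     "(groups %d low / %d high)\n"),
              x$best_cutpoint, x$group_sizes[["low"]], x$group_sizes[["high"]]))
  cat(sprintf("  log-rank chi-square %.4g, raw p %.3g, Bonferroni p %.3g over %d cutpoints\n",
              x$chi_square, x$p_raw, x$p_adjusted, x$n_cutpoints_tested))
  invisible(x)
}

#' @export
tidy.cutpoint_scan <- function(x, ...) x$scan

#' @export
glance.cutpoint_scan <- function(x, ...) {
  tibble::tibble(best_cutpoint = x$best_cutpoint,
                 chi_square = x$chi_square,
                 p_raw = x$p_raw,
                 p_adjusted = x$p_adjusted,
                 n_cutpoints_tested = x$n_cutpoints_tested,
                 n_low = x$group_sizes[["low"]],
                 n_high = x$group_sizes[["high"]])
}

#' Kaplan-Meier plot of the best split found by a cutpoint scan
#'
#' @param object A [scan_best_cutpoint()] result.
#' @param ... Unused.
#' @return A ggplot object with one survival step curve per group.
#' @export
autoplot.cutpoint_scan <- function(object, ...) {
  co <- object$cohort
  lo <- km_estimate(co[co$expression <= object$best_cutpoint, ])
  hi <- km_estimate(co[co$expression > object$best_cutpoint, ])
  km <- dplyr::bind_rows(
    tibble::tibble(time = c(0, lo$time), estimate = c(1, lo$estimate),
                   group = "low expression"),
    tibble::tibble(time = c(0, hi$time), estimate = c(1, hi$estimate),
                   group = "high expression"))
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$estimate,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability",
                  colour = NULL,
                  subtitle = sprintf("cutpoint %.4g, log-rank p = %.3g (adjusted %.3g)",
                                     object$best_cutpoint, object$p_raw,
                                     object$p_adjusted)) +
    ggplot2::theme_minimal()
}
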