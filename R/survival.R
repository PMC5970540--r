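#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the
#' distinct event times of each group, via [survival::survfit()]. Subjects
#' censored at an event time remain in the risk set for that time (the
#' standard convention).
#'
#' @param records Data frame with columns `sample_id`, `time` (>= 0) and
#'   `event` (1 = event observed, 0 = censored).
#' @param groups Named vector: group per sample id; every group needs at
#'   least one record.
#' @return Data frame with columns group, time, n_risk, n_event, survival
#'   (one row per distinct observed time per group).
#' @export
km_estimate <- function(records, groups) {
  stopifnot(all(c("sample_id", "time", "event") %in% names(records)))
  g <- groups[records$sample_id]
  if (anyNA(g)) stop("group missing for some survival records")
  present <- unique(as.character(g))
  empty <- setdiff(unique(as.character(groups)), present)
  if (length(empty) > 0)
    stop("group(s) with no survival records: ", paste(empty, collapse = ", "))
  g <- factor(as.character(g))
  fit <- survival::survfit(survival::Surv(records$time, records$event) ~ g)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(g)[1], length(sm$time))
         else sub("^g=", "", as.character(sm$strata))
  data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
             n_event = sm$n.event, survival = sm$surv,
             stringsAsFactors = FALSE)
}

#' Multi-group log-rank test
#'
#' Observed-versus-expected event counts with hypergeometric variance at
#' each distinct event time, summed into a chi-square statistic on
#' `groups - 1` degrees of freedom, via [survival::survdiff()].
#'
#' @inheritParams km_estimate
#' @return Object of class `logrank_result`: list with `chi_square`, `df`,
#'   `p_value`, `n` (per-group sizes), `observed` and `expected`.
#' @export
logrank_test <- function(records, groups) {
  stopifnot(all(c("sample_id", "time", "event") %in% names(records)))
  g <- factor(as.character(groups[records$sample_id]))
  if (anyNA(groups[records$sample_id]))
    stop("group missing for some survival records")
  if (nlevels(g) < 2) stop("log-rank test requires at least 2 groups")
  if (sum(records$event) == 0) stop("log-rank test requires at least 1 event")
  sd <- survival::survdiff(survival::Surv(records$time, records$event) ~ g)
  df <- nlevels(g) - 1L
  structure(list(chi_square = unname(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 n = sd$n, observed = sd$obs, expected = sd$exp),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}
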