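# Stage-3 engine: Kaplan-Meier product-limit estimation and the
# Gehan-Breslow (generalized Wilcoxon) two-group test, both written from
# their defining formulas. The survival package is used only as an
# independent cross-check in the test suite, never here.

#' Kaplan-Meier product-limit estimate for one group
#'
#' S(t_j) = prod_{i <= j} (1 - d_i / n_i) over the ordered distinct event
#' times, with the Greenwood variance
#' S(t)^2 sum d_i / (n_i (n_i - d_i)). At tied times, events are processed
#' before censorings (a subject censored at t is still at risk for an event
#' at t).
#'
#' @param records Tibble with `time` (non-negative) and `event` (logical)
#'   columns, one row per subject.
#' @return An object of class `km_curve`: a tibble with one row per distinct
#'   event time (`time`, `n_risk`, `n_event`, `surv`, `std_err` via
#'   Greenwood), plus attributes `n` and `n_events`.
#' @examples
#' km_estimate(tibble::tibble(time = c(1, 2, 3), event = c(TRUE, TRUE, FALSE)))
#' @export
km_estimate <- function(records) {
  if (nrow(records) == 0) abort("no survival records")
  if (any(records$time < 0)) abort("negative survival time")
  event_times <- sort(unique(records$time[records$event]))
  n_risk <- vapply(event_times, function(t) sum(records$time >= t), numeric(1))
  n_event <- vapply(event_times, function(t) sum(records$time == t & records$event),
                    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  greenwood <- cumsum(n_event / (n_risk * (n_risk - n_event)))
  curve <- tibble(time = event_times, n_risk = as.integer(n_risk),
                  n_event = as.integer(n_event), surv = surv,
                  std_err = surv * sqrt(greenwood))
  structure(curve, class = c("km_curve", class(curve)),
            n = nrow(records), n_events = sum(records$event))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events\n",
              attr(x, "n"), attr(x, "n_events")))
  NextMethod()
}

#' Survival probability at arbitrary times from a km_curve
#'
#' @param curve A [km_estimate()] result.
#' @param times Times at which to evaluate the step function.
#' @return Numeric vector of S(t); 1 before the first event.
#' @export
km_survival_at <- function(curve, times) {
  vapply(times, function(t) {
    i <- findInterval(t, curve$time)
    if (i == 0) 1 else curve$surv[i]
  }, numeric(1))
}

#' Gehan-Breslow (generalized Wilcoxon) two-group test
#'
#' A weighted log-rank test in which each distinct pooled event time t_j is
#' weighted by the total number at risk n_j, so early differences dominate.
#' With d_j pooled events and n_1j at risk in group 1:
#' U = sum_j n_j (d_1j - d_j n_1j / n_j) and
#' Var = sum_j n_j^2 d_j (n_j - d_j) n_1j n_2j / (n_j^2 (n_j - 1)).
#' U^2 / Var is referred to a 1-df chi-square. Setting `weights = "logrank"`
#' replaces the weight n_j by 1, recovering the standard log-rank statistic.
#'
#' @param records Tibble with `group` (exactly two levels), `time`, `event`.
#' @param weights `"gehan"` (default, weight = number at risk) or
#'   `"logrank"` (weight = 1).
#' @return An object of class `gb_test`: list with `statistic` (chi-square,
#'   1 df), `p_value`, `U`, `variance`, `groups`, `n`, `weights`.
#' @export
gehan_breslow_test <- function(records, weights = c("gehan", "logrank")) {
  weights <- arg_match(weights)
  groups <- sort(unique(records$group))
  if (length(groups) != 2) abort("exactly two groups required")
  if (!any(records$event)) {
    warn("no events: test degenerate, p = 1")
    return(structure(list(statistic = NA_real_, p_value = 1, U = 0,
                          variance = 0, groups = groups,
                          n = c(sum(records$group == groups[1]),
                                sum(records$group == groups[2])),
                          weights = weights), class = "gb_test"))
  }
  g1 <- records$group == groups[1]
  event_times <- sort(unique(records$time[records$event]))
  U <- 0; V <- 0
  for (t in event_times) {
    at_risk <- records$time >= t
    n_j <- sum(at_risk)
    n_1j <- sum(at_risk & g1)
    n_2j <- n_j - n_1j
    d_j <- sum(records$time == t & records$event)
    d_1j <- sum(records$time == t & records$event & g1)
    w <- if (weights == "gehan") n_j else 1
    U <- U + w * (d_1j - d_j * n_1j / n_j)
    if (n_j > 1) {
      V <- V + w^2 * d_j * (n_j - d_j) * n_1j * n_2j / (n_j^2 * (n_j - 1))
    }
  }
  if (V <= 0) {
    warn("zero variance (one group absent at all event times): p = 1")
    stat <- NA_real_; p <- 1
  } else {
    stat <- U^2 / V
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(statistic = stat, p_value = p, U = U, variance = V,
                 groups = groups,
                 n = c(sum(g1), sum(!g1)), weights = weights),
            class = "gb_test")
}

#' @export
print.gb_test <- function(x, ...) {
  cat(sprintf("%s two-group test\n",
              if (x$weights == "gehan") "Gehan-Breslow (generalized Wilcoxon)"
              else "Log-rank"))
  cat(sprintf("  groups: %s (n=%d) vs %s (n=%d)\n", x$groups[1], x$n[1],
              x$groups[2], x$n[2]))
  cat(sprintf("  chi-square = %.4g (1 df), p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' @rdname gehan_breslow_test
#' @param x A `gb_test` object.
#' @param ... Unused.
#' @export
tidy.gb_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, U = x$U,
         variance = x$variance, df = 1)
}

#' @rdname gehan_breslow_test
#' @export
glance.gb_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value,
         n_group1 = x$n[1], n_group2 = x$n[2], method = x$weights)
}

#' Transplant-free survival report for a two-group cohort
#'
#' Applies the age-eligibility filter (subjects at least `min_age` years old
#' at last follow-up, when an `age_years` column is present), estimates a
#' Kaplan-Meier curve per group and runs the Gehan-Breslow test.
#'
#' @param records Survival tibble (`subject_id`, `group`, `time`, `event`,
#'   optional `age_years`).
#' @param min_age Minimum age in years for inclusion (default 6); ignored
#'   when no `age_years` column exists.
#' @return An object of class `survival_report`: list with `n` (named group
#'   sizes), `median_followup`, `curves` (named list of `km_curve`), `test`
#'   (`gb_test`), `min_age`.
#' @export
survival_report <- function(records, min_age = 6) {
  if ("age_years" %in% names(records)) {
    records <- filter(records, .data$age_years >= min_age)
  }
  groups <- sort(unique(records$group))
  sizes <- table(records$group)
  if (nrow(records) == 0 || length(groups) < 2 || any(sizes == 0)) {
    abort("age filter emptied a group; survival comparison impossible")
  }
  curves <- purrr::map(setNames(groups, groups),
                       ~ km_estimate(filter(records, .data$group == .x)))
  structure(list(
    n = setNames(as.integer(sizes[groups]), groups),
    median_followup = median(records$time),
    curves = curves,
    test = gehan_breslow_test(records),
    min_age = min_age
  ), class = "survival_report")
}

#' @export
print.survival_report <- function(x, ...) {
  cat("Transplant-free survival report\n")
  cat(sprintf("  eligible subjects (age >= %g yr): %s\n", x$min_age,
              paste(sprintf("%s n=%d", names(x$n), x$n), collapse = ", ")))
  cat(sprintf("  median follow-up: %.2f yr\n", x$median_followup))
  print(x$test)
  invisible(x)
}

#' @rdname survival_report
#' @param x A `survival_report`.
#' @param ... Unused.
#' @export
glance.survival_report <- function(x, ...) {
  tibble(n_group1 = x$n[1], n_group2 = x$n[2],
         median_followup = x$median_followup,
         statistic = x$test$statistic, p.value = x$test$p_value)
}
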