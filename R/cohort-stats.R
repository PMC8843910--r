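#' Two-by-two contingency table
#'
#' Rows are groups, columns are outcome levels.
#'
#' @param a,b Counts in row 1 (group 1: outcome 1, outcome 2).
#' @param c,d Counts in row 2 (group 2: outcome 1, outcome 2).
#' @return An object of class `"cc_table2x2"` (an integer 2x2 matrix).
#' @export
contingency_2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers")
  if (sum(x) == 0) stop("at least one margin must be positive")
  structure(matrix(as.integer(x), 2L, 2L, byrow = TRUE),
            class = c("cc_table2x2", "matrix", "array"))
}

as_table2x2 <- function(t) {
  if (inherits(t, "cc_table2x2")) return(t)
  if (is.matrix(t) && all(dim(t) == 2L))
    return(contingency_2x2(t[1, 1], t[1, 2], t[2, 1], t[2, 2]))
  stop("expected a 2x2 table")
}

#' Two-sided Fisher exact test
#'
#' Conditions on both margins: the first cell follows a hypergeometric
#' distribution over its support, and the two-sided p-value sums the point
#' probabilities of every table at most as probable as the observed one
#' (probability-ordering convention, with relative tolerance 1e-7 for ties).
#' A table with an empty margin carries no information: p = 1 with a warning.
#'
#' @param t A 2x2 matrix or [contingency_2x2()] object.
#' @return The two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(contingency_2x2(2, 6, 20, 6))  # 0.0127
#' @export
fisher_exact_two_sided <- function(t) {
  t <- as_table2x2(t)
  r1 <- sum(t[1, ]); r2 <- sum(t[2, ])
  c1 <- sum(t[, 1]); c2 <- sum(t[, 2])
  if (min(r1, r2, c1, c2) == 0L) {
    warning("table has an empty margin: p = 1")
    return(1)
  }
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(t[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties.  `U` is the statistic for `x`
#' (number of (x, y) pairs with x < y, counting ties as half).  The p-value
#' is exact by enumeration of all rank assignments when
#' `length(x) + length(y) <= 12`, otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y Numeric samples (both non-empty).
#' @return A list with `U` and `p_value`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("samples must be finite")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n <= 12L) {
    combos <- utils::combn(n, n1)
    u_all <- colSums(matrix(rk[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
  } else {
    ties <- table(rk)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = U, p_value = 1))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  }
  list(U = U, p_value = p)
}

#' Kaplan-Meier product-limit curve
#'
#' Censored observations tied with event times are treated as still at risk
#' at that time (events first).  The curve is evaluated at the distinct
#' event times.
#'
#' @param time Positive follow-up times in months.
#' @param event 0/1 (or logical) event indicators; 1 = event observed.
#' @return An object of class `"cc_km"`: a list with `event_times`,
#'   `n_events`, `at_risk`, `survival` and the sample size `n`.
#' @examples
#' km_curve(c(1, 2, 3, 4), c(1, 1, 1, 1))$survival  # 0.75 0.50 0.25 0.00
#' @export
km_curve <- function(time, event) {
  event <- as.integer(event)
  if (!length(time)) stop("need at least one observation")
  if (any(!is.finite(time) | time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0L, 1L))) stop("event must be 0/1")
  et <- sort(unique(time[event == 1L]))
  at_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  n_events <- vapply(et, function(t) sum(time == t & event == 1L), numeric(1))
  surv <- cumprod(1 - n_events / at_risk)
  structure(list(event_times = et, n_events = n_events,
                 at_risk = at_risk, survival = surv, n = length(time)),
            class = "cc_km")
}

#' @export
print.cc_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event time(s)\n",
              x$n, length(x$event_times)))
  med <- km_median(x)
  cat("  median:", if (is.na(med)) "not reached" else sprintf("%.2f months", med), "\n")
  invisible(x)
}

#' Median survival from a Kaplan-Meier curve
#'
#' The smallest event time at which the survival estimate drops to 0.5 or
#' below.  `NA` means the median was not reached within follow-up (an
#' explicit "not reached", following the convention of survival software).
#'
#' @param curve A [km_curve()] object.
#' @return Months, or `NA_real_` for "not reached".
#' @export
km_median <- function(curve) {
  stopifnot(inherits(curve, "cc_km"))
  i <- which(curve$survival <= 0.5 + 1e-9)
  if (!length(i)) return(NA_real_)
  curve$event_times[min(i)]
}

#' Log-rank test for two survival curves
#'
#' Standard one-degree-of-freedom log-rank: at each distinct event time the
#' observed events in group A are compared with their hypergeometric
#' expectation given the pooled risk set; the statistic is
#' `(sum(O - E))^2 / sum(V)` with a chi-square(1) reference.
#'
#' @param time_a,event_a Times and 0/1 event indicators of group A.
#' @param time_b,event_b Times and 0/1 event indicators of group B.
#' @return A list with `chisq`, `p_value`, `observed` (group-A events) and
#'   `expected` (group-A expected events).
#' @examples
#' logrank_test(1, 1, 2, 1)  # chisq = 1, p = 0.3173
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  event_a <- as.integer(event_a); event_b <- as.integer(event_b)
  if (!length(time_a) || !length(time_b)) stop("both groups must be non-empty")
  if (any(c(time_a, time_b) <= 0)) stop("times must be positive")
  if (sum(event_a) + sum(event_b) == 0L)
    stop("no events in either group: log-rank test undefined")
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  in_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  et <- sort(unique(time[event == 1L]))
  o_minus_e <- 0; v <- 0; obs <- 0; expd <- 0
  for (t in et) {
    at_risk <- time >= t
    nj <- sum(at_risk); n1j <- sum(at_risk & in_a)
    dj <- sum(time == t & event == 1L)
    d1j <- sum(time == t & event == 1L & in_a)
    ej <- dj * n1j / nj
    o_minus_e <- o_minus_e + (d1j - ej)
    obs <- obs + d1j; expd <- expd + ej
    if (nj > 1L)
      v <- v + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  }
  if (v <= 0) return(list(chisq = 0, p_value = 1, observed = obs, expected = expd))
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = obs, expected = expd)
}

#' Build a 2x2 table from a patient table
#'
#' Cross-tabulates two binary patient fields after excluding patients whose
#' CC class is undetermined (when a `classification` column is present) and
#' dropping rows with a missing value in either field (the number dropped is
#' reported via `message()`).  Row/column order follows the sorted unique
#' values of each field.
#'
#' @param patients Patient data frame.
#' @param group_field,outcome_field Column names; each must take exactly two
#'   distinct non-missing values among the included patients.
#' @return A [contingency_2x2()] object with `dimnames` recording the levels.
#' @export
build_contingency <- function(patients, group_field, outcome_field) {
  if (!nrow(patients)) stop("empty patient table")
  for (f in c(group_field, outcome_field))
    if (!f %in% names(patients)) stop("no such column: ", f)
  if ("classification" %in% names(patients))
    patients <- patients[patients$classification != "undetermined", , drop = FALSE]
  g <- patients[[group_field]]; o <- patients[[outcome_field]]
  keep <- !is.na(g) & !is.na(o)
  if (any(!keep))
    message(sum(!keep), " patient(s) dropped for missing ", group_field,
            " or ", outcome_field)
  g <- g[keep]; o <- o[keep]
  gl <- sort(unique(g)); ol <- sort(unique(o))
  if (length(gl) != 2L) stop("'", group_field, "' is not binary")
  if (length(ol) != 2L) stop("'", outcome_field, "' is not binary")
  t <- contingency_2x2(sum(g == gl[1] & o == ol[1]), sum(g == gl[1] & o == ol[2]),
                       sum(g == gl[2] & o == ol[1]), sum(g == gl[2] & o == ol[2]))
  dimnames(t) <- list(as.character(gl), as.character(ol))
  t
}
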