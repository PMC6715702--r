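#' 2x2 exposure-outcome contingency table
#'
#' Layout: rows are exposure (exposed / unexposed), columns are outcome
#' (event / no event): `a` exposed events, `b` exposed non-events, `c`
#' unexposed events, `d` unexposed non-events.
#'
#' @param a,b,c,d non-negative integer counts
#' @return a `contingency_2x2` (2x2 integer matrix)
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (all(c(a, b) == 0) || all(c(c, d) == 0) ||
      all(c(a, c) == 0) || all(c(b, d) == 0))
    stop("degenerate table: a full margin is zero")
  m <- matrix(as.integer(round(counts)), 2, 2, byrow = TRUE,
              dimnames = list(exposure = c("exposed", "unexposed"),
                              outcome = c("event", "no_event")))
  class(m) <- c("contingency_2x2", class(m))
  m
}

# two-sided Fisher exact p: sum of probabilities of all tables with the
# observed margins whose probability does not exceed the observed table's
# (up to a relative tolerance, as is conventional)
.fisher_p_two_sided <- function(a, b, c, d) {
  K <- a + b          # exposed total (drawn)
  m1 <- a + c         # events total (marked)
  N <- a + b + c + d
  support <- max(0, K + m1 - N):min(K, m1)
  probs <- stats::dhyper(support, m1, N - m1, K)
  p_obs <- stats::dhyper(a, m1, N - m1, K)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Odds ratio with confidence interval and Fisher's exact p-value
#'
#' Cross-product odds ratio `(a*d)/(b*c)` with the Haldane-Anscombe
#' correction (add 0.5 to every cell) applied only when some cell is zero.
#' The p-value is the two-sided Fisher exact test (sum of hypergeometric
#' probabilities of margin-fixed tables no more likely than the observed
#' one). Confidence intervals: `"woolf"` (default; normal interval on the
#' log odds ratio, with the same 0.5 correction rule) or
#' `"conditional-exact"` (the conditional exact interval of
#' [stats::fisher.test()]).
#'
#' @param table a [contingency_2x2()] (or 2x2 matrix in the same layout)
#' @param ci_method `"woolf"` or `"conditional-exact"`
#' @param alpha two-sided type-I level for the CI (default 0.05)
#' @return list with `or`, `ci_low`, `ci_high`, `p_value`, `ci_method`
#' @export
odds_ratio <- function(table, ci_method = c("woolf", "conditional-exact"),
                       alpha = 0.05) {
  ci_method <- match.arg(ci_method)
  if (!inherits(table, "contingency_2x2"))
    table <- contingency_2x2(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  corrected <- any(c(a, b, c, d) == 0)
  h <- if (corrected) 0.5 else 0
  or <- ((a + h) * (d + h)) / ((b + h) * (c + h))
  p <- .fisher_p_two_sided(a, b, c, d)
  z <- stats::qnorm(1 - alpha / 2)
  if (ci_method == "woolf") {
    se <- sqrt(1 / (a + h) + 1 / (b + h) + 1 / (c + h) + 1 / (d + h))
    ci <- exp(log(or) + c(-1, 1) * z * se)
  } else {
    ft <- stats::fisher.test(matrix(c(a, c, b, d), 2, 2),
                             conf.level = 1 - alpha)
    ci <- as.numeric(ft$conf.int)
  }
  list(or = or, ci_low = ci[1], ci_high = ci[2], p_value = p,
       ci_method = ci_method)
}

#' Relative risk from a 2x2 table
#'
#' Ratio of outcome proportions, `[a/(a+b)] / [c/(c+d)]`. A zero unexposed
#' risk yields `Inf` with a warning.
#'
#' @param table a [contingency_2x2()]
#' @return numeric relative risk
#' @export
relative_risk <- function(table) {
  if (!inherits(table, "contingency_2x2"))
    table <- contingency_2x2(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  risk1 <- a / (a + b)
  risk0 <- c / (c + d)
  if (risk0 == 0) {
    warning("unexposed risk is zero; relative risk is infinite")
    return(Inf)
  }
  risk1 / risk0
}
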