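#' Two-sided binomial proportion test for cohort mutation frequencies
#'
#' Compares mutation frequencies between two cohorts, e.g. 0 of 34 samples
#' in later series versus 18 of 23 in the original report. The default is
#' the pooled two-proportion z-test without continuity correction,
#' \deqn{z = \frac{\hat p_2 - \hat p_1}
#'   {\sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}},}
#' with \eqn{\hat p} the pooled proportion and a two-sided normal p-value.
#' Fisher's exact test (two-sided hypergeometric) is available as the exact
#' alternative; the headline cohort discrepancy is significant at
#' p < 1e-8 under either.
#'
#' @param k1,n1 Successes and trials in cohort 1.
#' @param k2,n2 Successes and trials in cohort 2.
#' @param method `"pooled_z"` (default) or `"fisher"`.
#' @return An object of class `htest` with `statistic` (z, for the pooled
#'   test), `estimate` (the two proportions), and `p.value`. When both
#'   counts are zero (or both complete), the pooled variance vanishes and
#'   p = 1 by convention.
#' @examples
#' two_proportion_test(0, 34, 18, 23)
#' two_proportion_test(0, 34, 18, 23, method = "fisher")
#' @export
two_proportion_test <- function(k1, n1, k2, n2,
                                method = c("pooled_z", "fisher")) {
  method <- match.arg(method)
  if (n1 < 1 || n2 < 1) stop("both cohorts must have n >= 1")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop("counts must satisfy 0 <= k <= n")
  }
  p1 <- k1 / n1; p2 <- k2 / n2
  dname <- sprintf("%d/%d vs %d/%d", k1, n1, k2, n2)
  if (method == "pooled_z") {
    pooled <- (k1 + k2) / (n1 + n2)
    se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
    if (se == 0) {
      z <- 0; p <- 1  # degenerate: identical extreme proportions
    } else {
      z <- (p2 - p1) / se
      p <- 2 * pnorm(-abs(z))
    }
    res <- list(statistic = c(z = z), p.value = p,
                estimate = c(prop1 = p1, prop2 = p2),
                method = "Two-sample pooled z-test for equality of proportions",
                data.name = dname)
  } else {
    ft <- fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2,
                             byrow = TRUE))
    res <- list(statistic = NULL, p.value = ft$p.value,
                estimate = c(prop1 = p1, prop2 = p2),
                method = "Fisher's exact test for equality of proportions",
                data.name = dname)
  }
  structure(res, class = "htest")
}

#' Two-sided Mann-Whitney U test
#'
#' Wilcoxon rank-sum comparison of two independent samples: the exact null
#' distribution is used for small untied samples (combined n <= 20 without
#' ties), and the tie-corrected normal approximation otherwise.
#'
#' @param sample_a,sample_b Numeric vectors; both must be nonempty.
#' @return An `htest` object with the two-sided p-value.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(10, 11, 12))$p.value  # 0.1 exactly
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    stop("both samples must be nonempty")
  }
  combined <- c(sample_a, sample_b)
  use_exact <- length(combined) <= 20L && !any(duplicated(combined))
  suppressWarnings(
    wilcox.test(sample_a, sample_b, alternative = "two.sided",
                exact = use_exact, correct = TRUE)
  )
}

#' Two-sided two-sample t-test
#'
#' Student's t-test with pooled variance by default (`variant = "pooled"`),
#' or Welch's unequal-variance form. Degenerate inputs follow documented
#' conventions rather than erroring: when every value is identical in both
#' samples combined, p = 1; when the within-group variance is zero but the
#' means differ, p = 0.
#'
#' @param sample_a,sample_b Numeric vectors, each with at least 2 values.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return An `htest` object.
#' @export
two_sided_t_test <- function(sample_a, sample_b,
                             variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("each sample needs at least 2 values")
  }
  v_a <- var(sample_a); v_b <- var(sample_b)
  if (v_a == 0 && v_b == 0) {
    same <- isTRUE(all.equal(mean(sample_a), mean(sample_b)))
    res <- list(statistic = c(t = if (same) 0 else Inf),
                p.value = if (same) 1 else 0,
                estimate = c(mean_a = mean(sample_a), mean_b = mean(sample_b)),
                method = "Two-sample t-test (degenerate: zero variance)",
                data.name = "sample_a vs sample_b")
    return(structure(res, class = "htest"))
  }
  t.test(sample_a, sample_b, alternative = "two.sided",
         var.equal = (variant == "pooled"))
}
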