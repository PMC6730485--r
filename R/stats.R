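# Group-level statistics: summary-form and raw t-tests, FC comparisons,
# metric-score correlation and the sample-size computation.

new_test <- function(statistic, df, p, kind, alpha = 0.01,
                     degenerate = FALSE, note = NULL) {
  structure(list(statistic = statistic, df = df, p = p, kind = kind,
                 alpha = alpha, significant = !degenerate && !is.na(p) &&
                   p < alpha, degenerate = degenerate, note = note),
            class = "fnirs_test")
}

#' @export
print.fnirs_test <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("%s: degenerate (%s)\n", x$kind, x$note))
  } else {
    cat(sprintf("%s: t = %.4g, df = %.4g, two-tailed p = %.4g%s\n",
                x$kind, x$statistic, x$df, x$p,
                if (x$significant) sprintf(" (significant at alpha = %g)",
                                           x$alpha) else ""))
  }
  invisible(x)
}

#' Two-sample t-test from group summary statistics
#'
#' Computes the two-tailed independent-samples t-test directly from printed
#' means, SDs and group sizes, as needed to check reported demographic and
#' cognitive-score comparisons. Both the pooled-variance (Student) and the
#' Welch variant are available.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @param alpha significance level attached to the result.
#' @return An object of class `fnirs_test` with `statistic`, `df`, `p`.
#' @examples
#' # MoCA-K, healthy controls vs baseline MCI
#' two_sample_t_summary(27.17, 2.34, 12, 19.33, 2.21, 12)
#' @export
two_sample_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 variant = c("pooled", "welch"),
                                 alpha = 0.01) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("SDs must be non-negative", call. = FALSE)
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2) {
    return(new_test(NA_real_, NA_real_, NA_real_,
                    kind = sprintf("two-sample (%s)", variant), alpha = alpha,
                    degenerate = TRUE, note = "zero variance, equal means"))
  }
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tstat <- (mean1 - mean2) / se
  p <- 2 * pt(-abs(tstat), df)
  new_test(tstat, df, p, kind = sprintf("two-sample (%s)", variant),
           alpha = alpha)
}

#' Paired t-test on per-subject values
#'
#' Two-tailed paired t-test of aligned per-subject measurements (e.g. a
#' cognitive score or network metric before and after an intervention).
#' Zero-variance differences are flagged as degenerate rather than tested.
#'
#' @param x,y equal-length (>= 3) numeric vectors aligned by subject.
#' @param alpha significance level attached to the result.
#' @return An `fnirs_test`.
#' @export
paired_t <- function(x, y, alpha = 0.01) {
  if (length(x) != length(y)) stop("`x` and `y` must be aligned", call. = FALSE)
  if (length(x) < 3L) stop("at least 3 pairs required", call. = FALSE)
  d <- x - y
  if (sd(d) == 0) {
    return(new_test(NA_real_, length(d) - 1, NA_real_, kind = "paired",
                    alpha = alpha, degenerate = TRUE,
                    note = "zero-variance differences"))
  }
  ht <- t.test(x, y, paired = TRUE)
  new_test(unname(ht$statistic), unname(ht$parameter), ht$p.value,
           kind = "paired", alpha = alpha)
}

#' Two-sample t-test on raw values
#'
#' Convenience wrapper around [stats::t.test()] with the pooled/Welch switch
#' used throughout the package, returning the same `fnirs_test` structure as
#' the summary-form test.
#'
#' @param x,y numeric vectors.
#' @inheritParams two_sample_t_summary
#' @return An `fnirs_test`.
#' @export
two_sample_t <- function(x, y, variant = c("pooled", "welch"), alpha = 0.01) {
  variant <- match.arg(variant)
  ht <- t.test(x, y, var.equal = (variant == "pooled"))
  new_test(unname(ht$statistic), unname(ht$parameter), ht$p.value,
           kind = sprintf("two-sample (%s)", variant), alpha = alpha)
}

#' Compare two collections of connectivity matrices
#'
#' Reduces every subject's r matrix to its mean off-diagonal Fisher z
#' ([mean_fisher_z()]) and compares the two collections with a paired or
#' independent two-sample t-test.
#'
#' @param matrices_a,matrices_b lists of `fnirs_fc` matrices of kind `"r"`.
#' @param paired logical; subjects aligned across the two collections.
#' @param variant two-sample variant when `paired = FALSE`.
#' @param alpha significance level.
#' @return An `fnirs_test` with the per-subject mean-z values attached as
#'   attributes `z_a`, `z_b`.
#' @export
fc_compare <- function(matrices_a, matrices_b, paired = FALSE,
                       variant = c("pooled", "welch"), alpha = 0.01) {
  dims <- vapply(c(matrices_a, matrices_b), nrow, 1L)
  if (any(dims != dims[1])) stop("matrices differ in dimension", call. = FALSE)
  za <- vapply(matrices_a, mean_fisher_z, 1)
  zb <- vapply(matrices_b, mean_fisher_z, 1)
  res <- if (paired) paired_t(za, zb, alpha = alpha) else
    two_sample_t(za, zb, variant = variant, alpha = alpha)
  attr(res, "z_a") <- za
  attr(res, "z_b") <- zb
  res
}

#' Correlation between a network metric and cognitive scores
#'
#' Pearson correlation between per-visit (or per-subject) metric values and
#' the matching cognitive scores.
#'
#' @param metrics,scores aligned numeric vectors of length >= 3.
#' @return The correlation coefficient r.
#' @export
metric_score_correlation <- function(metrics, scores) {
  if (length(metrics) != length(scores) || length(metrics) < 3L) {
    stop("aligned sequences of length >= 3 required", call. = FALSE)
  }
  if (sd(metrics) == 0 || sd(scores) == 0) {
    stop("zero variance in one of the sequences", call. = FALSE)
  }
  cor(metrics, scores)
}

#' Per-group sample size for a hypothesized score change
#'
#' Normal-approximation sample size for detecting a mean change `delta`
#' against score variability `sd` at two-sided level `alpha` and the given
#' power: `n_base = ceil(2 (z_{1-alpha/2} + z_{power})^2 / d^2)` per group
#' with `d = delta / sd`, inflated for the anticipated dropout rate:
#' `n_final = ceil(n_base / (1 - dropout))`.
#'
#' @param delta hypothesized mean change (score units).
#' @param sd score standard deviation (same units).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param dropout anticipated dropout fraction in \[0, 1).
#' @param n_base optional externally supplied base sample size; when given,
#'   only the dropout inflation is applied.
#' @return List with `effect_size` (d), `n_base` and `n_final`.
#' @examples
#' sample_size(delta = 6, sd = 4.8)             # d = 1.25
#' sample_size(delta = 6, sd = 4.8, n_base = 10) # dropout chain only
#' @export
sample_size <- function(delta, sd, alpha = 0.05, power = 0.80,
                        dropout = 0.15, n_base = NULL) {
  if (!(alpha > 0 && alpha < 1) || !(power > 0 && power < 1)) {
    stop("`alpha` and `power` must lie in (0, 1)", call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) {
    stop("`dropout` must lie in [0, 1)", call. = FALSE)
  }
  d <- NA_real_
  if (is.null(n_base)) {
    stopifnot_scalar_pos(delta, "delta")
    stopifnot_scalar_pos(sd, "sd")
    d <- delta / sd
    n_base <- ceiling(2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 / d^2)
  }
  list(effect_size = d, n_base = as.integer(n_base),
       n_final = as.integer(ceiling(n_base / (1 - dropout))))
}
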