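#' Two-sample permutation test on group means
#'
#' Builds the null distribution of the difference in group means by permuting
#' group labels, and returns the add-one p-value
#' `p = (1 + #{permuted >= observed}) / (1 + n_perm)` (two-sided compares
#' absolute differences). Reproducible under [set.seed()].
#'
#' @param x,y Numeric vectors of per-subject values (>= 2 each).
#' @param n_perm Number of label permutations.
#' @param sided 1 (tests `mean(x) > mean(y)`) or 2.
#' @return A list of class `perm_test`: `statistic` (observed difference),
#'   `p_value`, `n_perm`, `sided`.
#' @export
#' @examples
#' set.seed(1)
#' permutation_test(rnorm(10, 1), rnorm(10))$p_value
permutation_test <- function(x, y, n_perm = 10000, sided = 2) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 finite values")
  stopifnot(sided %in% c(1, 2))
  pool <- c(x, y)
  n <- length(pool); nx <- length(x)
  obs <- mean(x) - mean(y)
  if (stats::sd(pool) == 0) {
    warning("constant pooled data: permutation distribution degenerate")
    return(structure(list(statistic = obs, p_value = 1,
                          n_perm = n_perm, sided = sided),
                     class = "perm_test"))
  }
  pm <- replicate(n_perm, sample.int(n, nx))
  sums <- colSums(matrix(pool[pm], nrow = nx))
  total <- sum(pool)
  perm_diff <- sums / nx - (total - sums) / (n - nx)
  exceed <- if (sided == 2) sum(abs(perm_diff) >= abs(obs))
            else sum(perm_diff >= obs)
  structure(list(statistic = obs,
                 p_value = (1 + exceed) / (1 + n_perm),
                 n_perm = n_perm, sided = sided),
            class = "perm_test")
}

#' Bias-corrected bootstrap effect size
#'
#' Bias-corrected (BC) bootstrap of the mean of `values` (for a group
#' difference, pass per-subject differences or use the paired construction
#' upstream): resamples with replacement, applies the median-bias correction
#' `z0`, and returns the BC confidence interval together with the two-tail
#' (or one-tail) bootstrap p-value for the effect differing from 0.
#'
#' @param values Numeric vector (>= 3 observations).
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level of the interval.
#' @param sided 1 or 2 for the p-value.
#' @return A list of class `boot_effect`: `effect`, `ci` (length 2),
#'   `p_value`, `n_boot`, `conf`.
#' @export
bootstrap_effect <- function(values, n_boot = 10000, conf = 0.95, sided = 2) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need at least 3 observations")
  n <- length(values)
  obs <- mean(values)
  if (stats::sd(values) == 0) {
    warning("all values equal: degenerate (zero-width) bootstrap interval")
    return(structure(list(effect = obs, ci = c(obs, obs),
                          p_value = if (obs == 0) 1 else 1 / (1 + n_boot),
                          n_boot = n_boot, conf = conf),
                     class = "boot_effect"))
  }
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  boots <- colMeans(matrix(values[idx], nrow = n))
  # median-bias correction
  prop_below <- (sum(boots < obs) + 0.5 * sum(boots == obs)) / n_boot
  prop_below <- min(max(prop_below, 1 / (n_boot + 1)), n_boot / (n_boot + 1))
  z0 <- stats::qnorm(prop_below)
  a <- (1 - conf) / 2
  lo_q <- stats::pnorm(2 * z0 + stats::qnorm(a))
  hi_q <- stats::pnorm(2 * z0 + stats::qnorm(1 - a))
  ci <- unname(stats::quantile(boots, c(lo_q, hi_q), type = 6))
  # BC-adjusted tail position of zero
  q0 <- (1 + sum(boots <= 0)) / (1 + n_boot)
  zq <- stats::qnorm(min(max(q0, 1 / (1 + n_boot)), n_boot / (1 + n_boot)))
  left <- stats::pnorm(zq - 2 * z0)
  p <- if (sided == 2) 2 * min(left, 1 - left) else 1 - left
  structure(list(effect = obs, ci = ci, p_value = min(max(p, 0), 1),
                 n_boot = n_boot, conf = conf),
            class = "boot_effect")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test (%d permutations, %d-sided)\n", x$n_perm, x$sided))
  cat(sprintf("  mean difference = %.4g, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' @export
print.boot_effect <- function(x, ...) {
  cat(sprintf("Bias-corrected bootstrap (%d resamples)\n", x$n_boot))
  cat(sprintf("  effect = %.4g, %g%% CI [%.4g, %.4g], p = %.4g\n",
              x$effect, 100 * x$conf, x$ci[1], x$ci[2], x$p_value))
  invisible(x)
}

#' Tidy a permutation test
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(estimate = x$statistic, p.value = x$p_value,
                 n.perm = x$n_perm, alternative = if (x$sided == 2) "two.sided" else "greater")
}

#' Tidy a bootstrap effect
#' @param x A `boot_effect` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.boot_effect <- function(x, ...) {
  tibble::tibble(estimate = x$effect, conf.low = x$ci[1], conf.high = x$ci[2],
                 p.value = x$p_value, n.boot = x$n_boot)
}

#' Turn a result object into a tidy tibble
#'
#' Broom-style generics: `tidy()` returns one row per component of a result
#' (clusters, assemblies, ...), `glance()` a one-row summary.
#'
#' @param x A result object.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
glance.perm_test <- function(x, ...) tidy(x)

#' @export
glance.boot_effect <- function(x, ...) tidy(x)
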