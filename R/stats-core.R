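#' Spearman rank correlation with mid-ranks and a t-approximation p-value
#'
#' Rank correlation is used throughout the package because timed-search
#' abundance estimates are strongly right-skewed; ranking makes the
#' statistic invariant to any monotone transform of either variable.
#' Ties receive mid-ranks (average ranks), and the coefficient is the
#' Pearson correlation of the two rank vectors, so tied data are handled
#' exactly rather than through the no-tie shortcut formula.
#'
#' The p-value tests rho = 0 via the t-approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of freedom.
#' For very small samples (\eqn{n \le 9}) an exact permutation p-value can
#' be requested instead, obtained by full enumeration of all \eqn{n!}
#' orderings (two-sided, counting the observed ordering itself, so the
#' result is always in (0, 1]).
#'
#' @param x,y Numeric vectors of equal length, at least 3, all finite.
#' @param p_method "t" (default) for the t-approximation, "exact" for the
#'   enumerated permutation p-value (only allowed for n <= 9).
#' @return An object of class `spearman_cor`: a list with elements `rho`,
#'   `p_value`, `n`, and `degenerate`. When either input is constant the
#'   correlation is undefined: `rho` and `p_value` are `NA` and
#'   `degenerate` is `TRUE`.
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(10, 20, 30, 40))$rho  # 1
#' spearman_rho(c(1, 2, 3, 4), c(40, 30, 20, 10))$rho  # -1
#' @export
spearman_rho <- function(x, y, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  stop_if_not(length(x) == length(y), "x and y must have the same length")
  n <- length(x)
  stop_if_not(n >= 3L, "need at least 3 paired observations")
  stop_if_not(all(is.finite(x)) && all(is.finite(y)),
              "x and y must be finite")
  rx <- rank(x)  # mid-ranks for ties
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(structure(
      list(rho = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE),
      class = "spearman_cor"
    ))
  }
  rho <- stats::cor(rx, ry)
  # numeric noise can push |rho| past 1 by ~1e-16
  rho <- max(-1, min(1, rho))
  if (p_method == "exact") {
    stop_if_not(n <= 9L, "exact permutation p only supported for n <= 9")
    perms <- all_perms(n)
    rx_c <- rx - mean(rx)
    ry_c <- ry - mean(ry)
    denom <- sqrt(sum(rx_c^2) * sum(ry_c^2))
    # each permutation reorders the centered ranks of y against those of x
    perm_ry <- matrix(ry_c[perms], nrow = nrow(perms))
    rho_perm <- as.numeric(perm_ry %*% rx_c) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) == 1) {
      # t statistic diverges; report the smallest representable p rather
      # than an exact zero so p stays in (0, 1]
      p <- .Machine$double.xmin
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
      p <- min(1, max(p, .Machine$double.xmin))
    }
  }
  structure(list(rho = rho, p_value = p, n = n, degenerate = FALSE),
            class = "spearman_cor")
}

#' @export
print.spearman_cor <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Spearman rank correlation: degenerate input (constant vector), n =",
        x$n, "\n")
  } else {
    cat(sprintf("Spearman rank correlation: rho = %.4f, p = %.4g, n = %d\n",
                x$rho, x$p_value, x$n))
  }
  invisible(x)
}

#' Benjamini-Hochberg step-up false-discovery-rate adjustment
#'
#' Implements the classic step-up procedure: with the p-values sorted
#' ascending, the adjusted value at sorted rank k is
#' \eqn{\min_{j \ge k} m p_{(j)} / j} capped at 1, and the rejection set is
#' the largest prefix whose members satisfy \eqn{p_{(k)} \le k \alpha / m}.
#' The output is returned in the input order. Adjusted p-values are
#' monotone nondecreasing in the raw p-values, and `reject` is equivalent
#' to `p_adjusted <= alpha`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param alpha Target false-discovery rate (default 0.05).
#' @return List with `p_adjusted` and logical `reject`, both aligned with
#'   the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))$reject  # all TRUE
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  stop_if_not(length(p) >= 1L, "p must be nonempty")
  stop_if_not(all(is.finite(p)) && all(p >= 0) && all(p <= 1),
              "p-values must lie in [0, 1]")
  stop_if_not(is.numeric(alpha) && alpha > 0 && alpha < 1,
              "alpha must be in (0, 1)")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- rev(cummin(rev(m * ps / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  ok <- which(ps <= seq_len(m) * alpha / m)
  k_star <- if (length(ok)) max(ok) else 0L
  rej_sorted <- seq_len(m) <= k_star
  p_adjusted <- numeric(m)
  reject <- logical(m)
  p_adjusted[o] <- adj_sorted
  reject[o] <- rej_sorted
  list(p_adjusted = p_adjusted, reject = reject)
}
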