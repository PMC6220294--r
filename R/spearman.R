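# Spearman rank correlation with midranks for ties, exact permutation
# p-values for small n and the usual t approximation otherwise.

# all permutations of 1..n as an n!-row integer matrix (insertion build)
.all_perms <- function(n) {
  P <- matrix(1L, 1L, 1L)
  if (n == 1L) return(P)
  for (k in 2L:n) {
    m <- nrow(P)
    blocks <- vector("list", k)
    for (j in seq_len(k)) {
      B <- matrix(k, m, k)
      B[, -j] <- P
      blocks[[j]] <- B
    }
    P <- do.call(rbind, blocks)
  }
  P
}

.pearson <- function(x, y) {
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * sx * sy)
}

#' Spearman coverage-versus-proportion diagnostic
#'
#' The signature of conversion artifacts: if residual C calls come from a
#' small fixed per-base failure probability, the unconverted proportion at
#' the sites where any survive falls off as coverage grows (roughly 1/depth),
#' giving a strongly negative rank correlation; genuine methylation is
#' coverage-independent.  Computes rho as the Pearson correlation of midranks
#' (average ranks for ties).  The two-sided p-value uses exact enumeration of
#' all permutations for `n <= exact_n_max` and the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` otherwise.
#'
#' @param table a shared-site or unconverted-site table (any data.frame).
#' @param x,y column names for coverage and proportion (defaults
#'   `combined_depth` and `pooled_proportion`).
#' @param exact_n_max largest n for which the exact permutation null is
#'   enumerated (default 10).
#' @return list of class `correlation_result`: `rho`, `n`, `p`, `method`.
#' @examples
#' tab <- data.frame(combined_depth = c(2, 4, 4, 10),
#'                   pooled_proportion = c(0.5, 0.25, 0.3, 0.1))
#' spearman_coverage_correlation(tab)
#' @export
spearman_coverage_correlation <- function(table, x = "combined_depth",
                                          y = "pooled_proportion",
                                          exact_n_max = 10L) {
  xv <- as.numeric(table[[x]])
  yv <- as.numeric(table[[y]])
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3L) {
    stop("undefined correlation: need at least 3 complete observations",
         call. = FALSE)
  }
  if (sd(xv) == 0 || sd(yv) == 0) {
    stop("undefined correlation: zero variance in x or y", call. = FALSE)
  }
  rx <- rank(xv); ry <- rank(yv)
  rho <- .pearson(rx, ry)
  if (n <= exact_n_max) {
    P <- .all_perms(n)
    # only the cross-moment varies across permutations of y's ranks
    S <- matrix(ry[P], nrow(P), n) %*% rx
    rho_all <- (S - n * mean(rx) * mean(ry)) / ((n - 1) * sd(rx) * sd(ry))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "t-approximation"
  }
  structure(list(rho = rho, n = n, p = p, method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  pstr <- if (x$p < 0.001) "p < 0.001" else sprintf("p = %.3g", x$p)
  cat(sprintf("Spearman rank correlation: rho = %.4g, n = %d, %s (%s)\n",
              x$rho, x$n, pstr, x$method))
  invisible(x)
}
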