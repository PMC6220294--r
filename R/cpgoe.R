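#' Normalized CpG content (observed/expected)
#'
#' Per-sequence (or per-window) CpG depletion statistic
#' `oe = n_CpG * L / (n_C * n_G)` with overlapping dinucleotide counts.
#' Historically methylated genomes lose CpGs to deamination, so `oe` well
#' below 1 — and a bimodal gene-level distribution — is the evolutionary
#' fingerprint of a methylation system.  `N` bases are excluded from the
#' counts and from `L`; sequences where `n_C * n_G = 0` get a flagged
#' undefined record rather than being dropped.
#'
#' @param x a [ref_genome()], a (named) character vector of sequences, or a
#'   `Biostrings::DNAStringSet`.  Alphabet A/C/G/T/N.
#' @param window 0 for one record per sequence, otherwise non-overlapping
#'   tile width in bases (a shorter trailing window is kept and its true
#'   length recorded).
#' @return `data.table`: `seq_id`, `length` (N-excluded), `n_C`, `n_G`,
#'   `n_CpG`, `oe` (`NA` when undefined), `defined`.
#' @examples
#' cpg_oe(c(a = "CGCGCG"))$oe   # 2
#' cpg_oe(c(b = "ACGT"))$oe    # 4
#' @export
cpg_oe <- function(x, window = 0L) {
  if (inherits(x, "ref_genome")) x <- x$sequences
  if (!inherits(x, "DNAStringSet")) {
    x <- toupper(as.character(x))
    if (any(grepl("[^ACGTN]", x))) {
      stop("sequences are restricted to the alphabet A/C/G/T/N", call. = FALSE)
    }
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    x <- Biostrings::DNAStringSet(x)
  }
  if (window > 0L) {
    pieces <- lapply(seq_along(x), function(i) {
      L <- Biostrings::width(x)[i]
      starts <- seq.int(1L, L, by = window)
      ends <- pmin(starts + window - 1L, L)
      w <- Biostrings::DNAStringSet(Biostrings::Views(x[[i]], starts, ends))
      names(w) <- sprintf("%s:%d-%d", names(x)[i], starts, ends)
      w
    })
    x <- do.call(c, pieces)
  }
  lf <- Biostrings::letterFrequency(x, c("C", "G", "N"))
  n_cpg <- Biostrings::dinucleotideFrequency(x, step = 1L)[, "CG"]
  L <- Biostrings::width(x) - lf[, "N"]
  n_c <- as.numeric(lf[, "C"]); n_g <- as.numeric(lf[, "G"])
  defined <- n_c > 0 & n_g > 0
  oe <- ifelse(defined, as.numeric(n_cpg) * L / (n_c * n_g), NA_real_)
  data.table(seq_id = names(x), length = as.integer(L),
             n_C = as.integer(n_c), n_G = as.integer(n_g),
             n_CpG = as.integer(n_cpg), oe = oe,
             defined = defined)
}

# ---- univariate Gaussian mixture machinery -------------------------------

.ll_norm <- function(v, mu, s) sum(dnorm(v, mu, s, log = TRUE))

.fit1 <- function(v) {
  mu <- mean(v)
  s <- sqrt(mean((v - mu)^2)) # ML estimate
  list(mean = mu, sd = s, ll = .ll_norm(v, mu, s))
}

.em2 <- function(v, w, mu, s, tol, max_iter, sd_floor) {
  n <- length(v)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(v, mu[1], s[1])
    d2 <- w[2] * dnorm(v, mu[2], s[2])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    r <- d1 / tot
    s1 <- sum(r); s2 <- n - s1
    if (s1 < 1e-8 || s2 < 1e-8) break # one component died
    w <- c(s1, s2) / n
    mu <- c(sum(r * v) / s1, sum((1 - r) * v) / s2)
    s <- pmax(sqrt(c(sum(r * (v - mu[1])^2) / s1,
                     sum((1 - r) * (v - mu[2])^2) / s2)), sd_floor)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  d1 <- w[1] * dnorm(v, mu[1], s[1])
  d2 <- w[2] * dnorm(v, mu[2], s[2])
  tot <- d1 + d2
  tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
  list(w = w, mu = mu, sd = s, ll = sum(log(tot)))
}

.fit2 <- function(v, n_restarts, tol, max_iter, sd_floor) {
  f1 <- .fit1(v)
  s0 <- max(f1$sd, sd_floor)
  probs <- seq(0.05, 0.45, length.out = n_restarts)
  best <- NULL
  for (p in probs) {
    init_mu <- unname(quantile(v, c(p, 1 - p)))
    fit <- .em2(v, c(0.5, 0.5), init_mu, c(s0 / 2, s0 / 2),
                tol, max_iter, sd_floor)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  # a start at the one-component solution guarantees LL2 >= LL1
  fit <- .em2(v, c(0.5, 0.5), c(f1$mean, f1$mean), c(s0, s0),
              tol, max_iter, sd_floor)
  if (fit$ll > best$ll) best <- fit
  ord <- order(best$mu)
  list(w = best$w[ord], mu = best$mu[ord], sd = best$sd[ord], ll = best$ll)
}

#' Test a CpG o/e distribution for bimodality
#'
#' Fits one- and two-component Gaussian mixtures by EM and compares them
#' with a likelihood-ratio statistic whose null distribution is obtained by
#' parametric bootstrap under the one-component fit (the LRT is not
#' chi-squared here because the mixture null sits on the parameter
#' boundary).  Because the bootstrap LRT alone over-rejects for heavy-tailed
#' data, the `"bimodal"` call additionally requires the fitted component
#' means to be separated by more than twice the pooled within-component
#' standard deviation.
#'
#' @param values numeric vector of o/e values (at least 50 finite ones).
#' @param n_boot parametric bootstrap resamples (default 200).
#' @param seed integer seed (EM restarts are deterministic; only the
#'   bootstrap draws consume randomness).
#' @param n_restarts quantile-spaced EM initialisations per fit.
#' @param tol EM log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @param sd_floor lower bound on component standard deviations, guarding
#'   against likelihood singularities.
#' @return list of class `bimodality_result`: `fit1` (mean, sd, ll), `fit2`
#'   (weights, means, sds, ll), `lrt`, `p`, `separation` (mean gap over
#'   pooled sd), `call` (`"unimodal"`/`"bimodal"`), `n`, `n_boot`.
#' @export
bimodality_test <- function(values, n_boot = 200L, seed = 1L,
                            n_restarts = 10L, tol = 1e-8, max_iter = 500L,
                            sd_floor = 1e-3) {
  v <- values[is.finite(values)]
  if (length(v) < 50L) {
    stop("need at least 50 finite values", call. = FALSE)
  }
  if (sd(v) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  f1 <- .fit1(v)
  f2 <- .fit2(v, n_restarts, tol, max_iter, sd_floor)
  lrt <- max(0, 2 * (f2$ll - f1$ll))
  n <- length(v)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      vb <- rnorm(n, f1$mean, f1$sd)
      b1 <- .fit1(vb)
      b2 <- .fit2(vb, n_restarts, tol, max_iter, sd_floor)
      max(0, 2 * (b2$ll - b1$ll))
    }, 0)
  })
  p <- (1 + sum(boot >= lrt - 1e-9)) / (n_boot + 1)
  pooled_sd <- sqrt(sum(f2$w * f2$sd^2))
  separation <- abs(diff(f2$mu)) / pooled_sd
  call_ <- if (p < 0.05 && separation > 2) "bimodal" else "unimodal"
  structure(list(fit1 = f1,
                 fit2 = f2,
                 lrt = lrt, p = p, separation = separation,
                 call = call_, n = n, n_boot = n_boot, seed = seed),
            class = "bimodality_result")
}

#' @export
print.bimodality_result <- function(x, ...) {
  cat(sprintf("Gaussian-mixture bimodality test (n = %d)\n", x$n))
  cat(sprintf("  1 component: mean %.3f, sd %.3f, logLik %.2f\n",
              x$fit1$mean, x$fit1$sd, x$fit1$ll))
  cat(sprintf("  2 components: means %.3f/%.3f, sds %.3f/%.3f, weights %.2f/%.2f, logLik %.2f\n",
              x$fit2$mu[1], x$fit2$mu[2], x$fit2$sd[1], x$fit2$sd[2],
              x$fit2$w[1], x$fit2$w[2], x$fit2$ll))
  cat(sprintf("  LRT = %.2f, bootstrap p = %.4g (%d resamples), separation = %.2f sd\n",
              x$lrt, x$p, x$n_boot, x$separation))
  cat(sprintf("  call: %s\n", x$call))
  invisible(x)
}
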