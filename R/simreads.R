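#' Bisulfite sequencing simulation settings
#'
#' Parameters of the stochastic read/pileup model shared by
#' [simulate_reads()] and [simulate_pileup()].  Coverage on placed
#' chromosomes follows `depth_model` at `mean_depth` informative reads per
#' strand-specific cytosine site; unplaced scaffolds get their own (usually
#' much deeper, overdispersed) stratum via `unplaced_mean_depth` and
#' `unplaced_depth_model`, emulating repeat-derived sequence whose many
#' genomic copies collapse onto few reference positions.
#'
#' @param mean_depth expected informative depth per site on chromosomes (> 0).
#' @param depth_model `"poisson"` or `"nb"` (negative binomial).
#' @param nb_size negative-binomial size (dispersion) parameter.
#' @param unplaced_mean_depth expected depth on unplaced scaffolds; the
#'   default, roughly fifteen-fold the chromosomal depth, stands in for
#'   repeat-derived scaffolds whose genomic copies collapse onto few
#'   reference positions.
#' @param unplaced_depth_model depth model for unplaced scaffolds
#'   (default `"nb"`).
#' @param eps_conv per-cytosine bisulfite non-conversion probability,
#'   in \[0, 1).
#' @param eps_seq per-base sequencing error probability, in \[0, 0.25);
#'   errors replace the base by one of the three alternatives uniformly.
#' @param read_length read length in bases.
#' @param seed integer seed recorded in all outputs.
#' @return list of class `seq_sim_config`.
#' @export
seq_sim_config <- function(mean_depth = 6, depth_model = c("poisson", "nb"),
                           nb_size = 0.5,
                           unplaced_mean_depth = 95,
                           unplaced_depth_model = "nb",
                           eps_conv = 0.004, eps_seq = 0.001,
                           read_length = 105L, seed = 1L) {
  depth_model <- match.arg(depth_model)
  unplaced_depth_model <- match.arg(unplaced_depth_model, c("poisson", "nb"))
  .assert_scalar_num(mean_depth, "mean_depth", 0, Inf, lo_open = TRUE)
  .assert_scalar_num(unplaced_mean_depth, "unplaced_mean_depth", 0, Inf,
                     lo_open = TRUE)
  .assert_scalar_num(eps_conv, "eps_conv", 0, 1, hi_open = TRUE)
  .assert_scalar_num(eps_seq, "eps_seq", 0, 0.25, hi_open = TRUE)
  .assert_scalar_num(nb_size, "nb_size", 0, Inf, lo_open = TRUE)
  .assert_scalar_num(read_length, "read_length", 20, Inf)
  structure(list(mean_depth = mean_depth, depth_model = depth_model,
                 nb_size = nb_size,
                 unplaced_mean_depth = unplaced_mean_depth,
                 unplaced_depth_model = unplaced_depth_model,
                 eps_conv = eps_conv, eps_seq = eps_seq,
                 read_length = as.integer(read_length),
                 seed = seed),
            class = "seq_sim_config")
}

# Emission probabilities at a cytosine site with true methylation m:
# the molecule retains C with p_C = m + (1-m) * eps_conv, then sequencing
# error moves mass uniformly to the three alternative bases.
.emission_probs <- function(m, eps_conv, eps_seq) {
  p_c <- m + (1 - m) * eps_conv
  list(
    obs_c = (1 - eps_seq) * p_c + (eps_seq / 3) * (1 - p_c),
    obs_t = (1 - eps_seq) * (1 - p_c) + (eps_seq / 3) * p_c
  )
}

.site_depths <- function(n, model, mu, nb_size) {
  if (n == 0L) return(integer(0))
  if (model == "poisson") rpois(n, mu) else rnbinom(n, size = nb_size, mu = mu)
}

#' Simulate a per-cytosine bisulfite pileup
#'
#' Draws, for every cytosine site, an informative depth from the configured
#' coverage model and multinomial base calls from the bisulfite emission
#' model: unconverted (C-state) calls with probability
#' `(1-eps_seq) * p_C + eps_seq/3 * (1-p_C)` where
#' `p_C = m + (1-m) * eps_conv`, converted (T-state) calls from the
#' complementary probability, and the remainder recorded as other.  This is
#' the marginal distribution of [call_sites()] applied to
#' [simulate_reads()] output at matched parameters, and is the fast path for
#' large simulation studies.
#'
#' @param genome a [ref_genome()].
#' @param methylome a [simulate_methylome()] table, or `NULL` for the null
#'   (fully unmethylated) methylome.
#' @param cfg a [seq_sim_config()].
#' @param contexts cytosine contexts to tabulate.
#' @return a `site_counts` `data.table`: `chrom`, `pos`, `strand`, `context`,
#'   `n_unconverted`, `n_converted`, `n_other`, `depth`, `ratio`
#'   (= C/(C+T), `NA` when no informative calls); zero-depth sites are
#'   omitted.
#' @export
simulate_pileup <- function(genome, methylome = NULL, cfg = seq_sim_config(),
                            contexts = c("CpG", "CHG", "CHH")) {
  stopifnot(inherits(genome, "ref_genome"), inherits(cfg, "seq_sim_config"))
  sites <- index_cytosines(genome, contexts)
  if (nrow(sites) == 0L) stop("genome contains no cytosines", call. = FALSE)
  sites[, m := 0]
  if (!is.null(methylome)) {
    sites[methylome, on = c("chrom", "pos", "strand"), m := i.m]
  }
  plc <- genome$placement[sites$chrom]
  n <- nrow(sites)
  res <- with_seed(cfg$seed, {
    d <- integer(n)
    is_chr <- plc == "chromosome"
    d[is_chr] <- .site_depths(sum(is_chr), cfg$depth_model, cfg$mean_depth,
                              cfg$nb_size)
    d[!is_chr] <- .site_depths(sum(!is_chr), cfg$unplaced_depth_model,
                               cfg$unplaced_mean_depth, cfg$nb_size)
    pr <- .emission_probs(sites$m, cfg$eps_conv, cfg$eps_seq)
    x <- rbinom(n, d, pr$obs_c)
    p_t_given_not_c <- pr$obs_t / (1 - pr$obs_c)
    p_t_given_not_c[!is.finite(p_t_given_not_c)] <- 0 # obs_c == 1 exactly
    conv <- rbinom(n, d - x, p_t_given_not_c)
    list(d = d, x = x, conv = conv)
  })
  sites[, `:=`(n_unconverted = res$x, n_converted = res$conv,
               n_other = res$d - res$x - res$conv, depth = res$d)]
  sites[, m := NULL]
  sites <- sites[depth > 0L]
  sites[, ratio := fifelse(n_unconverted + n_converted > 0L,
                           n_unconverted / (n_unconverted + n_converted),
                           NA_real_)]
  setattr(sites, "merged", FALSE)
  setattr(sites, "seed", cfg$seed)
  sites[]
}
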