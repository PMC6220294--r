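#' qPCR simulation design
#'
#' One target gene plus reference (housekeeping) genes, measured by
#' crossing points (Cp) in a control and a treatment group with technical
#' replicates.  Simulated Cp values follow
#' `Cp = base_cp(gene) - log_E(rel_concentration) + biological noise`,
#' where the treatment group's target concentration is multiplied by
#' `true_ratio` and reference genes are unaffected; technical replicates
#' share the biological draw and add independent noise.
#'
#' @param target,references gene names.
#' @param efficiencies named per-gene amplification factors in (1, 2.2\];
#'   default perfect doubling (E = 2) for every gene.
#' @param true_ratio fold change of the target in treatment vs control
#'   (> 0).
#' @param n_control,n_treatment biological sample counts.
#' @param n_tech technical replicates per sample (>= 1).
#' @param cp_noise_sd biological between-sample Cp noise (cycles).
#' @param tech_noise_sd technical replicate noise; defaults to a third of
#'   the biological noise.
#' @param base_cp named baseline Cp per gene; defaults to 24 for the target
#'   and 20, 20.5, ... for references.
#' @param seed integer seed.
#' @return list of class `qpcr_sim_design`.
#' @export
qpcr_sim_design <- function(target = "target",
                            references = c("ref1", "ref2"),
                            efficiencies = NULL, true_ratio = 1,
                            n_control = 6L, n_treatment = 6L, n_tech = 2L,
                            cp_noise_sd = 0.3,
                            tech_noise_sd = cp_noise_sd / 3,
                            base_cp = NULL, seed = 1L) {
  genes <- c(target, references)
  stopifnot(length(references) >= 1L, !anyDuplicated(genes))
  if (is.null(efficiencies)) {
    efficiencies <- setNames(rep(2, length(genes)), genes)
  }
  if (is.null(names(efficiencies)) || !all(genes %in% names(efficiencies))) {
    stop("`efficiencies` must be named for every gene", call. = FALSE)
  }
  if (any(efficiencies <= 1)) {
    stop("amplification efficiencies must exceed 1", call. = FALSE)
  }
  .assert_scalar_num(true_ratio, "true_ratio", 0, Inf, lo_open = TRUE)
  stopifnot(n_control >= 1L, n_treatment >= 1L, n_tech >= 1L)
  .assert_scalar_num(cp_noise_sd, "cp_noise_sd", 0, Inf)
  .assert_scalar_num(tech_noise_sd, "tech_noise_sd", 0, Inf)
  if (is.null(base_cp)) {
    base_cp <- setNames(c(24, 20 + 0.5 * (seq_along(references) - 1)), genes)
  }
  structure(list(target = target, references = references,
                 genes = genes, efficiencies = efficiencies[genes],
                 true_ratio = true_ratio, n_control = as.integer(n_control),
                 n_treatment = as.integer(n_treatment),
                 n_tech = as.integer(n_tech), cp_noise_sd = cp_noise_sd,
                 tech_noise_sd = tech_noise_sd, base_cp = base_cp[genes],
                 seed = seed),
            class = "qpcr_sim_design")
}

#' Simulate a qPCR crossing-point table
#'
#' @param design a [qpcr_sim_design()].
#' @return `data.table` of class `cp_table`: `sample_id`, `group`
#'   (`"control"`/`"treatment"`), `gene`, `tech_rep`, `cp`.
#' @export
simulate_qpcr <- function(design) {
  stopifnot(inherits(design, "qpcr_sim_design"))
  samples <- data.table(
    sample_id = c(paste0("c", seq_len(design$n_control)),
                  paste0("t", seq_len(design$n_treatment))),
    group = rep(c("control", "treatment"),
                c(design$n_control, design$n_treatment)))
  grid <- CJ(sample_id = samples$sample_id, gene = design$genes,
             sorted = FALSE)
  grid <- samples[grid, on = "sample_id"]
  res <- with_seed(design$seed, {
    rel <- fifelse(grid$group == "treatment" & grid$gene == design$target,
                   design$true_ratio, 1)
    e <- design$efficiencies[grid$gene]
    bio <- design$base_cp[grid$gene] - log(rel) / log(e) +
      rnorm(nrow(grid), 0, design$cp_noise_sd)
    tech <- lapply(seq_len(design$n_tech), function(k) {
      data.table(sample_id = grid$sample_id, group = grid$group,
                 gene = grid$gene, tech_rep = k,
                 cp = bio + rnorm(nrow(grid), 0, design$tech_noise_sd))
    })
    rbindlist(tech)
  })
  setorder(res, group, sample_id, gene, tech_rep)
  setattr(res, "class", c("cp_table", class(res)))
  setattr(res, "design", design)
  res[]
}

#' Technical-replicate quality control
#'
#' Averages technical replicates per sample x gene, discarding measurements
#' whose technical standard deviation (n-1 denominator; for a duplicate,
#' `|a-b|/sqrt(2)`) reaches `max_std` cycles.  Singleton measurements pass
#' with a warning.
#'
#' @param cp a `cp_table` (columns `sample_id`, `group`, `gene`,
#'   `tech_rep`, `cp`).
#' @param max_std exclusion threshold in Cp units (strict: kept only if
#'   sd < `max_std`).
#' @return `data.table` with `sample_id`, `group`, `gene`, `mean_cp`,
#'   `cp_sd`, `n_tech`; excluded measurements in attribute `excluded`.
#' @examples
#' tab <- data.table::data.table(sample_id = "s1", group = "control",
#'   gene = "g", tech_rep = 1:2, cp = c(20.0, 20.4))
#' qc_technical_replicates(tab)$mean_cp  # 20.2
#' @export
qc_technical_replicates <- function(cp, max_std = 0.5) {
  stopifnot(all(c("sample_id", "group", "gene", "cp") %in% names(cp)))
  if (any(cp$cp <= 0)) stop("Cp values must be positive", call. = FALSE)
  agg <- as.data.table(cp)[, .(mean_cp = mean(cp), cp_sd = sd(cp),
                               n_tech = .N),
                           by = .(sample_id, group, gene)]
  if (any(agg$n_tech == 1L)) {
    warning(sum(agg$n_tech == 1L),
            " singleton measurement(s) kept without replicate QC")
  }
  keep <- is.na(agg$cp_sd) | agg$cp_sd < max_std
  excluded <- agg[!keep]
  res <- agg[keep]
  setattr(res, "excluded", excluded[])
  setattr(res, "max_std", max_std)
  res[]
}

#' Amplification efficiency from a serial dilution curve
#'
#' Ordinary least-squares fit of Cp against log10 dilution;
#' `E = 10^(-1/slope)`, so a perfect doubling assay has slope -3.3219 and
#' E = 2.  Assays with E outside (1, 2.2\] are flagged but returned.
#'
#' @param log10_dilution,cp paired numeric vectors (>= 3 points), or a
#'   data.frame with those two columns as the first argument.
#' @param gene optional gene label carried through.
#' @return list of class `efficiency_estimate`: `gene`, `slope`, `E`, `r2`,
#'   `n`, `in_range`.
#' @examples
#' d <- seq(0, -4)             # ten-fold dilutions
#' cp <- 20 - d * 3.321928     # perfect doubling
#' efficiency_from_dilution(d, cp)$E  # 2
#' @export
efficiency_from_dilution <- function(log10_dilution, cp = NULL, gene = NA) {
  if (is.data.frame(log10_dilution)) {
    df <- log10_dilution
    log10_dilution <- df[[1]]
    cp <- df[[2]]
  }
  stopifnot(length(log10_dilution) == length(cp))
  if (length(cp) < 3L) {
    stop("need at least 3 dilution points", call. = FALSE)
  }
  fit <- lm(cp ~ log10_dilution)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("invalid assay: dilution slope must be negative", call. = FALSE)
  }
  e <- 10^(-1 / slope)
  r2 <- 1 - sum(fit$residuals^2) / sum((cp - mean(cp))^2)
  structure(list(gene = gene, slope = slope, E = e, r2 = r2,
                 n = length(cp), in_range = e > 1 && e <= 2.2),
            class = "efficiency_estimate")
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf("qPCR efficiency%s: E = %.4f (slope %.4f, r2 %.4f, %d points)%s\n",
              if (is.na(x$gene)) "" else sprintf(" [%s]", x$gene),
              x$E, x$slope, x$r2, x$n,
              if (x$in_range) "" else "  ** outside accepted range (1, 2.2] **"))
  invisible(x)
}

# -- internal: per-sample x gene mean-Cp matrix and the Pfaffl weights ------

.extract_e <- function(efficiencies, genes) {
  if (is.list(efficiencies) && !is.data.frame(efficiencies)) {
    e <- vapply(efficiencies, function(x) {
      if (inherits(x, "efficiency_estimate")) x$E else as.numeric(x)
    }, 0)
  } else {
    e <- efficiencies
  }
  if (is.null(names(e)) || !all(genes %in% names(e))) {
    stop("missing efficiency for gene(s): ",
         paste(setdiff(genes, names(e)), collapse = ", "), call. = FALSE)
  }
  e <- e[genes]
  if (any(!is.finite(e)) || any(e <= 1)) {
    stop("efficiencies must be finite and exceed 1", call. = FALSE)
  }
  e
}

.cp_matrix <- function(qc, target, references) {
  genes <- c(target, references)
  missing_genes <- setdiff(genes, unique(qc$gene))
  if (length(missing_genes)) {
    stop("gene(s) absent from the Cp table: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  wide <- dcast(as.data.table(qc)[gene %in% genes],
                sample_id + group ~ gene, value.var = "mean_cp")
  complete <- complete.cases(wide)
  if (any(!complete)) {
    warning(sum(!complete),
            " sample(s) dropped: not all genes passed QC")
    wide <- wide[complete]
  }
  for (g in c("control", "treatment")) {
    if (!any(wide$group == g)) {
      stop("group \"", g, "\" has no complete samples", call. = FALSE)
    }
  }
  M <- as.matrix(wide[, genes, with = FALSE])
  list(M = M, group = wide$group, sample_id = wide$sample_id, genes = genes)
}

# Pfaffl weights: the log ratio is a contrast of per-gene dCp values, so
# each sample contributes one scalar (its weighted Cp) and the statistic is
# a difference of group means of that scalar.
.pfaffl_weights <- function(log_e) {
  k <- length(log_e) - 1L
  c(log_e[1], -log_e[-1] / k)
}

.log_ratio <- function(M, is_control, log_e) {
  mw <- drop(M %*% .pfaffl_weights(log_e))
  mean(mw[is_control]) - mean(mw[!is_control])
}

#' Efficiency-corrected relative expression ratio (Pfaffl)
#'
#' `ratio = E_t^dCp_t / geomean_r(E_r^dCp_r)` with
#' `dCp = mean Cp(control) - mean Cp(treatment)` per gene, so target
#' up-regulation in the treatment group gives a ratio above 1.  Multiple
#' reference genes are combined by the geometric mean of their
#' normalization factors.
#'
#' @param qc QC'd measurements from [qc_technical_replicates()].
#' @param target target gene name.
#' @param references character vector of reference gene names.
#' @param efficiencies named numeric vector (or list of
#'   [efficiency_from_dilution()] results) covering every gene.
#' @return the ratio (positive scalar).
#' @export
pfaffl_ratio <- function(qc, target, references, efficiencies) {
  e <- .extract_e(efficiencies, c(target, references))
  cpm <- .cp_matrix(qc, target, references)
  exp(.log_ratio(cpm$M, cpm$group == "control", log(e)))
}

#' REST-style fixed-reallocation randomization test
#'
#' Permutes group labels jointly across all genes per biological sample and
#' recomputes the Pfaffl ratio; the two-sided p-value is the fraction of
#' reallocations whose |log ratio| is at least the observed one.  When the
#' number of distinct control/treatment reallocations is at most `n_iter`
#' they are enumerated exactly (the identity included); otherwise `n_iter`
#' random reallocations are drawn and the estimate is add-one smoothed.
#'
#' @inheritParams pfaffl_ratio
#' @param n_iter iteration budget (default 10000).
#' @param seed integer seed (used only in the Monte-Carlo branch).
#' @return list of class `randomization_result`: `p`, `ratio`, `method`
#'   (`"exact"`/`"monte-carlo"`), `n_reallocations`, `n_control`,
#'   `n_treatment`.
#' @export
randomization_test <- function(qc, target, references, efficiencies,
                               n_iter = 10000L, seed = 1L) {
  e <- .extract_e(efficiencies, c(target, references))
  log_e <- log(e)
  cpm <- .cp_matrix(qc, target, references)
  n <- nrow(cpm$M)
  n_ctrl <- sum(cpm$group == "control")
  if (n < 4L) {
    stop("need at least 4 biological samples for the randomization test",
         call. = FALSE)
  }
  mw <- drop(cpm$M %*% .pfaffl_weights(log_e))
  tot <- sum(mw)
  n_trt <- n - n_ctrl
  obs <- mean(mw[cpm$group == "control"]) - mean(mw[cpm$group != "control"])
  n_exact <- choose(n, n_ctrl)
  if (n_exact <= n_iter) {
    combos <- utils::combn(n, n_ctrl)
    sums_c <- colSums(matrix(mw[combos], nrow = n_ctrl))
    stats <- sums_c / n_ctrl - (tot - sums_c) / n_trt
    p <- mean(abs(stats) >= abs(obs) - 1e-12)
    method <- "exact"
    n_used <- n_exact
  } else {
    stats <- with_seed(seed, {
      vapply(seq_len(n_iter), function(i) {
        s <- sum(mw[sample.int(n, n_ctrl)])
        s / n_ctrl - (tot - s) / n_trt
      }, 0)
    })
    p <- (1 + sum(abs(stats) >= abs(obs) - 1e-12)) / (1 + n_iter)
    method <- "monte-carlo"
    n_used <- n_iter
  }
  structure(list(p = p, ratio = exp(obs), method = method,
                 n_reallocations = n_used, n_control = n_ctrl,
                 n_treatment = n - n_ctrl),
            class = "randomization_result")
}

#' Bootstrap percentile confidence interval for the expression ratio
#'
#' Biological samples are resampled with replacement within each group; the
#' interval is the percentile range of the recomputed ratios.
#'
#' @inheritParams pfaffl_ratio
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed.
#' @param conf coverage level (default 0.95).
#' @return list: `lower`, `upper`, `conf`, `ratio` (the point estimate).
#' @export
bootstrap_ci <- function(qc, target, references, efficiencies,
                         n_boot = 2000L, seed = 1L, conf = 0.95) {
  e <- .extract_e(efficiencies, c(target, references))
  log_e <- log(e)
  cpm <- .cp_matrix(qc, target, references)
  ic <- which(cpm$group == "control")
  it <- which(cpm$group == "treatment")
  if (length(ic) == 1L || length(it) == 1L) {
    warning("a group has a single sample: the interval is degenerate")
  }
  mw <- drop(cpm$M %*% .pfaffl_weights(log_e))
  obs <- mean(mw[ic]) - mean(mw[it])
  boots <- with_seed(seed, {
    bc <- matrix(sample.int(length(ic), n_boot * length(ic), replace = TRUE),
                 nrow = n_boot)
    bt <- matrix(sample.int(length(it), n_boot * length(it), replace = TRUE),
                 nrow = n_boot)
    rowMeans(matrix(mw[ic][bc], nrow = n_boot)) -
      rowMeans(matrix(mw[it][bt], nrow = n_boot))
  })
  qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  list(lower = exp(qs[1]), upper = exp(qs[2]), conf = conf,
       ratio = exp(obs))
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, k * p)` for a declared family of `k` comparisons
#' (`k` may exceed the number of p-values supplied, as when the same control
#' is compared to several treatment groups analysed separately).
#'
#' @param pvals p-values in \[0, 1\].
#' @param k family size; must be at least `length(pvals)`.
#' @return adjusted p-values, capped at 1.
#' @export
adjust_bonferroni <- function(pvals, k = length(pvals)) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (k < length(pvals)) {
    stop("family size `k` cannot be smaller than the number of p-values",
         call. = FALSE)
  }
  pmin(1, k * pvals)
}

#' Full relative-expression analysis for one target
#'
#' Technical-replicate QC, Pfaffl ratio over the reference genes,
#' fixed-reallocation randomization p-value, bootstrap percentile interval
#' and Bonferroni adjustment, mirroring the columns of a REST-style results
#' table.
#'
#' @param cp raw `cp_table` (with technical replicates).
#' @param target,references,efficiencies as in [pfaffl_ratio()].
#' @param max_std technical-replicate QC threshold.
#' @param n_iter,n_boot,seed,conf resampling settings.
#' @param bonferroni_k family size for the Bonferroni adjustment.
#' @return list of class `expression_result`.
#' @export
relative_expression <- function(cp, target, references, efficiencies,
                                max_std = 0.5, n_iter = 10000L,
                                n_boot = 2000L, seed = 1L, conf = 0.95,
                                bonferroni_k = 1L) {
  qc <- qc_technical_replicates(cp, max_std)
  ratio <- pfaffl_ratio(qc, target, references, efficiencies)
  rt <- randomization_test(qc, target, references, efficiencies,
                           n_iter = n_iter, seed = seed)
  ci <- bootstrap_ci(qc, target, references, efficiencies,
                     n_boot = n_boot, seed = seed + 1L, conf = conf)
  structure(list(target = target, references = references,
                 ratio = ratio, ci_lower = ci$lower, ci_upper = ci$upper,
                 conf = conf, p = rt$p,
                 p_adjusted = adjust_bonferroni(rt$p, bonferroni_k),
                 p_method = rt$method,
                 n_control = rt$n_control, n_treatment = rt$n_treatment,
                 qc = qc),
            class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("Relative expression of %s (vs %s)\n", x$target,
              paste(x$references, collapse = ", ")))
  cat(sprintf("  ratio %.3f, %d%% CI %.3f-%.3f, n = %d/%d\n",
              x$ratio, round(100 * x$conf), x$ci_lower, x$ci_upper,
              x$n_control, x$n_treatment))
  cat(sprintf("  p = %.4g (%s randomization), Bonferroni-adjusted p = %.4g\n",
              x$p, x$p_method, x$p_adjusted))
  invisible(x)
}
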