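cp_row <- function(sample_id, group, gene, cps) {
  data.table::data.table(sample_id = sample_id, group = group, gene = gene,
                         tech_rep = seq_along(cps), cp = cps)
}

test_that("technical-replicate QC uses the n-1 standard deviation, strictly", {
  tab <- rbind(cp_row("s1", "control", "g", c(20.0, 20.4)),
               cp_row("s2", "control", "g", c(20.0, 21.0)))
  qc <- qc_technical_replicates(tab)
  expect_equal(nrow(qc), 1L)
  expect_equal(qc$mean_cp, 20.2)
  expect_equal(qc$cp_sd, 0.4 / sqrt(2), tolerance = 1e-12)
  excl <- attr(qc, "excluded")
  expect_equal(excl$sample_id, "s2")
  expect_equal(excl$cp_sd, 1 / sqrt(2), tolerance = 1e-12)

  # a pair at exactly the threshold is excluded (strict <)
  at <- cp_row("s3", "control", "g", c(20.0, 20.7))
  expect_equal(nrow(qc_technical_replicates(at, max_std = sd(c(20, 20.7)))),
               0L)

  expect_warning(qcs <- qc_technical_replicates(
    cp_row("s4", "control", "g", 20.0)), "singleton")
  expect_equal(qcs$mean_cp, 20.0)

  expect_error(qc_technical_replicates(cp_row("s5", "control", "g",
                                              c(-1, 20))), "positive")
})

test_that("dilution-curve efficiency follows 10^(-1/slope) and flags bad assays", {
  d <- 0:-4
  eff <- efficiency_from_dilution(d, 20 - d * log2(10)) # perfect doubling
  expect_equal(eff$E, 2, tolerance = 1e-9)
  expect_equal(eff$slope, -log2(10), tolerance = 1e-9)
  expect_true(eff$in_range)
  expect_equal(eff$r2, 1, tolerance = 1e-12)

  # slope -1 gives E = 10, outside the accepted range but returned
  eff10 <- efficiency_from_dilution(d, 20 - d * 1)
  expect_equal(eff10$E, 10, tolerance = 1e-9)
  expect_false(eff10$in_range)

  expect_error(efficiency_from_dilution(d, rep(20, 5) + d), "negative")
  expect_error(efficiency_from_dilution(0:-1, c(20, 23)), "3")

  # noisy series against the normal-equations oracle
  set.seed(3)
  x <- rep(0:-4, each = 2)
  y <- 21 - 3.4 * x + rnorm(10, 0, 0.2)
  eff <- efficiency_from_dilution(x, y)
  beta <- solve(crossprod(cbind(1, x)), crossprod(cbind(1, x), y))
  expect_equal(eff$slope, beta[2], tolerance = 1e-9)
})

test_that("Pfaffl ratios obey identity, geometric-mean reference combination and invariances", {
  mk_qc <- function(cp_by_gene_group) {
    rows <- list()
    for (g in names(cp_by_gene_group)) {
      v <- cp_by_gene_group[[g]]
      rows[[g]] <- data.table::data.table(
        sample_id = c("c1", "c2", "t1", "t2"),
        group = c("control", "control", "treatment", "treatment"),
        gene = g, mean_cp = c(v[1], v[1], v[2], v[2]),
        cp_sd = 0, n_tech = 2L)
    }
    data.table::rbindlist(rows)
  }
  e2 <- c(target = 2, ref1 = 2, ref2 = 2)

  # all dCp = 0: ratio 1 exactly
  qc <- mk_qc(list(target = c(24, 24), ref1 = c(20, 20), ref2 = c(21, 21)))
  expect_equal(pfaffl_ratio(qc, "target", c("ref1", "ref2"), e2), 1)

  # E_t = 2, dCp_t = 1, single neutral reference: ratio 2
  qc <- mk_qc(list(target = c(25, 24), ref1 = c(20, 20)))
  expect_equal(pfaffl_ratio(qc, "target", "ref1", e2[1:2]), 2)

  # geometric mean across references: dCp_r of 1 and 0 gives 1/sqrt(2)
  qc <- mk_qc(list(target = c(24, 24), ref1 = c(21, 20), ref2 = c(20, 20)))
  expect_equal(pfaffl_ratio(qc, "target", c("ref1", "ref2"), e2),
               1 / sqrt(2), tolerance = 1e-12)

  # shift invariance: adding a constant to one gene in both groups
  qc1 <- mk_qc(list(target = c(25, 23.4), ref1 = c(20.2, 20.9),
                    ref2 = c(22, 21.5)))
  qc2 <- data.table::copy(qc1)[gene == "ref1", mean_cp := mean_cp + 3.7]
  expect_equal(pfaffl_ratio(qc1, "target", c("ref1", "ref2"), e2),
               pfaffl_ratio(qc2, "target", c("ref1", "ref2"), e2),
               tolerance = 1e-12)

  # the target as its own reference: self-normalization to 1
  expect_equal(pfaffl_ratio(qc1, "target", "target", e2), 1)

  expect_error(pfaffl_ratio(qc1, "target", "ref9", e2), "absent|missing")
  expect_error(pfaffl_ratio(qc1, "target", "ref1", c(target = 2)), "missing")
})

test_that("zero-noise simulation recovery is exact and intervals collapse", {
  d <- qpcr_sim_design(true_ratio = 3.5, cp_noise_sd = 0,
                       efficiencies = c(target = 1.9, ref1 = 2, ref2 = 1.8),
                       seed = 4)
  qc <- qc_technical_replicates(simulate_qpcr(d))
  expect_equal(pfaffl_ratio(qc, "target", c("ref1", "ref2"),
                            d$efficiencies), 3.5, tolerance = 1e-9)
  ci <- suppressWarnings(bootstrap_ci(qc, "target", c("ref1", "ref2"),
                                      d$efficiencies, n_boot = 200, seed = 1))
  expect_equal(ci$lower, 3.5, tolerance = 1e-9)
  expect_equal(ci$upper, 3.5, tolerance = 1e-9)
})

test_that("randomization test is exact for small designs and matches enumeration", {
  d <- qpcr_sim_design(true_ratio = 2.5, cp_noise_sd = 0.2, n_control = 3,
                       n_treatment = 3, seed = 6)
  qc <- qc_technical_replicates(simulate_qpcr(d))
  rt <- randomization_test(qc, "target", c("ref1", "ref2"), d$efficiencies)
  expect_equal(rt$method, "exact")
  expect_equal(rt$n_reallocations, choose(6, 3))

  # independent enumeration over all 20 label assignments
  wide <- data.table::dcast(qc, sample_id + group ~ gene,
                            value.var = "mean_cp")
  M <- as.matrix(wide[, c("target", "ref1", "ref2"), with = FALSE])
  ratio_for <- function(ctrl_idx) {
    dcp <- colMeans(M[ctrl_idx, , drop = FALSE]) -
      colMeans(M[-ctrl_idx, , drop = FALSE])
    log(2) * dcp[1] - mean(log(2) * dcp[2:3])
  }
  obs <- ratio_for(which(wide$group == "control"))
  all_stats <- apply(utils::combn(6, 3), 2, ratio_for)
  p_oracle <- mean(abs(all_stats) >= abs(obs) - 1e-12)
  expect_equal(rt$p, p_oracle, tolerance = 1e-12)

  # identical groups with no noise: nothing to detect
  d0 <- qpcr_sim_design(true_ratio = 1, cp_noise_sd = 0, seed = 7)
  qc0 <- qc_technical_replicates(simulate_qpcr(d0))
  rt0 <- randomization_test(qc0, "target", c("ref1", "ref2"),
                            d0$efficiencies)
  expect_gte(rt0$p, 0.9)

  # a strong effect at low noise is detected
  d4 <- qpcr_sim_design(true_ratio = 4, cp_noise_sd = 0.05, seed = 8)
  qc4 <- qc_technical_replicates(simulate_qpcr(d4))
  expect_lte(randomization_test(qc4, "target", c("ref1", "ref2"),
                                d4$efficiencies)$p, 0.01)

  expect_error(randomization_test(
    qc[sample_id %in% c("c1", "t1")], "target", c("ref1", "ref2"),
    d$efficiencies), "4")
})

test_that("Bonferroni adjustment multiplies, caps and validates", {
  expect_equal(adjust_bonferroni(c(0.01, 0.04), k = 2), c(0.02, 0.08))
  expect_equal(adjust_bonferroni(0.9, k = 4), 1)
  expect_equal(adjust_bonferroni(0.3, k = 1), 0.3)
  expect_error(adjust_bonferroni(c(0.1, 0.2), k = 1), "family")
  expect_error(adjust_bonferroni(1.2), "0, 1")
})

test_that("the full relative-expression wrapper reports a coherent table-style result", {
  d <- qpcr_sim_design(true_ratio = 2, cp_noise_sd = 0.2, seed = 9)
  res <- relative_expression(simulate_qpcr(d), "target", c("ref1", "ref2"),
                             d$efficiencies, n_boot = 300, seed = 2,
                             bonferroni_k = 3)
  expect_s3_class(res, "expression_result")
  expect_gt(res$ratio, 1)
  expect_lte(res$ci_lower, res$ratio)
  expect_gte(res$ci_upper, res$ratio)
  expect_equal(res$p_adjusted, min(1, 3 * res$p))
  expect_output(print(res), "Relative expression")
})
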