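make_counts <- function(x, d, context = "CpG", chrom = "chr1",
                        strand = "+", pos = NULL) {
  n <- length(x)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  tab <- data.table::data.table(
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    strand = rep_len(strand, n), context = rep_len(context, n),
    n_unconverted = as.integer(x), n_converted = as.integer(d - x),
    n_other = 0L, depth = as.integer(d),
    ratio = ifelse(d > 0, x / d, NA_real_))
  data.table::setattr(tab, "merged", FALSE)
  tab[]
}

test_that("conversion rate pools base calls, not sites", {
  tab <- make_counts(c(41L, 0L), c(5000L, 5000L))
  cs <- estimate_conversion_rate(tab)
  expect_equal(cs$conversion_rate, 9959 / 10000)
  expect_equal(100 * cs$conversion_rate, 99.59)
  expect_equal(cs$total_unconverted, 41)

  expect_equal(estimate_conversion_rate(make_counts(0L, 100L))$conversion_rate, 1)
  expect_error(estimate_conversion_rate(make_counts(integer(0), integer(0))),
               "empty")

  # scope filters before pooling
  tab2 <- rbind(make_counts(10L, 100L, context = "CpG"),
                make_counts(0L, 100L, context = "CHH", pos = 55L))
  expect_equal(estimate_conversion_rate(tab2, "non-CpG")$conversion_rate, 1)
  expect_equal(estimate_conversion_rate(tab2, "CpG")$conversion_rate, 0.9)
  expect_equal(estimate_conversion_rate(tab2, "all")$conversion_rate,
               190 / 200)
})

test_that("unconverted-site selection matches a brute-force filter", {
  expect_equal(nrow(select_unconverted_sites(make_counts(c(0L, 0L),
                                                         c(6L, 8L)))), 0L)
  one <- select_unconverted_sites(make_counts(1L, 6L))
  expect_equal(nrow(one), 1L)
  expect_equal(one$proportion, 1 / 6, tolerance = 1e-12)

  rt <- random_sites_table(80, seed = 41)
  sel <- select_unconverted_sites(rt, min_unconverted = 2L)
  df <- as.data.frame(rt)
  keep <- df[df$n_unconverted >= 2L, c("chrom", "pos", "strand")]
  expect_equal(nrow(sel), nrow(keep))
  expect_identical(paste(sel$chrom, sel$pos, sel$strand),
                   paste(keep$chrom, keep$pos, keep$strand))
  # the two summary statistics answer different questions
  expect_equal(attr(sel, "mean_site_proportion"),
               mean(df$n_unconverted[df$n_unconverted >= 2L] /
                      df$depth[df$n_unconverted >= 2L]))
  expect_equal(attr(sel, "pooled_proportion"),
               sum(df$n_unconverted[df$n_unconverted >= 2L]) /
                 sum(df$depth[df$n_unconverted >= 2L]))
})

test_that("replicate intersection equals a nested-loop join oracle", {
  t1 <- select_unconverted_sites(make_counts(1L, 5L, pos = 10L))
  t2 <- select_unconverted_sites(make_counts(1L, 10L, pos = 10L))
  sh <- intersect_replicates(t1, t2)
  expect_equal(nrow(sh), 1L)
  expect_equal(sh$pooled_proportion, 2 / 15, tolerance = 1e-12)
  expect_equal(sh$combined_depth, 15L)

  # disjoint sites give an empty table
  t3 <- select_unconverted_sites(make_counts(1L, 5L, pos = 99L))
  expect_equal(nrow(intersect_replicates(t1, t3)), 0L)

  # mixed strand-merge modes are refused
  t4 <- data.table::copy(t1); data.table::setattr(t4, "merged", TRUE)
  expect_error(intersect_replicates(t1, t4), "merge")

  # random tables against the oracle
  a <- select_unconverted_sites(random_sites_table(70, seed = 51))
  b <- select_unconverted_sites(random_sites_table(70, seed = 52))
  sh <- intersect_replicates(a, b)
  or <- join_oracle(a, b)
  expect_equal(nrow(sh), nrow(or))
  expect_identical(paste(sh$chrom, sh$pos, sh$strand),
                   paste(or$chrom, or$pos, or$strand))
  expect_equal(sh$x1, or$x1)
  expect_equal(sh$x2, or$x2)
  expect_equal(sh$pooled_proportion,
               (or$x1 + or$x2) / (or$depth1 + or$depth2))

  # TSV export carries the scatter column on the log10 depth scale
  f <- tempfile(fileext = ".tsv")
  write_shared_tsv(sh, f)
  back <- data.table::fread(f)
  expect_equal(nrow(back), nrow(sh))
  expect_equal(back$log10_combined_depth, log10(sh$combined_depth))
})

test_that("placement partition reproduces printed and derived percentages", {
  g <- ref_genome(c(chr1 = strrep("ACGT", 300),
                    scaffold1 = strrep("ACGT", 300)),
                  c("chromosome", "unplaced"))
  sh <- data.table::data.table(
    chrom = rep(c("chr1", "scaffold1"), c(84L, 954L)),
    pos = 2L, strand = "+")
  res <- partition_by_placement(sh, g)
  expect_equal(res$n_placed, 84L)
  expect_equal(res$n_total, 1038L)
  expect_equal(res$placed_percent, 8.1)

  all_placed <- partition_by_placement(sh[chrom == "chr1"], g)
  expect_equal(all_placed$placed_percent, 100.0)
  expect_equal(partition_by_placement(sh[c(1, 100, 200)], g)$placed_percent,
               33.3)

  expect_error(partition_by_placement(sh[0], g), "empty")
  bad <- data.table::data.table(chrom = "chrZ", pos = 1L, strand = "+")
  expect_error(partition_by_placement(bad, g), "unknown")
})

test_that("Spearman midrank rho matches hand computation and handles edges", {
  tab <- data.frame(combined_depth = c(2, 4, 4, 10),
                    pooled_proportion = c(0.5, 0.25, 0.3, 0.1))
  r <- spearman_coverage_correlation(tab)
  expect_equal(r$rho, -4.5 / sqrt(4.5 * 5), tolerance = 1e-12)
  expect_equal(round(r$rho, 4), -0.9487)

  # proportions exactly 1/depth: perfect monotone decrease
  d <- c(2, 3, 5, 8, 13, 21)
  r1 <- spearman_coverage_correlation(
    data.frame(combined_depth = d, pooled_proportion = 1 / d))
  expect_equal(r1$rho, -1)

  expect_error(spearman_coverage_correlation(
    data.frame(combined_depth = 1:5, pooled_proportion = rep(0.2, 5))),
    "zero variance")
  expect_error(spearman_coverage_correlation(
    data.frame(combined_depth = 1:2, pooled_proportion = 2:1)), "3")
})

test_that("exact Spearman permutation p equals full-enumeration oracle up to n = 8", {
  set.seed(61)
  cases <- list(
    list(x = c(3, 1, 4, 1), y = c(5, 9, 2, 6)),            # n = 4, tie in x
    list(x = rnorm(5), y = rnorm(5)),
    list(x = c(1, 2, 2, 3, 4, 4), y = rnorm(6)),           # ties
    list(x = rnorm(7), y = rnorm(7)),
    list(x = rnorm(8), y = sample(1:8))
  )
  for (cs in cases) {
    r <- spearman_coverage_correlation(
      data.frame(combined_depth = cs$x, pooled_proportion = cs$y))
    o <- spearman_oracle(cs$x, cs$y)
    expect_equal(r$rho, o$rho, tolerance = 1e-12)
    expect_equal(r$p, o$p, tolerance = 1e-12)
    expect_equal(r$method, "exact permutation")
  }
  # above the exact range the t approximation agrees with stats::cor.test
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  r <- spearman_coverage_correlation(
    data.frame(combined_depth = x, pooled_proportion = y))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  expect_equal(r$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(r$p, ct$p.value, tolerance = 1e-9)
})

test_that("chance-overlap expectation matches closed form and simulation", {
  expect_equal(expected_chance_overlap(1, 1, 0.5)$expected, 0.25)
  expect_equal(expected_chance_overlap(c(3, 7), c(2, 4), 0)$expected, 0)

  # Monte-Carlo oracle over 200 heterogeneous sites
  set.seed(71)
  d1 <- sample(1:6, 200, TRUE); d2 <- sample(1:6, 200, TRUE)
  eps <- 0.15
  exp_res <- expected_chance_overlap(d1, d2, eps)
  n_rep <- 400L
  counts <- vapply(seq_len(n_rep), function(i) {
    sum(rbinom(200, d1, eps) >= 1 & rbinom(200, d2, eps) >= 1)
  }, 0)
  se <- sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - exp_res$expected), 3 * se)
  # the Poisson-binomial sd is close to the empirical one
  expect_lt(abs(sd(counts) - exp_res$sd), 0.15 * exp_res$sd + 0.2)
})

test_that("genuinely methylated sites keep their proportion at any depth", {
  g <- simulate_genome(1, 1, chrom_length = 60000, unplaced_length = 10000,
                       gc = 0.4, cpg_oe = 1.0, seed = 81)
  meth <- simulate_methylome(g, "uniform", m = 0.8)
  eps_c <- 0.004; eps_s <- 0.001
  mk <- function(s) simulate_pileup(g, meth, seq_sim_config(
    mean_depth = 6, eps_conv = eps_c, eps_seq = eps_s, seed = s),
    contexts = "CpG")
  u1 <- select_unconverted_sites(mk(82))
  u2 <- select_unconverted_sites(mk(83))
  sh <- intersect_replicates(u1, u2)

  # pooled unconverted fraction sits at the error-adjusted emission rate
  p_c <- 0.8 + 0.2 * eps_c
  p_obs_c <- (1 - eps_s) * p_c + (eps_s / 3) * (1 - p_c)
  n_calls <- sum(sh$combined_depth)
  se <- sqrt(p_obs_c * (1 - p_obs_c) / n_calls)
  expect_lt(abs(sum(sh$x1 + sh$x2) / n_calls - p_obs_c), 3 * se)

  # and shows no artifact-style coverage dependence
  r <- spearman_coverage_correlation(sh)
  expect_gt(r$rho, -0.8)
})

test_that("the verdict rule applies the recorded thresholds mechanically", {
  conv_good <- structure(list(total_unconverted = 40, total_converted = 9960,
                              conversion_rate = 0.996, scope = "all",
                              n_sites = 100, per_context = NULL),
                         class = "conversion_summary")
  conv_bad <- structure(list(total_unconverted = 1000, total_converted = 9000,
                             conversion_rate = 0.90, scope = "all",
                             n_sites = 100, per_context = NULL),
                        class = "conversion_summary")
  # shared sites at high depth: pooled fraction 40/6000 = 0.0067, below
  # twice the global non-conversion rate of 0.004
  shared <- data.table::data.table(
    chrom = "chr1", pos = seq_len(20) * 2L, strand = "+", context = "CpG",
    depth1 = 150L, x1 = 1L, depth2 = 150L, x2 = 1L,
    pooled_proportion = 2 / 300, combined_depth = 300L)
  corr_strong <- structure(list(rho = -0.92, n = 20, p = 1e-6,
                                method = "t-approximation"),
                           class = "correlation_result")
  rep1 <- assess_methylation(list(conv_good, conv_good), shared, corr_strong)
  expect_equal(rep1$verdict, "absent")

  # poor conversion with an otherwise null pattern is inconclusive
  rep2 <- assess_methylation(list(conv_bad, conv_bad), shared, corr_strong)
  expect_equal(rep2$verdict, "inconclusive")

  # heavy shared-site non-conversion without the artifact correlation
  shared_hot <- data.table::copy(shared)
  shared_hot[, `:=`(x1 = 140L, x2 = 140L, pooled_proportion = 280 / 300)]
  corr_flat <- structure(list(rho = -0.1, n = 20, p = 0.4,
                              method = "t-approximation"),
                         class = "correlation_result")
  rep3 <- assess_methylation(list(conv_good, conv_good), shared_hot, corr_flat)
  expect_equal(rep3$verdict, "present")

  expect_error(assess_methylation(list(), shared, corr_strong), "missing")
  expect_error(assess_methylation(list(conv_good, conv_good), NULL,
                                  corr_strong), "missing")

  # verdict is a pure function of evidence: thresholds echoed in the report
  expect_equal(rep1$thresholds$min_conversion, 0.995)
  expect_true(any(grepl("rho", rep1$evidence)))

  # JSON serialisation round-trips the verdict
  f <- tempfile(fileext = ".json")
  write_report_json(rep1, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$verdict, "absent")
  expect_equal(parsed$schema, "methdx-diagnostic-1")
})
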