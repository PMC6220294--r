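#' Pooled bisulfite conversion rate
#'
#' The fraction of informative base calls (C + T states) that were converted,
#' pooled over base calls rather than averaged over sites, optionally
#' restricted to a context scope.  On fully unmethylated DNA this estimates
#' `1 - eps_conv` (up to sequencing error); the customary check restricts to
#' non-CpG cytosines, which are unmethylated in almost all animal genomes.
#'
#' @param sites a `site_counts` table.
#' @param scope `"all"` cytosines, `"non-CpG"` only, or `"CpG"` only.
#' @return list of class `conversion_summary`: `total_unconverted`,
#'   `total_converted`, `conversion_rate`, `scope`, `n_sites` and a
#'   `per_context` breakdown table.
#' @examples
#' tab <- data.table::data.table(chrom = "c", pos = 1L, strand = "+",
#'   context = "CpG", n_unconverted = 41L, n_converted = 9959L,
#'   n_other = 0L, depth = 10000L, ratio = 41 / 10000)
#' estimate_conversion_rate(tab)$conversion_rate  # 0.9959
#' @export
estimate_conversion_rate <- function(sites,
                                     scope = c("all", "non-CpG", "CpG")) {
  scope <- match.arg(scope)
  if (nrow(sites) == 0L) {
    stop("empty site table: no base calls to estimate a conversion rate from",
         call. = FALSE)
  }
  sub <- switch(scope,
                "all" = sites,
                "non-CpG" = sites[context != "CpG"],
                "CpG" = sites[context == "CpG"])
  tot_u <- sum(as.numeric(sub$n_unconverted))
  tot_c <- sum(as.numeric(sub$n_converted))
  if (tot_u + tot_c == 0) {
    stop("no informative base calls in the requested scope", call. = FALSE)
  }
  per_ctx <- sub[, .(n_unconverted = sum(as.numeric(n_unconverted)),
                     n_converted = sum(as.numeric(n_converted)),
                     conversion_rate = sum(as.numeric(n_converted)) /
                       pmax(sum(as.numeric(n_converted)) +
                              sum(as.numeric(n_unconverted)), 1)),
                 by = context]
  structure(list(total_unconverted = tot_u, total_converted = tot_c,
                 conversion_rate = tot_c / (tot_c + tot_u),
                 scope = scope, n_sites = nrow(sub),
                 per_context = per_ctx[]),
            class = "conversion_summary")
}

#' @export
print.conversion_summary <- function(x, ...) {
  cat(sprintf("Bisulfite conversion rate (%s scope): %.2f%% (%s converted / %s unconverted calls)\n",
              x$scope, 100 * x$conversion_rate,
              format(x$total_converted, big.mark = ","),
              format(x$total_unconverted, big.mark = ",")))
  invisible(x)
}

#' Sites with residual unconverted cytosines
#'
#' Filters a call table to the sites carrying at least `min_unconverted`
#' C-state calls — the candidate methylation marks.  Two summary statistics
#' are attached because they answer different questions: the mean per-site
#' proportion (each site weighted equally) and the pooled base-call
#' proportion (deep sites weigh more).
#'
#' @param sites a `site_counts` table.
#' @param min_unconverted minimum unconverted calls per retained site.
#' @return `data.table` with `chrom`, `pos`, `strand`, `context`, `depth`,
#'   `n_unconverted`, `proportion = n_unconverted/depth`; attributes
#'   `mean_site_proportion`, `pooled_proportion`, `min_unconverted`,
#'   `merged`.
#' @export
select_unconverted_sites <- function(sites, min_unconverted = 1L) {
  res <- sites[n_unconverted >= min_unconverted,
               .(chrom, pos, strand, context, depth, n_unconverted)]
  res[, proportion := n_unconverted / depth]
  setattr(res, "mean_site_proportion",
          if (nrow(res)) mean(res$proportion) else NA_real_)
  setattr(res, "pooled_proportion",
          if (nrow(res)) sum(res$n_unconverted) / sum(res$depth) else NA_real_)
  setattr(res, "min_unconverted", min_unconverted)
  setattr(res, "merged", isTRUE(attr(sites, "merged")))
  res[]
}

#' Intersect partially unconverted sites across replicates
#'
#' Inner join on (chrom, pos, strand): the sites that escaped conversion in
#' BOTH replicates.  Independent artifacts rarely recur, so this table is
#' small for clean libraries; genuine methylation reproduces.
#'
#' @param t1,t2 tables from [select_unconverted_sites()], produced in the
#'   same strand-merge mode.
#' @return `data.table` of class `shared_sites`: `chrom`, `pos`, `strand`,
#'   `context`, `depth1`, `x1`, `depth2`, `x2`,
#'   `pooled_proportion = (x1+x2)/(depth1+depth2)`, `combined_depth`.
#' @export
intersect_replicates <- function(t1, t2) {
  m1 <- attr(t1, "merged"); m2 <- attr(t2, "merged")
  if (!is.null(m1) && !is.null(m2) && !identical(m1, m2)) {
    stop("replicate tables use different CpG strand-merge modes",
         call. = FALSE)
  }
  a <- t1[, .(chrom, pos, strand, context, depth1 = depth,
              x1 = n_unconverted)]
  b <- t2[, .(chrom, pos, strand, depth2 = depth, x2 = n_unconverted)]
  res <- a[b, on = c("chrom", "pos", "strand"), nomatch = NULL]
  res[, `:=`(pooled_proportion = (x1 + x2) / (depth1 + depth2),
             combined_depth = depth1 + depth2)]
  setorder(res, chrom, pos, strand)
  setattr(res, "merged", isTRUE(m1))
  res[]
}

#' Partition shared sites by assembly placement
#'
#' How many replicate-shared unconverted sites sit on assembled chromosomes
#' versus unplaced scaffolds.  Artifact sites concentrate in repeat-derived
#' unplaced sequence, so a small placed fraction argues against genuine
#' methylation.
#'
#' @param shared a [intersect_replicates()] table (must be non-empty).
#' @param genome the [ref_genome()] supplying placement flags.
#' @return list: `n_placed`, `n_unplaced`, `n_total`, `placed_fraction`
#'   (raw) and `placed_percent` (percentage rounded to one decimal).
#' @examples
#' g <- ref_genome(c(chr1 = "ACGT", scaffold1 = "ACGT"),
#'                 c("chromosome", "unplaced"))
#' sh <- data.table::data.table(
#'   chrom = rep(c("chr1", "scaffold1"), c(84, 954)), pos = 2L, strand = "+")
#' partition_by_placement(sh, g)$placed_percent  # 8.1
#' @export
partition_by_placement <- function(shared, genome) {
  stopifnot(inherits(genome, "ref_genome"))
  if (nrow(shared) == 0L) {
    stop("empty shared-site table: nothing to partition", call. = FALSE)
  }
  bad <- setdiff(unique(shared$chrom), names(genome$sequences))
  if (length(bad)) {
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  plc <- genome$placement[shared$chrom]
  n_placed <- sum(plc == "chromosome")
  n_total <- nrow(shared)
  list(n_placed = n_placed, n_unplaced = n_total - n_placed,
       n_total = n_total, placed_fraction = n_placed / n_total,
       placed_percent = round(100 * n_placed / n_total, 1))
}

#' Expected replicate overlap under independent artifacts
#'
#' If unconverted calls arise independently per base with probability
#' `eps_eff`, a site of depths `d1`, `d2` carries at least one in both
#' replicates with probability `(1-(1-eps_eff)^d1) * (1-(1-eps_eff)^d2)`.
#' Summed over the site universe this gives the chance-overlap expectation;
#' an observed shared-site count compatible with it means the overlap itself
#' carries no evidence of methylation.
#'
#' @param d1,d2 per-site informative depths over a common site universe
#'   (equal length, aligned).
#' @param eps_eff per-base unconverted probability; a scalar or a length-2
#'   vector giving each replicate its own rate (conversion failure and
#'   sequencing error folded together).
#' @return list of class `overlap_expectation`: `expected`, `sd` (the
#'   Poisson-binomial standard deviation) and `n_sites`.
#' @examples
#' expected_chance_overlap(1, 1, 0.5)$expected  # 0.25
#' @export
expected_chance_overlap <- function(d1, d2, eps_eff) {
  stopifnot(length(d1) == length(d2))
  if (any(eps_eff < 0) || any(eps_eff >= 1) || !length(eps_eff) %in% 1:2) {
    stop("`eps_eff` must be one or two values in [0, 1)", call. = FALSE)
  }
  e1 <- eps_eff[1]
  e2 <- if (length(eps_eff) == 2L) eps_eff[2] else eps_eff[1]
  p <- (1 - (1 - e1)^d1) * (1 - (1 - e2)^d2)
  structure(list(expected = sum(p), sd = sqrt(sum(p * (1 - p))),
                 n_sites = length(p)),
            class = "overlap_expectation")
}

#' Write a shared-site table as TSV
#'
#' Optionally adds `log10_combined_depth` so the file doubles as scatter-plot
#' data for the coverage-versus-proportion diagnostic.
#'
#' @param shared an [intersect_replicates()] table.
#' @param file output path.
#' @param scatter add the log10 depth column (default TRUE).
#' @return `file`, invisibly.
#' @export
write_shared_tsv <- function(shared, file, scatter = TRUE) {
  out <- copy(shared)
  if (scatter && nrow(out)) {
    out[, log10_combined_depth := log10(combined_depth)]
  }
  fwrite(out, file, sep = "\t")
  invisible(file)
}

#' Default thresholds for the methylation-presence verdict
#'
#' Chosen to separate a clean unmethylated library (conversion above 99.5%,
#' strong negative coverage correlation, shared-site non-conversion at the
#' global artifact level) from even modest genuine methylation at moderate
#' depth; every threshold is echoed into the report.
#'
#' @param min_conversion minimum per-replicate conversion rate for "absent".
#' @param max_rho Spearman rho must be at or below this for the artifact
#'   signature.
#' @param max_rho_p the rho test's p-value must be below this.
#' @param absent_fold "absent" requires the pooled shared-site unconverted
#'   fraction at or below this multiple of the global non-conversion rate.
#' @param present_fold "present" requires at least this multiple.
#' @return named list.
#' @export
diag_thresholds <- function(min_conversion = 0.995, max_rho = -0.8,
                            max_rho_p = 0.01, absent_fold = 2,
                            present_fold = 10) {
  list(min_conversion = min_conversion, max_rho = max_rho,
       max_rho_p = max_rho_p, absent_fold = absent_fold,
       present_fold = present_fold)
}

#' Formal absent/present/inconclusive verdict
#'
#' Encodes the inference chain for deciding whether residual unconverted
#' CpGs reflect methylation: "absent" needs high conversion in every
#' replicate, the negative coverage-proportion correlation of an artifact
#' process, and replicate-shared sites no more unconverted than about the
#' global artifact rate; "present" needs shared-site non-conversion far
#' above the artifact rate without the artifact's coverage signature;
#' anything else is "inconclusive".  The verdict is a pure function of the
#' recorded evidence and thresholds, both echoed into the report.
#'
#' @param conversion list of `conversion_summary` objects, one per replicate.
#' @param shared the [intersect_replicates()] table.
#' @param correlation a [spearman_coverage_correlation()] result, or `NULL`
#'   when undefined (fewer than 3 shared sites).
#' @param thresholds a [diag_thresholds()] list.
#' @param placement optional [partition_by_placement()] summary.
#' @param expected_overlap optional [expected_chance_overlap()] result.
#' @param calling_mode free-text note on how sites were called (for example
#'   `"per-strand"` or `"merged-dinucleotide"`).
#' @return list of class `diagnostic_report`.
#' @export
assess_methylation <- function(conversion, shared, correlation = NULL,
                               thresholds = diag_thresholds(),
                               placement = NULL, expected_overlap = NULL,
                               calling_mode = "per-strand") {
  if (inherits(conversion, "conversion_summary")) conversion <- list(conversion)
  if (length(conversion) == 0L) {
    stop("missing component diagnostic: at least one conversion summary",
         call. = FALSE)
  }
  if (is.null(shared)) {
    stop("missing component diagnostic: shared-site table", call. = FALSE)
  }
  rates <- vapply(conversion, function(s) s$conversion_rate, 0)
  tot_u <- sum(vapply(conversion, function(s) s$total_unconverted, 0))
  tot_c <- sum(vapply(conversion, function(s) s$total_converted, 0))
  global_nonconv <- tot_u / (tot_u + tot_c)
  pooled_shared <- if (nrow(shared)) {
    sum(shared$x1 + shared$x2) / sum(shared$depth1 + shared$depth2)
  } else 0
  mean_site_prop <- if (nrow(shared)) mean(shared$pooled_proportion) else NA_real_
  rho_ok <- !is.null(correlation) &&
    correlation$rho <= thresholds$max_rho &&
    correlation$p < thresholds$max_rho_p
  conv_ok <- all(rates >= thresholds$min_conversion)
  low_shared <- pooled_shared <= thresholds$absent_fold * global_nonconv
  high_shared <- pooled_shared >= thresholds$present_fold * global_nonconv
  verdict <- if (conv_ok && rho_ok && low_shared) {
    "absent"
  } else if (high_shared && !rho_ok) {
    "present"
  } else {
    "inconclusive"
  }
  evidence <- c(
    sprintf("conversion rates: %s (threshold >= %.4g in every replicate: %s)",
            paste(sprintf("%.4f", rates), collapse = ", "),
            thresholds$min_conversion, if (conv_ok) "met" else "not met"),
    if (!is.null(correlation)) {
      sprintf("coverage-proportion Spearman rho = %.3f (n = %d, p = %.3g); artifact signature (rho <= %.2g, p < %.2g): %s",
              correlation$rho, correlation$n, correlation$p,
              thresholds$max_rho, thresholds$max_rho_p,
              if (rho_ok) "met" else "not met")
    } else "coverage-proportion correlation undefined (< 3 shared sites)",
    sprintf("pooled shared-site unconverted fraction %.4g vs global non-conversion %.4g (x%.2f)",
            pooled_shared, global_nonconv,
            if (global_nonconv > 0) pooled_shared / global_nonconv else NA_real_))
  structure(list(
    verdict = verdict,
    conversion = conversion,
    conversion_rates = rates,
    global_nonconversion = global_nonconv,
    shared_count = nrow(shared),
    pooled_shared_fraction = pooled_shared,
    mean_shared_site_proportion = mean_site_prop,
    correlation = correlation,
    placement = placement,
    expected_overlap = expected_overlap,
    thresholds = thresholds,
    calling_mode = calling_mode,
    evidence = evidence,
    schema = "methdx-diagnostic-1"),
    class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat("Bisulfite methylation diagnostic report\n")
  cat(sprintf("  verdict: %s  (calling mode: %s)\n", x$verdict, x$calling_mode))
  cat(sprintf("  replicates: %d; shared partially-unconverted sites: %d\n",
              length(x$conversion), x$shared_count))
  if (!is.null(x$placement)) {
    cat(sprintf("  placed on chromosomes: %d of %d (%.1f%%)\n",
                x$placement$n_placed, x$placement$n_total,
                x$placement$placed_percent))
  }
  if (!is.null(x$expected_overlap)) {
    cat(sprintf("  chance-overlap expectation: %.1f sites (sd %.1f)\n",
                x$expected_overlap$expected, x$expected_overlap$sd))
  }
  for (e in x$evidence) cat("  -", e, "\n")
  invisible(x)
}

#' Serialise a diagnostic report to JSON
#'
#' @param report a `diagnostic_report`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_report_json <- function(report, file) {
  x <- report
  x$conversion <- lapply(x$conversion, function(s) {
    s$per_context <- as.data.frame(s$per_context)
    unclass(s)
  })
  if (!is.null(x$correlation)) x$correlation <- unclass(x$correlation)
  if (!is.null(x$expected_overlap)) x$expected_overlap <- unclass(x$expected_overlap)
  jsonlite::write_json(unclass(x), file, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(file)
}

#' One-call replicate diagnosis
#'
#' Runs the whole inference chain on two replicate call tables: conversion
#' summaries, unconverted-site selection, replicate intersection, placement
#' partition, coverage-proportion correlation, chance-overlap expectation
#' and the final verdict.
#'
#' @param calls1,calls2 `site_counts` tables for the two replicates (any
#'   contexts; the shared-site analysis restricts to CpG rows).
#' @param genome optional [ref_genome()] for the placement partition.
#' @param min_unconverted per-site threshold for "partially unconverted".
#' @param merge_cpg merge CpG strand-mates before the analysis.
#' @param scope scope for the conversion-rate summaries.
#' @param thresholds a [diag_thresholds()] list.
#' @return a `diagnostic_report`.
#' @export
diagnose_replicates <- function(calls1, calls2, genome = NULL,
                                min_unconverted = 1L, merge_cpg = FALSE,
                                scope = "all",
                                thresholds = diag_thresholds()) {
  conv <- list(estimate_conversion_rate(calls1, scope),
               estimate_conversion_rate(calls2, scope))
  cpg1 <- calls1[context == "CpG"]
  cpg2 <- calls2[context == "CpG"]
  setattr(cpg1, "merged", isTRUE(attr(calls1, "merged")))
  setattr(cpg2, "merged", isTRUE(attr(calls2, "merged")))
  if (merge_cpg) {
    cpg1 <- merge_cpg_strands(cpg1)
    cpg2 <- merge_cpg_strands(cpg2)
  }
  u1 <- select_unconverted_sites(cpg1, min_unconverted)
  u2 <- select_unconverted_sites(cpg2, min_unconverted)
  shared <- intersect_replicates(u1, u2)
  correlation <- if (nrow(shared) >= 3L &&
                     sd(shared$combined_depth) > 0 &&
                     sd(shared$pooled_proportion) > 0) {
    spearman_coverage_correlation(shared)
  } else NULL
  placement <- if (!is.null(genome) && nrow(shared) > 0L) {
    partition_by_placement(shared, genome)
  } else NULL
  # chance overlap over the union of covered CpG sites, one artifact rate
  # per replicate (estimated from that replicate's own calls)
  depths <- merge(cpg1[, .(chrom, pos, strand, d1 = depth)],
                  cpg2[, .(chrom, pos, strand, d2 = depth)],
                  by = c("chrom", "pos", "strand"), all = TRUE)
  depths[is.na(d1), d1 := 0L]
  depths[is.na(d2), d2 := 0L]
  eps <- vapply(conv, function(s) 1 - s$conversion_rate, 0)
  expected <- expected_chance_overlap(depths$d1, depths$d2, eps)
  assess_methylation(conv, shared, correlation, thresholds, placement,
                     expected,
                     calling_mode = if (merge_cpg) "merged-dinucleotide"
                                    else "per-strand")
}
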