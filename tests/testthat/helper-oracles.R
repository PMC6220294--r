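# Brute-force oracles, written independently of the package internals, plus
# small fixture builders used across the suite.

# all permutations of 1..n, recursively (independent of the package's
# insertion-based enumerator)
perms_oracle <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- perms_oracle(n - 1L)
  out <- list()
  for (p in sub) {
    for (j in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = j - 1L)
    }
  }
  out
}

# exact Spearman rho and two-sided permutation p via stats::cor on midranks
spearman_oracle <- function(x, y) {
  rho <- stats::cor(rank(x), rank(y))
  ry <- rank(y)
  rhos <- vapply(perms_oracle(length(y)),
                 function(p) stats::cor(rank(x), ry[p]), 0)
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# nested-loop inner join of two unconverted-site tables
join_oracle <- function(t1, t2) {
  rows <- list()
  for (i in seq_len(nrow(t1))) {
    for (j in seq_len(nrow(t2))) {
      if (t1$chrom[i] == t2$chrom[j] && t1$pos[i] == t2$pos[j] &&
          t1$strand[i] == t2$strand[j]) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = t1$chrom[i], pos = t1$pos[i], strand = t1$strand[i],
          depth1 = t1$depth[i], x1 = t1$n_unconverted[i],
          depth2 = t2$depth[j], x2 = t2$n_unconverted[j])
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), depth1 = integer(),
                      x1 = integer(), depth2 = integer(), x2 = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
}

# write a SAM file for hand-constructed alignment records
write_test_sam <- function(genome, records, file = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome$sequences),
                      nchar(genome$sequences)))
  writeLines(c(header, records), file)
  file
}

# a SAM record with sane defaults; qual defaults to phred 40 everywhere
sam_rec <- function(qname, chrom, pos, seq, flag = 0L, tag = "CT",
                    mapq = 42L, qual = NULL) {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  tagf <- if (is.na(tag)) "" else sprintf("\tXG:Z:%s", tag)
  sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s%s",
          qname, flag, chrom, pos, mapq, nchar(seq), seq, qual, tagf)
}

# random small site_counts table (CpG context) for oracle comparisons
random_sites_table <- function(n, seed, n_chrom = 2L, span = 30L) {
  set.seed(seed)
  key <- unique(data.frame(
    chrom = sample(paste0("chr", seq_len(n_chrom)), n, TRUE),
    pos = sample.int(span, n, TRUE),
    strand = sample(c("+", "-"), n, TRUE)))
  d <- 1L + stats::rpois(nrow(key), 5)
  x <- stats::rbinom(nrow(key), d, 0.3)
  tab <- data.table::data.table(
    chrom = key$chrom, pos = key$pos, strand = key$strand, context = "CpG",
    n_unconverted = x, n_converted = d - x, n_other = 0L, depth = d,
    ratio = ifelse(d > 0, x / d, NA_real_))
  data.table::setattr(tab, "merged", FALSE)
  tab[]
}
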