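# SAM emission and read-level bisulfite simulation.
#
# Directional (non-PBAT) library model: every read descends from either the
# original top strand (conversion strand CT, flag 0) or the original bottom
# strand (GA, flag 16).  On forward reference coordinates a CT read shows
# C -> T conversion at unmethylated forward cytosines; a GA read shows
# G -> A conversion at reference G positions (the reverse-strand cytosines).
# The conversion strand travels on the Bismark-style XG:Z: tag so callers
# never have to guess it.

.BASES <- c("A", "C", "G", "T")

# coverage of [start, start+rl-1] intervals over 1..L, via cumulated starts
.interval_coverage <- function(starts, rl, L) {
  cnt <- tabulate(starts, nbins = L)
  cs <- cumsum(cnt)
  lag <- c(rep(0, min(rl, L)), cs[seq_len(max(0L, L - rl))])
  as.integer(cs - lag)
}

#' Simulate directional bisulfite reads as a SAM alignment
#'
#' Generates uniformly placed, ungapped single-end reads from both
#' conversion strands of every sequence, applies the bisulfite chemistry
#' (per-cytosine non-conversion `eps_conv`, true methylation from
#' `methylome`) and uniform sequencing error `eps_seq`, and writes a
#' coordinate-sorted SAM file whose records carry the conversion strand as
#' `XG:Z:CT` / `XG:Z:GA`.  Unplaced scaffolds receive the deep,
#' overdispersed coverage stratum of the configuration.  A truth table of
#' per-site methylation and realized informative depth is returned
#' alongside.
#'
#' @inheritParams simulate_pileup
#' @param sam_file output SAM path.
#' @return (invisibly) list with `sam` (the path), `truth` (a `data.table`:
#'   `chrom`, `pos`, `strand`, `context`, `true_m`, `depth`), and `n_reads`.
#' @export
simulate_reads <- function(genome, methylome = NULL, cfg = seq_sim_config(),
                           sam_file = tempfile(fileext = ".sam")) {
  stopifnot(inherits(genome, "ref_genome"), inherits(cfg, "seq_sim_config"))
  chroms <- names(genome$sequences)
  lens <- nchar(genome$sequences)
  sites <- index_cytosines(genome)
  sites[, true_m := 0]
  if (!is.null(methylome)) {
    sites[methylome, on = c("chrom", "pos", "strand"), true_m := i.m]
  }
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms, lens),
              "@PG\tID:methdx\tPN:methdx")
  out <- with_seed(cfg$seed, {
    recs <- list()
    depths <- list()
    n_reads <- 0L
    for (nm in chroms) {
      ref <- strsplit(genome$sequences[[nm]], "", fixed = TRUE)[[1]]
      L <- length(ref)
      rl <- min(cfg$read_length, L)
      placed <- genome$placement[[nm]] == "chromosome"
      mu <- if (placed) cfg$mean_depth else cfg$unplaced_mean_depth
      model <- if (placed) cfg$depth_model else cfg$unplaced_depth_model
      # per-sequence gamma multiplier turns Poisson read counts into a
      # negative-binomial per-site coverage marginal
      mult <- if (model == "nb") {
        rgamma(1L, shape = cfg$nb_size, rate = cfg$nb_size)
      } else 1
      lambda <- L * mu * mult / rl
      m_fwd <- numeric(L); m_rev <- numeric(L)
      sc <- sites[chrom == nm]
      m_fwd[sc[strand == "+", pos]] <- sc[strand == "+", true_m]
      m_rev[sc[strand == "-", pos]] <- sc[strand == "-", true_m]
      for (tag in c("CT", "GA")) {
        nr <- rpois(1L, lambda)
        if (nr == 0L) next
        starts <- sample.int(L - rl + 1L, nr, replace = TRUE)
        idx <- outer(starts, 0:(rl - 1L), "+")
        bmat <- matrix(ref[idx], nr, rl)
        if (tag == "CT") {
          conv_from <- "C"; conv_to <- "T"
          mm <- matrix(m_fwd[idx], nr, rl)
        } else {
          conv_from <- "G"; conv_to <- "A"
          mm <- matrix(m_rev[idx], nr, rl)
        }
        is_cyt <- bmat == conv_from
        p_c <- mm + (1 - mm) * cfg$eps_conv
        u <- matrix(runif(nr * rl), nr, rl)
        bmat[is_cyt & u >= p_c] <- conv_to
        if (cfg$eps_seq > 0) {
          err <- matrix(runif(nr * rl) < cfg$eps_seq, nr, rl)
          if (any(err)) {
            cur <- match(bmat[err], .BASES)
            shift <- sample.int(3L, sum(err), replace = TRUE)
            bmat[err] <- .BASES[(cur - 1L + shift) %% 4L + 1L]
          }
        }
        seqs <- do.call(paste0, lapply(seq_len(rl), function(j) bmat[, j]))
        ord <- order(starts)
        qual <- strrep("I", rl)
        recs[[paste(nm, tag)]] <- data.table(
          chrom = nm, start = starts[ord],
          line = sprintf("%s\t%d\t%s\t%d\t42\t%dM\t*\t0\t0\t%s\t%s\tXG:Z:%s",
                         sprintf("%s_%s_%06d", nm, tag, seq_len(nr)),
                         if (tag == "CT") 0L else 16L,
                         nm, starts[ord], rl, seqs[ord], qual, tag))
        n_reads <- n_reads + nr
        depths[[paste(nm, tag)]] <- data.table(
          chrom = nm, strand = if (tag == "CT") "+" else "-",
          pos = seq_len(L),
          depth = .interval_coverage(starts, rl, L))
      }
    }
    list(recs = recs, depths = depths, n_reads = n_reads)
  })
  body <- if (length(out$recs)) {
    rb <- rbindlist(out$recs)
    rb[, chrom := factor(chrom, levels = chroms)]
    setorder(rb, chrom, start)
    rb$line
  } else character(0)
  writeLines(c(header, body), sam_file)
  truth <- sites
  if (length(out$depths)) {
    dcov <- rbindlist(out$depths)
    truth <- dcov[truth, on = c("chrom", "pos", "strand")]
    truth[is.na(depth), depth := 0L]
  } else {
    truth[, depth := 0L]
  }
  setcolorder(truth, c("chrom", "pos", "strand", "context", "true_m", "depth"))
  setorder(truth, chrom, pos, strand)
  setattr(truth, "seed", cfg$seed)
  invisible(list(sam = sam_file, truth = truth[], n_reads = out$n_reads))
}

#' Write a truth table as TSV
#'
#' @param truth the `truth` element of [simulate_reads()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_truth_tsv <- function(truth, file) {
  fwrite(truth, file, sep = "\t")
  invisible(file)
}
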