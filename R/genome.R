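#' Reference genome container
#'
#' A minimal in-memory reference: named nucleotide sequences plus a
#' per-sequence placement flag distinguishing assembled chromosomes from
#' unplaced (typically repeat-derived) scaffolds.  The placement flag drives
#' [partition_by_placement()] and the per-stratum coverage models of the
#' simulators.
#'
#' @param sequences named character vector of A/C/G/T strings; names must be
#'   unique and every sequence non-empty.
#' @param placement character vector (recycled) of `"chromosome"` or
#'   `"unplaced"`, one per sequence.  Defaults to all `"chromosome"`.
#' @return An object of class `ref_genome`: a list with elements `sequences`
#'   and `placement`.
#' @examples
#' g <- ref_genome(c(chr1 = "ACGTACGT"))
#' g
#' @export
ref_genome <- function(sequences, placement = NULL) {
  nms <- names(sequences)
  if (is.null(nms) || anyDuplicated(nms) || any(!nzchar(nms))) {
    stop("`sequences` must be uniquely named", call. = FALSE)
  }
  sequences <- toupper(as.character(sequences))
  names(sequences) <- nms
  if (any(nchar(sequences) == 0L)) {
    stop("every sequence must be non-empty", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", sequences))) {
    stop("sequences are restricted to the alphabet A/C/G/T", call. = FALSE)
  }
  placement <- placement %||% rep("chromosome", length(sequences))
  placement <- rep_len(as.character(placement), length(sequences))
  if (!all(placement %in% c("chromosome", "unplaced"))) {
    stop("`placement` entries must be \"chromosome\" or \"unplaced\"",
         call. = FALSE)
  }
  names(placement) <- nms
  structure(list(sequences = sequences, placement = placement),
            class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  n <- length(x$sequences)
  tot <- sum(nchar(x$sequences))
  cat(sprintf("<ref_genome> %d sequence%s, %s bp total (%d chromosome, %d unplaced)\n",
              n, if (n == 1L) "" else "s", format(tot, big.mark = ","),
              sum(x$placement == "chromosome"), sum(x$placement == "unplaced")))
  comp <- genome_composition(x)
  cat(sprintf("  GC %.3f, CpG o/e %.3f\n", comp$gc, comp$cpg_oe))
  invisible(x)
}

#' Realized base composition of a genome
#'
#' @param genome a [ref_genome()].
#' @return list with overall `gc` fraction and overall CpG observed/expected
#'   ratio (pooled over sequences), plus the per-sequence [cpg_oe()] table.
#' @export
genome_composition <- function(genome) {
  stopifnot(inherits(genome, "ref_genome"))
  rec <- cpg_oe(genome)
  n_c <- sum(rec$n_C); n_g <- sum(rec$n_G)
  L <- sum(rec$length)
  list(gc = (n_c + n_g) / L,
       cpg_oe = sum(rec$n_CpG) * L / (n_c * n_g),
       per_sequence = rec)
}

# First-order Markov transition rows realising a target stationary base
# composition (A,C,G,T) = (a,c,c,a) with P(G|C) = cpg_oe * c, so that the
# expected CpG observed/expected ratio equals cpg_oe.
.markov_rows <- function(gc, cpg_oe) {
  a <- (1 - gc) / 2
  cc <- gc / 2
  g <- cpg_oe * cc # P(G | C)
  if (g >= 1) {
    stop(sprintf(
      "impossible composition: cpg_oe = %g at gc = %g forces P(G|C) = %g >= 1",
      cpg_oe, gc, g), call. = FALSE)
  }
  w <- c(a, cc, a) # weights for A, C, T in the C row
  rest <- (1 - g) * w / sum(w)
  c_row <- c(rest[1], rest[2], g, rest[3])
  # remaining rows share one distribution q chosen so the chain is stationary
  q <- c((a - cc * c_row[1]) / (1 - cc),
         cc * (1 - c_row[2]) / (1 - cc),
         cc * (1 - g) / (1 - cc),
         (a - cc * c_row[4]) / (1 - cc))
  if (any(q < -1e-12)) {
    stop("impossible composition: no stationary transition rows exist for ",
         sprintf("gc = %g, cpg_oe = %g", gc, cpg_oe), call. = FALSE)
  }
  q <- pmax(q, 0)
  list(q = q / sum(q), c_row = c_row)
}

.markov_chain_seq <- function(L, q, c_row) {
  bases <- c("A", "C", "G", "T")
  if (max(abs(q - c_row)) < 1e-12) { # iid shortcut (cpg_oe == 1)
    return(paste(sample(bases, L, replace = TRUE, prob = q), collapse = ""))
  }
  cq <- cumsum(q)
  cc <- cumsum(c_row)
  u <- runif(L)
  s <- integer(L)
  prev_c <- FALSE
  for (i in seq_len(L)) {
    cum <- if (prev_c) cc else cq
    x <- 1L
    while (u[i] >= cum[x]) x <- x + 1L
    s[i] <- x
    prev_c <- x == 2L
  }
  paste(bases[s], collapse = "")
}

#' Simulate a reference genome with controlled composition
#'
#' Emits sequences from a first-order Markov chain whose stationary base
#' composition matches `gc` and whose C-to-G transition probability is scaled
#' so the expected CpG observed/expected ratio equals `cpg_oe`.  With
#' `cpg_oe = 1` the chain collapses to independent draws.  The genome is split
#' into placed chromosomes (`chr1`, `chr2`, ...) and unplaced scaffolds
#' (`scaffold1`, ...), mirroring an assembly where repeat-derived sequence is
#' left off the chromosomes.
#'
#' @param n_chromosomes,n_unplaced number of placed / unplaced sequences.
#' @param chrom_length,unplaced_length sequence lengths in bases (recycled);
#'   each must be at least 1000.
#' @param gc target GC fraction, strictly inside (0, 1).
#' @param cpg_oe target CpG observed/expected ratio (> 0).
#' @param seed integer seed; identical seeds give byte-identical genomes.
#' @return a [ref_genome()].
#' @examples
#' g <- simulate_genome(1, 0, chrom_length = 2000, gc = 0.4, seed = 1)
#' genome_composition(g)$gc
#' @export
simulate_genome <- function(n_chromosomes, n_unplaced = 0,
                            chrom_length = 1e6,
                            unplaced_length = max(1000, chrom_length[1] %/% 20),
                            gc = 0.4, cpg_oe = 1.0, seed = NULL) {
  stopifnot(n_chromosomes >= 0, n_unplaced >= 0,
            n_chromosomes + n_unplaced >= 1)
  .assert_scalar_num(gc, "gc", 0, 1, lo_open = TRUE, hi_open = TRUE)
  .assert_scalar_num(cpg_oe, "cpg_oe", 0, Inf, lo_open = TRUE)
  lens <- c(if (n_chromosomes > 0) rep_len(chrom_length, n_chromosomes),
            if (n_unplaced > 0) rep_len(unplaced_length, n_unplaced))
  lens <- as.integer(lens)
  if (any(lens < 1000L)) {
    stop("sequence lengths must be at least 1000 bases", call. = FALSE)
  }
  rows <- .markov_rows(gc, cpg_oe)
  nms <- c(if (n_chromosomes > 0) paste0("chr", seq_len(n_chromosomes)),
           if (n_unplaced > 0) paste0("scaffold", seq_len(n_unplaced)))
  plc <- c(rep("chromosome", n_chromosomes), rep("unplaced", n_unplaced))
  seqs <- with_seed(seed, {
    vapply(lens, .markov_chain_seq, "", q = rows$q, c_row = rows$c_row)
  })
  names(seqs) <- nms
  g <- ref_genome(seqs, plc)
  attr(g, "seed") <- seed
  g
}

#' Write a genome to FASTA
#'
#' @param genome a [ref_genome()].
#' @param file output path.
#' @param width line-wrap width (default 60 columns).
#' @return `file`, invisibly.
#' @export
write_fasta <- function(genome, file, width = 60L) {
  stopifnot(inherits(genome, "ref_genome"))
  x <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(x, filepath = file, width = width)
  invisible(file)
}

#' Read a genome from FASTA
#'
#' Placement is taken from `placement` when supplied, otherwise inferred from
#' sequence names: names matching `unplaced_pattern` (case-insensitive) are
#' flagged unplaced.
#'
#' @param file FASTA path.
#' @param placement optional character vector named by sequence.
#' @param unplaced_pattern regular expression marking unplaced scaffolds.
#' @return a [ref_genome()].
#' @export
read_genome_fasta <- function(file, placement = NULL,
                              unplaced_pattern = "^(scaffold|contig|un)") {
  x <- Biostrings::readDNAStringSet(file)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  if (is.null(placement)) {
    placement <- ifelse(grepl(unplaced_pattern, names(seqs),
                              ignore.case = TRUE), "unplaced", "chromosome")
  } else {
    placement <- placement[names(seqs)]
  }
  ref_genome(seqs, placement)
}
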