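#' Per-cytosine methylation calling from bisulfite alignments
#'
#' A methratio-style caller: walks aligned, deduplicated bisulfite reads and
#' tallies, for every cytosine site of the requested contexts, unconverted
#' (C-state), converted (T-state) and other base calls.  A read contributes
#' to a site only when the read's conversion strand (the `XG:Z:CT` /
#' `XG:Z:GA` tag) matches the site's strand; on forward-strand sites C counts
#' as unconverted and T as converted, on reverse-strand sites G and A
#' respectively (forward reference coordinates).  Base calls below
#' `min_base_quality`, reads below `min_mapping_quality`, unmapped reads and
#' reads with non-trivial CIGARs are skipped.  When both mates of a pair
#' cover one site the first mate wins, so fragments are never counted twice.
#'
#' @param alignments path to a SAM or BAM file, coordinate-sorted, whose
#'   reads carry the conversion-strand tag.
#' @param genome the matching [ref_genome()].
#' @param min_base_quality,min_mapping_quality phred thresholds
#'   (defaults 20/20).
#' @param contexts cytosine contexts to report (default CpG only).
#' @param on_missing_tag `"skip"` (drop such reads with a warning) or
#'   `"error"`.
#' @return a `site_counts` `data.table` (same shape as
#'   [simulate_pileup()]): `chrom`, `pos`, `strand`, `context`,
#'   `n_unconverted`, `n_converted`, `n_other`, `depth`,
#'   `ratio = C/(C+T)`; only covered sites appear.
#' @export
call_sites <- function(alignments, genome,
                       min_base_quality = 20L, min_mapping_quality = 20L,
                       contexts = "CpG",
                       on_missing_tag = c("skip", "error")) {
  on_missing_tag <- match.arg(on_missing_tag)
  stopifnot(inherits(genome, "ref_genome"))
  bam <- alignments
  if (grepl("\\.sam$", alignments, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(alignments, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = "XG")
  b <- Rsamtools::scanBam(bam, param = param)[[1]]
  nr <- length(b$qname)
  if (nr == 0L) {
    return(.empty_site_counts())
  }
  reads <- data.table(
    qname = b$qname, flag = b$flag, chrom = as.character(b$rname),
    pos = b$pos, mapq = b$mapq, cigar = b$cigar,
    seq = as.character(b$seq), qual = as.character(b$qual),
    tag = if (is.null(b$tag$XG)) rep(NA_character_, nr) else b$tag$XG)
  reads <- reads[bitwAnd(flag, 4L) == 0L]
  bad_chrom <- setdiff(unique(reads$chrom), names(genome$sequences))
  if (length(bad_chrom)) {
    stop("alignment references chromosomes absent from the genome: ",
         paste(bad_chrom, collapse = ", "), call. = FALSE)
  }
  if (anyNA(reads$tag) || any(!reads$tag %in% c("CT", "GA"))) {
    n_bad <- sum(is.na(reads$tag) | !reads$tag %in% c("CT", "GA"))
    if (on_missing_tag == "error") {
      stop(n_bad, " reads lack a usable XG conversion-strand tag",
           call. = FALSE)
    }
    warning(n_bad, " reads without a usable XG tag were skipped")
    reads <- reads[!is.na(tag) & tag %in% c("CT", "GA")]
  }
  reads <- reads[is.na(mapq) | mapq >= min_mapping_quality]
  simple <- grepl("^[0-9]+M$", reads$cigar)
  if (any(!simple)) {
    warning(sum(!simple), " reads with non-M CIGAR operations were skipped")
    reads <- reads[simple]
  }
  if (nrow(reads) == 0L) return(.empty_site_counts())
  w <- nchar(reads$seq)
  ridx <- rep(seq_len(nrow(reads)), w)
  off <- sequence(w) - 1L
  calls <- data.table(
    chrom = reads$chrom[ridx],
    gpos = reads$pos[ridx] + off,
    strand = fifelse(reads$tag[ridx] == "CT", "+", "-"),
    base = unlist(strsplit(reads$seq, "", fixed = TRUE), use.names = FALSE),
    q = utf8ToInt(paste(reads$qual, collapse = "")) - 33L,
    qname = reads$qname[ridx],
    # single-end reads and first mates take precedence over second mates
    firstmate = bitwAnd(reads$flag[ridx], 1L) == 0L |
      bitwAnd(reads$flag[ridx], 64L) > 0L)
  calls <- calls[q >= min_base_quality]
  sites <- index_cytosines(genome, contexts)
  calls <- calls[sites, on = c("chrom", gpos = "pos", "strand"),
                 nomatch = NULL]
  if (nrow(calls) == 0L) return(.empty_site_counts())
  # one fragment, one observation: drop the second mate where both cover
  setorder(calls, chrom, gpos, strand, qname, -firstmate)
  calls <- unique(calls, by = c("chrom", "gpos", "strand", "qname"))
  calls[, cls := fifelse(strand == "+",
                         fifelse(base == "C", "U", fifelse(base == "T", "C", "O")),
                         fifelse(base == "G", "U", fifelse(base == "A", "C", "O")))]
  res <- calls[, .(n_unconverted = sum(cls == "U"),
                   n_converted = sum(cls == "C"),
                   n_other = sum(cls == "O")),
               by = .(chrom, pos = gpos, strand, context)]
  res[, depth := n_unconverted + n_converted + n_other]
  res[, ratio := fifelse(n_unconverted + n_converted > 0L,
                         n_unconverted / (n_unconverted + n_converted),
                         NA_real_)]
  setorder(res, chrom, pos, strand)
  setattr(res, "merged", FALSE)
  res[]
}

.empty_site_counts <- function() {
  res <- data.table(chrom = character(), pos = integer(), strand = character(),
                    context = character(), n_unconverted = integer(),
                    n_converted = integer(), n_other = integer(),
                    depth = integer(), ratio = numeric())
  setattr(res, "merged", FALSE)
  res[]
}

#' Merge the two strands of each CpG dinucleotide
#'
#' CpG methylation is symmetric, so the strand-mates of one dinucleotide
#' estimate the same quantity; merging sums their counts.  The merged site is
#' reported at the forward-strand C coordinate; sites whose mate is uncovered
#' pass through unchanged.
#'
#' @param sites a `site_counts` table restricted to CpG context.
#' @return a `site_counts` table keyed by dinucleotide (strand `"+"`),
#'   with attribute `merged = TRUE`.
#' @export
merge_cpg_strands <- function(sites) {
  if (nrow(sites) > 0L && any(sites$context != "CpG")) {
    stop("merge_cpg_strands expects CpG-context rows only", call. = FALSE)
  }
  out <- copy(sites)
  out[, pos := fifelse(strand == "-", pos - 1L, pos)]
  out <- out[, .(n_unconverted = sum(n_unconverted),
                 n_converted = sum(n_converted),
                 n_other = sum(n_other)),
             by = .(chrom, pos, context)]
  out[, `:=`(strand = "+", depth = n_unconverted + n_converted + n_other)]
  out[, ratio := fifelse(n_unconverted + n_converted > 0L,
                         n_unconverted / (n_unconverted + n_converted),
                         NA_real_)]
  setcolorder(out, c("chrom", "pos", "strand", "context", "n_unconverted",
                     "n_converted", "n_other", "depth", "ratio"))
  setorder(out, chrom, pos)
  setattr(out, "merged", TRUE)
  out[]
}

#' Write per-site methylation calls as TSV
#'
#' methratio-dialect columns, 1-based coordinates:
#' `chrom, pos, strand, context, ratio, C_count, CT_count, depth`, with the
#' ratio printed to six decimals and `NA` when undefined.  A `#methdx` header
#' line records whether strands were merged so downstream joins can refuse
#' mixed modes.
#'
#' @param sites a `site_counts` table.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_methcall <- function(sites, file) {
  hdr <- sprintf("#methdx\tmerged=%s",
                 isTRUE(attr(sites, "merged")))
  df <- data.table(chrom = sites$chrom, pos = sites$pos,
                   strand = sites$strand, context = sites$context,
                   ratio = fifelse(is.na(sites$ratio), "NA",
                                   sprintf("%.6f", sites$ratio)),
                   C_count = sites$n_unconverted,
                   CT_count = sites$n_unconverted + sites$n_converted,
                   depth = sites$depth)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(hdr, paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    writeLines(do.call(paste, c(df, sep = "\t")), con)
  }
  invisible(file)
}

#' Read per-site methylation calls written by [write_methcall()]
#'
#' @param file TSV path.
#' @return a `site_counts` table with the `merged` attribute restored.
#' @export
read_methcall <- function(file) {
  first <- readLines(file, n = 1L)
  merged <- grepl("merged=TRUE", first, fixed = TRUE)
  df <- fread(file, sep = "\t", skip = if (startsWith(first, "#")) 1L else 0L,
              header = TRUE, na.strings = "NA")
  res <- data.table(chrom = as.character(df$chrom), pos = as.integer(df$pos),
                    strand = as.character(df$strand),
                    context = as.character(df$context),
                    n_unconverted = as.integer(df$C_count),
                    n_converted = as.integer(df$CT_count - df$C_count),
                    n_other = as.integer(df$depth - df$CT_count),
                    depth = as.integer(df$depth),
                    ratio = as.numeric(df$ratio))
  setattr(res, "merged", merged)
  res[]
}

#' Export calls as bedGraph
#'
#' 0-based half-open intervals with the methylation ratio as the value;
#' sites with undefined ratio are dropped.
#'
#' @param sites a `site_counts` table.
#' @param file output path.
#' @param track_name optional track name line.
#' @return `file`, invisibly.
#' @export
write_bedgraph <- function(sites, file, track_name = NULL) {
  keep <- !is.na(sites$ratio)
  lines <- sprintf("%s\t%d\t%d\t%.6f", sites$chrom[keep],
                   sites$pos[keep] - 1L, sites$pos[keep], sites$ratio[keep])
  if (!is.null(track_name)) {
    lines <- c(sprintf("track type=bedGraph name=\"%s\"", track_name), lines)
  }
  writeLines(lines, file)
  invisible(file)
}
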