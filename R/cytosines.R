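#' Enumerate cytosine sites and their sequence context
#'
#' Every cytosine of the genome, on both strands, with its context read from
#' the two downstream bases on the cytosine's own strand: `CpG` (next base G),
#' `CHG` (next-but-one base G), otherwise `CHH`.  Reverse-strand cytosines sit
#' at reference G positions and their context is read on the reverse
#' complement.  Cytosines too close to a sequence end to have a downstream G
#' fall into `CHH`.  The two strand-mates of one CpG dinucleotide appear as
#' separate rows at adjacent positions.
#'
#' @param genome a [ref_genome()].
#' @param contexts subset of `c("CpG", "CHG", "CHH")`; an empty selection
#'   returns an empty table.
#' @return `data.table` with columns `chrom`, `pos` (1-based position of the
#'   cytosine on the forward reference), `strand` (`"+"`/`"-"`) and `context`,
#'   ordered by (chrom, pos, strand).
#' @examples
#' index_cytosines(ref_genome(c(chr1 = "ACGT")))
#' @export
index_cytosines <- function(genome, contexts = c("CpG", "CHG", "CHH")) {
  stopifnot(inherits(genome, "ref_genome"))
  contexts <- as.character(contexts)
  if (!all(contexts %in% c("CpG", "CHG", "CHH"))) {
    stop("`contexts` must be a subset of CpG/CHG/CHH", call. = FALSE)
  }
  empty <- data.table(chrom = character(), pos = integer(),
                      strand = character(), context = character())
  if (length(contexts) == 0L) return(empty)
  out <- lapply(names(genome$sequences), function(nm) {
    ch <- strsplit(genome$sequences[[nm]], "", fixed = TRUE)[[1]]
    L <- length(ch)
    fwd <- which(ch == "C")
    n1 <- rep(NA_character_, length(fwd))
    n2 <- n1
    ok1 <- fwd < L;      n1[ok1] <- ch[fwd[ok1] + 1L]
    ok2 <- fwd < L - 1L; n2[ok2] <- ch[fwd[ok2] + 2L]
    ctx_f <- fifelse(!is.na(n1) & n1 == "G", "CpG",
                     fifelse(!is.na(n2) & n2 == "G", "CHG", "CHH"))
    rev <- which(ch == "G")
    p1 <- rep(NA_character_, length(rev))
    p2 <- p1
    ok1 <- rev > 1L; p1[ok1] <- ch[rev[ok1] - 1L]
    ok2 <- rev > 2L; p2[ok2] <- ch[rev[ok2] - 2L]
    ctx_r <- fifelse(!is.na(p1) & p1 == "C", "CpG",
                     fifelse(!is.na(p2) & p2 == "C", "CHG", "CHH"))
    data.table(chrom = nm,
               pos = c(fwd, rev),
               strand = rep(c("+", "-"), c(length(fwd), length(rev))),
               context = c(ctx_f, ctx_r))
  })
  res <- rbindlist(out)
  if (nrow(res) == 0L) return(empty)
  res <- res[context %in% contexts]
  setorder(res, chrom, pos, strand)
  res[]
}

#' Simulate a ground-truth methylome
#'
#' Assigns a true methylation probability `m` to every cytosine site of the
#' requested contexts.  Three models: `"null"` (all m = 0, the no-methylation
#' hypothesis), `"uniform"` (every site of the chosen contexts at `m`), and
#' `"mosaic"` (a seeded random fraction of CpG dinucleotides at `m_high`, the
#' rest at 0 — a cartoon of patchy gene-body methylation).  CpG assignment is
#' symmetric: both strand-mates of a dinucleotide always share one value.
#'
#' @param genome a [ref_genome()].
#' @param model `"null"`, `"uniform"` or `"mosaic"`.
#' @param m methylation probability for the uniform model, in \[0, 1\].
#' @param fraction_methylated fraction of CpG dinucleotides methylated under
#'   the mosaic model.
#' @param m_high methylation probability of the mosaic methylated fraction.
#' @param contexts contexts carried in the methylome (default CpG only).
#' @param seed integer seed for the mosaic draw.
#' @return `data.table` of class `methylome` with columns `chrom`, `pos`,
#'   `strand`, `context`, `m`; sites absent from the table are implicitly
#'   unmethylated.
#' @export
simulate_methylome <- function(genome, model = c("null", "uniform", "mosaic"),
                               m = 1.0, fraction_methylated = 0.2,
                               m_high = 0.8, contexts = "CpG", seed = NULL) {
  model <- match.arg(model)
  .assert_scalar_num(m, "m", 0, 1)
  .assert_scalar_num(fraction_methylated, "fraction_methylated", 0, 1)
  .assert_scalar_num(m_high, "m_high", 0, 1)
  sites <- index_cytosines(genome, contexts)
  sites[, m := 0]
  if (model == "uniform") {
    mm <- m
    sites[, m := mm]
  } else if (model == "mosaic") {
    # pick whole CpG dinucleotides so both strands stay symmetric
    sites[, dinuc := fifelse(strand == "+", pos, pos - 1L)]
    cpg <- sites[context == "CpG"]
    keys <- unique(cpg[, .(chrom, dinuc)])
    n_pick <- round(fraction_methylated * nrow(keys))
    picked <- with_seed(seed, keys[sample.int(nrow(keys), n_pick)])
    picked[, m_new := m_high]
    sites[picked, on = c("chrom", "dinuc"), m := fifelse(context == "CpG", i.m_new, m)]
    sites[, dinuc := NULL]
  }
  setattr(sites, "class", c("methylome", class(sites)))
  setattr(sites, "model", model)
  setattr(sites, "seed", seed)
  sites[]
}
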