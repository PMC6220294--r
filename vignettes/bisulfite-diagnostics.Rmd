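---
title: "Diagnosing the presence or absence of CpG methylation from bisulfite sequencing"
author: "methdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing the presence or absence of CpG methylation from bisulfite sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdx)
```

## The inference problem

Sodium bisulfite converts unmethylated cytosine to uracil (sequenced as T)
while 5-methylcytosine resists conversion, so methylation is read as the
C/T state of aligned reads at cytosine positions.  The catch is that the
chemistry is imperfect: a small per-cytosine fraction $\varepsilon_{conv}$
escapes conversion, and sequencing error $\varepsilon_{seq}$ adds further
spurious C calls.  In a genome with little or no methylation these artifacts
dominate the signal, and deciding "absent" requires more than observing a
low global methylation level.

`methdx` formalises the inference as four lines of evidence, each computable
from two replicate call tables:

1. **Conversion rate.** Pooled over base calls,
   $T/(C+T)$ should approach $1-\varepsilon_{conv}$; values
   below ~99.5% leave too much artifact background to call anything.
2. **Replicate reproducibility.** Sites partially unconverted in *both*
   replicates are compared with the chance expectation under independent
   artifacts, $\sum_i \bigl(1-(1-\varepsilon)^{d_{1i}}\bigr)
   \bigl(1-(1-\varepsilon)^{d_{2i}}\bigr)$.  Genuine methylation reproduces
   far in excess of chance.
3. **Coverage dependence.** For an artifact process the unconverted
   proportion at selected sites is approximately $x/d$ with $x$ small, so it
   decays with coverage; the Spearman rank correlation between combined
   depth and pooled proportion is strongly negative.  True methylation at
   level $m$ keeps the proportion near $m$ at any depth.
4. **Assembly placement.** Artifact sites concentrate in repeat-derived
   unplaced scaffolds whose collapsed copies accumulate both coverage and
   rare artifact calls; methylation would also populate assembled
   chromosomes.

`assess_methylation()` combines these into a verdict that is a pure function
of the recorded evidence and thresholds:

* **absent** — conversion $\ge$ 99.5% in every replicate, *and*
  $\rho \le -0.8$ with $p < 0.01$, *and* the pooled shared-site unconverted
  fraction at most $2\times$ the global non-conversion rate;
* **present** — pooled shared-site fraction at least $10\times$ the global
  rate *without* the artifact's coverage signature;
* **inconclusive** — anything else.

The 0.995 / $-0.8$ / $2\times$ / $10\times$ defaults separate a clean
unmethylated library from even a 10%-methylated alternative at six-fold
depth; all four are arguments to `diag_thresholds()` and are echoed
verbatim into the report, never hard-coded into its text.

## The calling model

`call_sites()` re-implements methratio-style counting.  A directional
library is assumed: each read carries its conversion strand as a Bismark
`XG:Z:CT` / `XG:Z:GA` tag, and a read contributes to a cytosine site only
when the tags agree with the site's strand — a CT read is uninformative for
reverse-strand cytosines and vice versa.  On forward coordinates, C counts
as unconverted and T as converted at forward sites; G and A play those roles
at reverse sites.  Everything else lands in `n_other`, which is excluded
from the ratio denominator (`ratio = C/(C+T)`, the effective-CT
convention).  Base calls below phred 20 and reads below mapping quality 20
are skipped by default; both cutoffs are arguments.  Overlapping mates are
counted once, first mate winning, so a fragment is never double-counted.
Positions are 1-based throughout (the R/Bioconductor convention) in memory
and in every emitted file; only the optional bedGraph export converts to
0-based half-open intervals.

CpG methylation is strand-symmetric, so `merge_cpg_strands()` can pool the
two strand-mates of each dinucleotide; merging is off by default and the
choice is recorded in the table (and refused when replicates mix modes),
because the shared-site analysis is sensitive to which universe of sites it
runs over.

## What the simulators emulate — and what they do not

`simulate_pileup()` draws, per cytosine site, an informative depth $d$ and
counts from the emission model

$$p_C = m + (1-m)\,\varepsilon_{conv}, \qquad
  p_{obsC} = (1-\varepsilon_{seq})\,p_C + \tfrac{\varepsilon_{seq}}{3}(1-p_C),$$

with the converted count drawn from the complementary T-emission probability
and the remainder recorded as other.  `simulate_reads()` realises the same
stochastic model at read level (uniformly placed, ungapped, single-end
reads on both conversion strands, constant base quality) and writes
coordinate-sorted SAM; calling those reads reproduces the pileup's marginal
distribution, which the test suite checks by comparing the two paths at
matched parameters.

Default parameters are the study conditions the package is built around:
mean depth 6 on chromosomes, $\varepsilon_{conv} = 0.004$ (a 99.6%
conversion rate), $\varepsilon_{seq} = 0.001$, read length 105.  Coverage on
chromosomes is Poisson; unplaced scaffolds instead receive a negative
binomial stratum with mean 95 and size 0.5.  That stratum is the package's
stand-in for repeat-derived scaffolds whose many genomic copies collapse
onto few reference positions, inflating apparent coverage by an order of
magnitude and spreading it over a long tail; its parameters were chosen so
that a two-replicate null simulation over a ~2 Mb genome (4 × 480 kb
chromosomes, 6 × 20 kb scaffolds) reproduces the qualitative artifact
signature end to end — several hundred shared unconverted sites, ~90% of
them unplaced, rho well below −0.8, pooled shared-site non-conversion under
twice the global rate — while a mosaic methylome (20% of CpG dinucleotides
at $m = 0.8$) flips the verdict to present.

Real WGBS data differ from this cartoon in ways that matter for
interpretation: no PBAT or amplicon protocols, no adapter or fragment-size
effects, no mapping ambiguity or duplicate reads (inputs are assumed
deduplicated), no base-quality structure, no context-dependent conversion
failure, and sequencing error is uniform over the three alternative bases.
Passing the simulation suite therefore validates the *inference machinery*,
not any claim that the generator matches a particular instrument.

`simulate_genome()` emits sequence from a first-order Markov chain whose
stationary composition matches the target GC and whose C→G transition is
scaled to hit a target CpG o/e (at o/e = 1 the chain collapses to
independent draws); compositions that would need $P(G\mid C) \ge 1$ or a
negative transition probability are rejected as impossible.
`simulate_methylome()` assigns symmetric per-dinucleotide methylation under
null, uniform or mosaic models.

## CpG depletion and bimodality

Methylated cytosines deaminate to thymine over evolutionary time, so
lineages with a long history of CpG methylation show
$o/e = n_{CpG} \cdot L / (n_C \cdot n_G)$ well below 1, and gene sets
split into methylated/unmethylated classes show a *bimodal* o/e
distribution.  `bimodality_test()` fits one- and two-component Gaussian
mixtures by EM (tolerance $10^{-8}$, at most 500 iterations, ten
quantile-spaced restarts plus one start at the one-component solution so the
two-component log-likelihood can never fall below the one-component one, and
a $10^{-3}$ floor on component standard deviations to avoid likelihood
singularities).  Because the LRT null sits on a parameter boundary, its
distribution is obtained by parametric bootstrap under the one-component
fit.  The bootstrap LRT alone over-rejects for heavy-tailed data, so the
"bimodal" call additionally requires the component means to be separated by
more than twice the pooled within-component standard deviation.

## qPCR model and conventions

Crossing points follow
$Cp = base_{Cp}(g) - \log_{E(g)}(\text{concentration}) + \text{noise}$;
efficiencies come from dilution series via $E = 10^{-1/slope}$.  The
relative expression of a target $t$ over references $r$ is the Pfaffl ratio

$$\text{ratio} = \frac{E_t^{\Delta Cp_t}}{\operatorname{geomean}_r\,E_r^{\Delta Cp_r}},
 \qquad \Delta Cp_g = \overline{Cp}_{control}(g) - \overline{Cp}_{treatment}(g),$$

so up-regulation in the treatment group gives a ratio above 1.  Design
choices the literature leaves open, fixed here and logged in the output:
multiple references combine by geometric mean of their normalization
factors; the randomization test permutes group labels jointly across genes
per biological sample and is two-sided on $|\log \text{ratio}|$ (enumerated
exactly whenever $\binom{n}{n_1}$ fits the iteration budget, add-one
smoothed otherwise); technical-replicate standard deviations use the
$n-1$ denominator and the 0.5-cycle QC cutoff is strict.  The simulator
splits noise into a biological draw shared by technical replicates
(`cp_noise_sd`) and independent technical noise (`tech_noise_sd`,
defaulting to a third of the biological scale, the usual ordering in
practice); at zero noise every estimator recovers the simulated truth
exactly, which the tests assert.

## Numerical and testing choices

* Spearman rho is the Pearson correlation of midranks (average ranks on
  ties); p-values come from full permutation enumeration for $n \le 10$ and
  the $t$ approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ above it.  The
  exact branch is compared against an independently written enumeration
  oracle for $n \le 8$ in the tests.
* The chance-overlap expectation reports the Poisson-binomial standard
  deviation alongside the mean, so observed counts can be judged against a
  99% envelope.
* Degenerate inputs fail loudly rather than silently: zero-variance
  correlation input, empty site tables, non-negative dilution slopes,
  impossible genome compositions and mixed strand-merge modes are all
  errors with specific messages.
* Problem sizes in the test suite are the package's chosen study scales:
  ~2 Mb genomes at depth 6 for the replicate-level properties, ~5 million
  base calls for conversion-rate recovery, 1000 null randomization tests for
  type-I calibration, 200 simulations of an 8 + 8 design for bootstrap
  coverage (n = 8 per group being the size of the life-stage comparisons the
  qPCR machinery mirrors), and 200-resample parametric bootstraps for the
  bimodality calls.

## Known limitations

The verdict thresholds are calibrated for shallow (~6×) WGBS with two
replicates; single-replicate designs lose the reproducibility axis and can
only reach "inconclusive" evidence of absence.  The chance-overlap formula
assumes artifact independence across replicates, which breaks if both
libraries share a conversion-resistant secondary structure.  The bimodality
test assumes Gaussian components on the o/e scale and at least 50
observations.  The qPCR randomization test conditions on the observed
samples and does not model pipetting structure beyond the technical/
biological split.  None of the tools address non-CpG methylation calling
beyond reporting CHG/CHH contexts, and hydroxymethylation is
indistinguishable from methylation in bisulfite data.
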