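---
title: "Fragile codons, NMD efficiency and transcriptional robustness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragile codons, NMD efficiency and transcriptional robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonfragility)
```

## The problem

Transcription is error-prone. A single mis-incorporated nucleotide can turn
a sense codon into a premature termination codon (PTC), and the resulting
truncated protein can be toxic. Cells "cure" many of these errors through
nonsense-mediated decay (NMD), but NMD is not uniformly efficient: in
mammals the potent, splicing-linked branch (EJC-dependent NMD) only sees
PTCs lying upstream of roughly 50–55 nt before the last exon–exon junction,
so single-exon genes, last exons of multi-exon genes, and replication-
dependent histone genes (which also lack the poly(A) signal the second,
PABP-dependent branch requires) are poorly surveilled. Where the cure is
weak, selection is expected to favor *prevention*: avoiding codons that
mistranscribe into stops at all. This package implements that analysis as a
reusable, fully testable pipeline.

## Codon fragility and the four metrics

Under the standard genetic code, 18 of the 61 sense codons can be converted
into TAA, TAG or TGA by a single point mutation ("fragile" codons); the
other 43 cannot ("robust"). Six amino acids (C, Q, E, K, W, Y) are encoded
only by fragile codons, ten only by robust codons, and four (S, L, R, G)
by a mixture. The package derives all of this by enumeration of the nine
single-nucleotide neighbors of every codon — the counts are never
hard-coded in the derivation path (a hard-coded table exists only in the
test suite, as an oracle).

Four usage metrics are provided:

* **FCU** — the fraction of a CDS's sense codons that are fragile.
* **NFCU** — fragile codons are AT-rich, and both base composition and
  amino-acid content vary between genes, so raw FCU conflates several
  signals. NFCU therefore compares usage only *within* groups of codons
  that are synonymous and have identical G+C counts but differ in
  fragility: \{TCA,TCT\} and \{TCG,TCC\} (Ser), \{CGA,CGT\} (Arg),
  \{GGA,GGT\} (Gly) and \{TTG,CTT,CTA\} (Leu). The per-group fragile
  fraction is averaged (unweighted) over all groups with a non-zero
  denominator.
* **FAU** — the fraction of a protein's residues that are fragile amino
  acids.
* **NFAU** — the GC-controlled analogue of FAU, averaging the fragile
  fraction within two groups of amino acids whose full codon families have
  equal G+C fraction: \{Y,K,N,F\} (1/6 G+C) and \{Q,E,C,S,H,T,V,D\}
  (1/2 G+C; Ser counts as non-fragile).

Two documented quirks of the classical group lists are preserved: the
three-membered group is labeled "Lysine" in the original description but
contains leucine codons (both lysine codons are fragile, so no lysine group
can exist) — it is treated as the leucine group here; and the AGN synonyms
(AGT/AGC for Ser, AGG for Arg) are absent from the classical lists without
stated rationale. `nfcu_groups("canonical")` (the default everywhere)
reproduces the classical lists exactly; `nfcu_groups("derived")` rebuilds
the partition from first principles (codons of each facultative amino acid
split by G+C count, mixed parts kept), which yields the same five groups
with the AGN codons included, and is exposed for sensitivity analysis.
TTA (fragile, G+C = 0) has no GC-matched robust synonym and belongs to no
group in either mode.

### Undefined values

A short sequence may contain no codon from any group. UNDEFINED is a
first-class value (`metric_value()` returns `NA`): downstream comparisons
drop undefined records and report how many were dropped, so cohort
accounting always sums to the input count.

## Gene models

`load_annotation()` builds strand-resolved transcript models from
FASTA + GFF3 (1-based inclusive on disk, transcript-oriented internally).
One representative transcript per gene is kept: the longest peptide, ties
broken by smallest transcript id. Validation failures (no terminal stop,
length not a multiple of 3, internal stops) flag the transcript rather than
silently dropping it; internal stops and frame defects exclude a gene from
all analyses, a missing terminal stop only from the exon-based ones.

The exon-level machinery assigns each codon to the exon that completely
encodes it; junction-spanning codons belong to no exon and are excluded
from per-exon metrics and from both boundary windows. The last exon of a
transcript is "reliable" when the CDS ends in a stop codon, no exon lies
downstream of the stop-containing exon, and the spliced 3' UTR is at least
100 nt (the 3' UTR criterion is interpreted as spliced length). Boundary
windows mirror the NMD geometry: a 3' window of the first 50 codons fully
inside the last exon (NMD-compromised) and a 5' window of 50 codons ending
at least `buffer_nt` nucleotides upstream of the last junction
(NMD-competent), snapped conservatively upstream to a codon boundary.
Because the "50–55 nt rule" boundary is itself uncertain, `buffer_nt` is a
parameter (default 50 nt), as is the window size (default 50 codons) and
the last-exon minimum (default: more than 100 fully encoded codons).

ESE (exonic splicing enhancer) coverage is the union of hexamer hits
(overlaps merged) over a nucleotide context; a codon "overlaps" an ESE when
any of its three nucleotides is covered. Fop, the fraction of optimal
codons, has a raw mode (optimal codons over codons of amino acids with at
least two synonyms) and a `gc_controlled` mode constructed exactly like
NFCU (per-family GC-matched subgroups mixing optimal and non-optimal
codons, averaged); the controlled variant's published definition is only
summarized in the source material, so this NFCU-analogous construction is
an interpretation, isolated behind the mode switch.

## Ka/Ks

Selective-constraint binning needs only quartile ranks of Ka/Ks, which are
robust to estimator choice at mouse–human divergence. The built-in
estimator is Nei–Gojobori (1986) with equal pathway weighting and the
Jukes–Cantor correction; substitutions to stop codons count as
nonsynonymous (so synonymous + nonsynonymous sites equal three per codon),
and pathways through stop codons are excluded unless all pathways are
blocked. A precomputed table (`read_kaks_table()`) bypasses the estimator
entirely. Multiple co-orthologs are resolved by keeping the longest
partner, ties by identifier order — a deterministic stand-in for the
original's random tie-break, chosen so runs are reproducible.

## Comparison statistics

All tests are two-sided, with conventions fixed so p-values are
bit-for-bit reproducible: average ranks, tie-corrected variance and a 0.5
continuity correction in the normal approximations; exact enumeration for
the rank-sum and signed-rank tests at small sample sizes without ties
(signed-rank additionally requires that no zero differences were dropped,
matching the standard reference implementation); the sign test is an exact
binomial; Spearman's rho uses the t approximation for p and a Fisher-z
interval with standard error $1/\sqrt{n-3}$ for its CI (the source does
not state a CI method). Quantile bins are computed on the pooled
distribution, with edge values assigned to the lower bin and duplicate
edges merged with a warning. These are deliberately independent
implementations — the test suite uses `wilcox.test()`, `binom.test()` and
`cor.test()` as external references rather than wrapping them.

## The synthetic world

The generator (`synthetic_config()` + `build_genome()`) emits FASTA, GFF3
and a truth manifest. Its defaults *are* the validation world: 2000
multi-exon and 500 single-exon genes; fragile-codon weights derived in
closed form from target ratios of 0.92 (single/multi gene-level NFCU,
matching the human intergenic depletion), 0.93 (last/upstream NFCU within
multi-exon genes, the ~7% last-exon depletion), 0.68 for the histone-like
class when requested, and a FAU target of 0.83 (0.76 for histones).
Remaining structural choices, stated once: exon counts
$2 + \mathrm{Poisson}(4)$ (mean ≈ 6); CDS lengths uniform over 150–700
codons (multi-exon), 100–500 (single-exon, shorter as in real genomes) and
100–160 (histone-like); per-gene GC targets uniform on 0.40–0.60
(isochore-like variation); introns 60–200 nt, GT..AG-flanked, placed
uniformly over CDS nucleotide boundaries so junction phases are uniform
over \{0,1,2\}; 5' UTR 100 nt; 3' UTRs 120–300 nt for reliable genes.

Three design points matter for interpretation:

* **Weights act within synonymous families.** The fragile-codon weight
  $\varphi$ multiplies fragile members within each codon family, the
  fragile-amino-acid weight $\psi$ reweights residues, and the GC target
  biases only choices among equal-fragility synonyms. A group with $f$
  fragile and $r$ robust members then has expected fragile fraction
  $\varphi f / (\varphi f + r)$ regardless of $\psi$ and GC — the three
  knobs are orthogonal by construction, which is precisely what lets the
  tests verify that NFCU isolates codon-level signal from amino-acid and
  compositional signal.
* **Calibration is analytic, not fitted.** Target ratios are inverted
  through the closed forms (`expected_nfcu()`, `expected_fau()`). The
  single-exon weight is calibrated against the *gene-level* multi-exon
  expectation, a mixture of upstream and depleted last-exon usage weighted
  by the expected last-exon codon share $E[1/\text{exon count}]$ under the
  exon-count distribution.
* **What a green test does not establish.** The generator draws residues
  and codons i.i.d.; real genes have autocorrelated composition, codon
  pair effects, isochore structure, ESE constraints and non-uniform exon
  sizes. Recovery of the configured ratios validates the pipeline's
  bookkeeping and estimators, not any biological claim about real genomes.

## A numerical subtlety: exon-level medians snap to a lattice

Per-exon NFCU is an average of group fractions with tiny denominators, so
its distribution is concentrated on lattice points (0, 1/3, 1/2, 2/3, 1,
and small averages of these). Medians of such distributions snap to atoms:
on the synthetic genome the pooled exon-level median ratio lands near 0.87
although the generative region ratio is 0.93 (the published exon-level
table shows the same fingerprint — an upstream median of exactly 0.50).
The per-gene paired comparison — last-exon NFCU against the NFCU of the
pooled upstream sequence of the same gene, which is long and lattice-free —
recovers the generative ratio well, so `run_intragenic()` reports both: the
pooled exon-level table for comparability, and the paired medians/ratio
(plus sign, signed-rank and rank-sum tests) as the preferred estimate of
region-level depletion.

## Other numerical choices

* Terminal stops are stripped before any metric; the initial methionine is
  counted in FAU/NFAU (it belongs to no NFAU group, so NFAU is
  unaffected).
* Unweighted mean across groups, not pooled counts, per the definition of
  the normalized metrics ("average of all fractions that are defined").
* Codons containing N are excluded from numerator and denominator and
  tallied as skipped.
* The binomial (sign) test is two-sided; the source wording does not
  specify sidedness.
* p-values are reported in full precision in all outputs; truncated
  renderings such as "<1e-15" are a formatting concern left to callers.

## Known limitations

* Only the standard nuclear genetic code is supported; fragile codons are
  not weighted by their number of stop neighbors or by a mutation
  spectrum.
* NG86 ignores transition/transversion bias; at high divergence
  (p ≥ 3/4) the correction is undefined and pairs are flagged instead.
* The generator does not model alternative isoforms, UTR introns beyond
  the downstream-exon unreliability case, or splice-site strength.
* ESE coverage is computed on the spliced CDS, ignoring exon boundaries;
  window-level partitioning uses CDS-relative coordinates.

## A worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(n_multi = 300, n_single = 150, seed = 7)
gen <- build_genome(cfg, dir = tempfile())
gms <- load_annotation(gen$fasta, gen$gff3)
ig <- run_intergenic(gms)
ig$NFCU
ia <- run_intragenic(gms)
ia$paired$ratio
```

The README shows the output these commands print at the default
(2000 + 500 gene) scale.
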