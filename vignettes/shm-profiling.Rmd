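---
title: "Profiling somatic hypermutation in TCR cDNA clone sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling somatic hypermutation in TCR cDNA clone sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrshm)
library(dplyr)
```

## The problem

Somatic hypermutation (SHM) introduces point mutations into rearranged
antigen-receptor genes at roughly a million times the background genomic
rate. Classically an antibody affinity-maturation mechanism, it also
operates on T-cell receptor (TCR) genes in several vertebrate lineages,
where it can diversify both the variable (VJ) region and — more
surprisingly — the constant (C) region. Detecting it from Sanger-sequenced
cDNA clone sets means answering a chain of questions, each of which this
package implements as a tested, reusable stage:

1. What is the germline baseline? (consensus inference, allelic/allotypic
   positions, near-identical gene subgroups, PCR-jumping chimeras)
2. Which differences from that baseline are somatic mutations, and of what
   kind? (substitution vs indel, transition vs transversion, replacement vs
   synonymous vs nonsense vs frameshift, per-region assignment)
3. Are particular nucleotides or k-mers targeted? (mutability index with
   chi-square significance)
4. Do mutations sit in known SHM motifs? (AID hotspots RGYW/WRCY,
   polymerase-eta WA/TW)
5. Where are the J gene segments in genomic sequence? (core-motif + RSS +
   splice-donor scanning)

Because the original fish data are not required, a truth-tagged synthetic
repertoire generator (`sim_config()`, `simulate_repertoire()`) provides
ground truth for every stage; the test suite is built around
parameter-recovery experiments on that generator.

## The mutability index

For a k-mer $w$ (k = 1, 2, 3) with relative frequency $f_w$ in the
germline reference and $N$ observed substitutions in the clone pool,

$$\mathrm{MI}(w) = \frac{\mathrm{obs}_w}{f_w \cdot N},$$

so MI = 1 means targeting proportional to composition, MI > 1 a hotspot,
MI < 1 a cold spot. Expected counts conserve the total by construction
($\sum_w f_w N = N$). Each k-mer gets a two-cell goodness-of-fit test
(df = 1):

$$\chi^2 = \frac{(\mathrm{obs}-\mathrm{exp})^2}{\mathrm{exp}} +
\frac{(\mathrm{obs}-\mathrm{exp})^2}{N-\mathrm{exp}},$$

with significance flagged at 0.01 and 0.001 and no multiple-testing
correction (the number of tests is small and is recorded on the result).

**Attribution convention.** Published mutation tables rarely state how a
mutated base is attributed to di- and trinucleotides. We use a
single-attribution rule — the dinucleotide *starting* at the mutated
position (falling back at the last base), the trinucleotide *centred* on
it (edges excluded) — because it keeps $\sum \mathrm{obs} = N$ and makes
observed and expected counts directly comparable. An alternative
`rule = "both"` attributes dinucleotide events to both overlapping
windows, with a correspondingly doubled total. This is a convention, not a
discovery; results at k = 2, 3 should be read with it in mind.

**Recovering a planted bias.** MI is normalised to the pooled mutation
total, so if one base is given a rate multiplier $b$ the *index* converges
to $b / \bar b$, where $\bar b$ is the composition-weighted mean
multiplier — not to $b$ itself. The recovery tests therefore estimate the
multiplier as the ratio of MI at the biased base to the pooled MI of the
unbiased bases, which is a consistent, truth-free estimator of $b$.

```{r}
cfg <- sim_config(seed = 203, n_clones = 200, v_length = 0, c_length = 999,
                  mutation_rate = 4e-3, indel_rate = 0,
                  base_bias = c(A = 2.5, C = 1, G = 1, T = 1))
sim <- simulate_repertoire(cfg)
rec <- call_mutations(sim$clones, germline_reference(sim$reference$c_a))
tab <- mutability_table(rec, sim$reference$c_a, k = 1)
tab
other <- tab$kmer != "A"
tab$mi[tab$kmer == "A"] / (sum(tab$observed[other]) / sum(tab$expected[other]))
```

## Germline inference and alleles

`infer_germline()` takes the per-column consensus of an alignable clone
pool as the reference. A column whose second most frequent base reaches
`allele_threshold` (default 0.3) of calls is recorded as an *allelic
position* — the signature of two alleles at roughly 50/50 — and is
excluded from somatic-mutation calling. The default 0.3 sits between the
~0.5 expected for a true heterozygous site and the low frequencies of
recurrent somatic mutations in pools of 20-50 clones; it is configurable.
Three-way ties are refused rather than guessed. `split_subgroups()` then
partitions clones purely by their bases at the allelic positions (not by
whole-sequence distance), giving each haplotype its own reference so an
allelic difference can never be double-counted as a mutation.

Constant-region allotypes are genotyped against supplied diagnostic-position
profiles (`genotype_allotypes()`): nearest profile wins, ties abstain,
more than `max_mismatch` diagnostic mismatches flags a novel-allotype
candidate, and a homozygous call requires one profile to explain at least
95% of assignable clones. `flag_chimeras()` marks the single-crossover
pattern (a 5' run matching one allele, a 3' run matching the other, at
least two diagnostic sites per side) that PCR template-switching produces;
interleaved patterns are treated as mutations instead.

## Mutation calling choices

* **Alignment.** Clones align to the reference ends-free (match +1,
  mismatch −1, gap open −4, extend −1, terminal gaps free). Near-identical
  sequences make the scores uncritical; they are fixed for determinism.
  Equal-length pairs at < 10% divergence shortcut to the identity
  alignment, which is provably optimal there (a compensating
  insertion–deletion pair costs at least 8).
* **Effect calls.** Each substitution is classified by translating its
  germline codon with only that substitution applied; a brute-force
  full-translation oracle confirms agreement whenever a codon carries at
  most one change. Events 3' of a frameshifting indel are still recorded
  at the nucleotide level but classified `noncoding`.
* **Denominators.** Mutation frequencies divide by surveyed
  reference-aligned bases, excluding primer-masked spans and N columns —
  the same accounting used for the published per-individual tables.
* **Printed precision.** Report ratios are truncated toward zero at two
  decimals (26/14 prints as 1.85); full precision is always retained in
  the returned tibbles, `printed_value()` only formats.
* **N bases.** Columns with N in either sequence are excluded from both
  event calling and composition/denominator counts, avoiding phantom
  mutations.

## Motif scanning

RGYW is scanned as `[AG]G[CT][AT]` with the G mutable, WRCY as
`[AT][AG]C[CT]` with the C mutable; the two patterns are reverse
complements of each other, which the tests exploit as a strand-symmetry
invariant. WA/TW get the analogous mutable-position semantics (the A of
WA, the T of TW). Scanning is on the sense strand of the germline, all
overlapping hits are kept, and a mutation only counts as motif-linked if
it sits exactly at a hit's mutable position with the matching germline
base — a mutation elsewhere in the window is tallied separately as
in-window/non-mutable.

## J-segment discovery

A candidate J exon is a 36-75 nt window whose translation in some frame
contains an FGXG-like core (`[FW]G.G` by default, admitting the slightly
modified cores seen in real loci), preceded immediately by a 12-spacer
RSS (heptamer `CACAGTG` with the invariant `CAC` exact and at most one
further mismatch; nonamer `ACAAAAACC` with at most two mismatches; spacer
12 ± 1 nt) and followed immediately by a `GT` splice donor. Both strands
are scanned; overlapping candidates keep the highest score
(`(2 − heptamer mm) + (2 − nonamer mm) + 1 if the core is strictly FGXG`),
ties to the leftmost. The consensus sequences and budgets are the
canonical operationalization of an RSS and are fully configurable.
Validation plants rule-complete cassettes in random background: at strict
budgets the scanner returns exactly the planted set; at default budgets it
must miss none.

## What the generator does and does not emulate

`simulate_repertoire()` draws, per clone: an allele (heterozygous configs),
a uniform J segment, frame-preserving junction trimming/addition, then
independent per-site substitutions with hazard
`rate x base_bias(base) x motif_multiplier(site)`, transitions with
probability `transition_prob`, and Poisson frameshift deletions. Defaults
are fixed at the restricted-PCR study conditions: 48 clones, 4.5
substitutions per kb, transition fraction 0.53, two expected frameshift
clones per 48, 25 J segments, uniform composition, 50/50 allele use.

Deliberate simplifications: no clonal lineage structure (the statistics
under test are marginal counts), motif multipliers are evaluated on the
unmutated template (static targeting, matching how the analysis scans the
germline), junctional length variation is kept in-frame (expressed
repertoires are selected for frame; out-of-frame clones enter through the
indel rate instead), and sequencing error is not modelled separately from
SHM. Passing recovery tests therefore demonstrates correctness of the
statistics under these assumptions, not robustness to, say, lineage
bursts or base-caller artefacts in real chromatogram data.

Problem sizes in the test suite (200 clones x 1 kb for rate and MI
recovery, 100 replicates for false-positive control, 50 kb scaffolds with
12 planted cassettes, 10,000 single-substitution classification cases)
were chosen as the smallest sets at which the binomial noise bands in the
assertions are comfortably narrow.

## Degenerate inputs and tie-breaks

* Consensus ties between the top two bases resolve alphabetically; true
  three-way ties are an error naming the columns.
* Clones equidistant between allelic haplotypes are flagged unresolved and
  excluded (with a count) rather than guessed.
* J assignment ties break toward the lowest library index; V-family labels
  order by family size, then first occurrence, making labels
  permutation-stable.
* Rate contrasts with zero control events report `NA` with a note instead
  of an infinite ratio; zero events in both groups give `NA` throughout.
* `expected = 0` with observations is flagged "unattributable" rather than
  silently dropped.

## Known limitations

* The ends-free aligner can absorb a terminal substitution into an
  overhang on very short fragments; germline inference therefore uses
  direct columns for equal-length pools.
* With multiple substitutions in one codon, per-event classification
  against the germline codon differs from whole-codon classification;
  at the observed per-site rates (< 0.005/bp) double-hit codons are rare.
* Di/trinucleotide MI depends on the attribution convention above;
  cross-study comparisons should verify the convention matches.
* The J scanner's spacer band default (12 ± 1) targets J-type RSS; V-type
  23-spacer elements need a different `jscan_config()`.
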