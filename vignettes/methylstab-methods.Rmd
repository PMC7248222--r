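---
title: "methylstab: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methylstab: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylstab)
```

# Scope and model

`methylstab` analyses N6-methyladenine (m6A) at palindromic
restriction–modification target motifs — GATC and CATG in the chlorovirus
system it was designed around — from PacBio-style per-site modification
calls. It deliberately consumes the *outputs* of the kinetics software
(ipdRatio, ModificationQV, coverage, methylFrac per strand-position) and
never re-estimates kinetics: the statistical test inside the base-calling
pipeline is out of scope, as are raw reads, assembly and external
methyltransferase databases.

Because the motifs are reverse-complement palindromes, one forward-strand
occurrence defines a two-strand *locus* carrying exactly one target adenine
per strand: for both GATC and CATG the forward adenine is the motif's
second base (`start + 1`), and the reverse-strand adenine pairs with the
forward thymine at `start + 2`. All internal coordinates are 0-based
half-open; emitted GFF3/BED follow their standards (1-based inclusive and
0-based half-open respectively).

## Motif-landscape statistics

* **Expected recurrence.** Under i.i.d. bases with
  $P(G)=P(C)=g/2$, $P(A)=P(T)=(1-g)/2$, a motif with two strong and two
  weak bases occurs with probability $(g/2)^2((1-g)/2)^2$ per position —
  once every 278 bp at $g = 0.4$. An alternative reading of the published
  description of this model multiplies one strong and three weak
  probabilities (yielding 185 bp), which contradicts the 278 bp figure it
  accompanies; we implement the two-strong/two-weak product, which is the
  self-consistent one for these motifs. This is a point probability, so
  overlapping occurrences are counted by the step-1 scanner and never
  de-overlapped.
* **Observed recurrence** is genome length divided by locus count — the
  "once every X bp" convention — while the **index of dispersion** is the
  variance-to-mean ratio of successive inter-start spacings. Dispersion
  over windowed counts would be an equally defensible definition; spacings
  were chosen because the mean-interval phrasing is spacing-based. The
  variance is the population variance (denominator $n$): the gap set is
  the complete population, not a sample. Fewer than two loci yield `NA`
  sentinels, not errors.
* **Motif-free gaps** are measured between merged motif footprints
  (end of one occurrence to start of the next), with the terminal segments
  included as candidates; with zero loci the whole genome is one gap.
* **Window enrichment (ME)** is observed loci per 278 bp window divided by
  the expected two (one per motif). The score is a ratio, not the
  "observed minus expected" a literal reading of the original method text
  suggests: the published worked values (9 loci → 4.5, 7 → 3.5, 8 → 4) are
  exactly count/2, and a worked table outranks prose. Windows at or above
  the threshold (default 3.5, which reproduces the published top-ten cut)
  are merged by overlap; the region score is the maximum member ME. The
  exact merging that produced the original region tables is unpublished;
  union-of-qualifying-windows is the simplest procedure consistent with
  their 279–415 bp spans, and it is idempotent.
* **Depletion** per gap is $139/\mathrm{length}$ at the defaults
  (reciprocal of the expected $2 \cdot \mathrm{length}/278$), so fold < 1
  flags depletion and `fold * expected == 1` exactly.
* **Gene/class correlation** codes transcription classes ordinally
  (Early = 0, Early-Late = 1, Late = 2; Unknown excluded) and correlates
  size-normalised per-gene locus counts with the code (Pearson). The
  mapping is minimal and documented rather than principled — the original
  analysis reports essentially zero correlation, and any monotone coding
  preserves that conclusion.

## Modification calls and thresholds

| parameter | default | meaning |
|---|---|---|
| `ipd threshold` | 2 (strict >) | kinetic evidence of modification at a strand-position |
| `qv_threshold` | 30 | Phred-scaled call quality; QV 30 ⇔ p = 0.001 |
| `binarize` | 0.5 (≥) | per-replicate methylFrac cut for the stability k-count |
| `threshold` (palindromes) | 0.75 (strict >) | per-strand mean methylFrac for a methylated strand |
| `window` | 278 bp | expected recurrence interval at 40% GC |
| `expected` | 2 per window | one occurrence of each motif |

Boundary conventions are deliberate and tested: ipdRatio exactly 2 does
not count (the published census says "> 2"); a methylFrac of exactly 0.5
counts as methylated (≥, a deterministic tie-break); a strand mean of
exactly 0.75 does not make a strand methylated (the rule is "> 75% of
reads"). The high-ipd fraction uses 2 × genome length as its denominator
(both strands, N positions included).

Parsers never invent data: a GFF record without `frac` keeps it missing.
The *stability* stage is the one place where absence becomes 0.0 — a
strand-site with no modification call in a replicate whose per-position
table covers the genome is evidence of non-methylation there.

The 75% rule is applied to the cross-replicate *mean* per strand (matching
"methylated on average in > 75% of reads"), not per replicate; strand
means come from the same records as the stability stage, so the two
classifications cannot disagree about the underlying fractions.

## Stability classes

With three replicates the k-count of binarised methylFrac values maps
bijectively to four classes: stable_methylated (k = 3), methylated_in_two,
methylated_in_one, stable_nonmethylated (k = 0). This k-count rule
reproduces mean-based quadrant binning at means ≈ {0, ⅓, ⅔, 1} while
remaining crisp for intermediate fractions. Note that the published figure
caption and body text for this analysis swap the k = 1 and k = 2 event
counts (457 vs 143); we follow the body text (457 sites methylated in two
replicates), and the simulator's strand-class defaults
(0.807, 0.131, 0.041, 0.021 for k = 3, 2, 1, 0) do the same.

# The synthetic world

The generator's defaults are a statement of the conditions the analysis
was designed for, not tuning knobs: a 330,611 bp genome at 40% GC; three
replicates at 30× coverage; palindrome states drawn per locus at
(fully 0.619, hemi 0.31, stochastic 0.071); per-read methylation
probability 0.97 at a methylated strand-site and 0.02 at a non-methylated
one; 9% background high-ipdRatio at non-motif positions.

* **Composition** is i.i.d. — no dinucleotide or codon structure. That is
  sufficient for the statistics under test (which condition only on locus
  positions and GC) and is a documented limitation: the synthetic genome
  is *not* depleted in the motifs the way a genome under RM selection is,
  so a default simulation yields ≈ 2,400 loci rather than the 1,749 of the
  real reference.
* **Planted features.** A motif-free gap is planted by anchoring motifs at
  both ends and destroying every interior occurrence; an enriched window
  by clearing then writing k evenly spaced motifs. Occurrences are
  destroyed by overwriting their middle two bases with `AA`: neither
  motif contains `AA`, starts with A, or ends with A, so the patch can
  never seed a new occurrence nor damage an adjacent kept motif — a
  one-pass-safe scrub that the tests verify by rescanning.
* **Latent model.** Every strand-site gets a latent methylation indicator
  per replicate. *fully* methylates both strands in all replicates; *hemi*
  one strand (chosen uniformly); *stochastic* flips a fair coin per
  strand-site and replicate — matching the observed phenomenology of
  complete methylation in only one or two replicates. methylFrac is then
  Binomial(coverage, π)/coverage; ModificationQV is 30 + geometric jitter
  (mean 9, i.e. jitter probability 0.1) for methylated draws and uniform
  on 0–20 otherwise, tying the QV to the latent draw rather than to a
  kinetics likelihood (which is out of scope); ipdRatio is Normal(4, 0.8)
  truncated at 2 for methylated adenines and Normal(1, 0.25) truncated at
  0 otherwise. Emitted values are quantised (ipdRatio to 2 decimals,
  fractions to 4) *at generation time* so that the file writers and
  readers round-trip bit-identically.
* **Two planting modes.** The locus-level model above cannot reach the
  published strand-class proportions (it implies ≈ 0.78/0.03/0.03/0.16
  against the published 0.807/0.131/0.041/0.021 — the real data's strand
  and palindrome marginals are not jointly consistent with this simple
  generative family). The generator therefore also supports `"strand"`
  mode, planting strand classes directly from
  `strand_stability_proportions`, used to validate the stability
  classifier against exact planted counts; `"locus"` mode remains the
  default and validates the palindrome classifier.
* **Ground truth** records both the *drawn* labels and the *realized*
  latent indicators. Recovery is asserted against the realized truth: a
  "stochastic" locus whose six coin flips all land methylated is, in the
  emitted files, indistinguishable from a fully methylated locus, so only
  the realized comparison makes the noiseless 100%-recovery criterion
  well-posed.

**What a green test establishes.** Noiseless recovery shows the
classification plumbing is exact; default-noise recovery within binomial
confidence intervals shows the thresholds are placed far from the noise
(at coverage 30, π = 0.97/0.02, misbinarisation probabilities are
≈ 10⁻¹²). It does *not* establish robustness to real-data pathologies the
generator omits: coverage variation, mapping artefacts, secondary ipd
peaks adjacent to true m6A, non-adenine modifications, or molecule-level
heterogeneity.

# Degenerate inputs and errors

Non-palindromic motifs are rejected (strand pairing undefined), as are
GC fractions of exactly 0/1 when the motif needs the absent base class.
Duplicate (position, strand) keys and header mismatches reject a CSV;
malformed GFF3 lines and bad coordinates are skipped with warnings;
unknown modification types are kept as `modified_base`. Fewer than three
classed genes make the correlation undefined (`NA` with a warning), and
fewer than two loci make dispersion undefined — sentinels, not errors,
because both arise legitimately on small inputs.

# Known limitations

* The real-reference acceptance path needs NC_000852 supplied externally
  (`$PBCV1_REFERENCE_FASTA`); it is too large to ship as a plain-text
  fixture and the published genome cannot be regenerated from code.
* Published percentages are reproduced to their printed precision ± one
  unit in the last digit; the source's own rounding is internally
  inconsistent in one place (80.76% printed as 80.7%).
* The CLI is a thin dispatcher over the R API; it does not expose every
  parameter.
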