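---
title: "Duplex consensus, mutational spectra and context enrichment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplex consensus, mutational spectra and context enrichment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexspectra)
```

## What the package computes

`duplexspectra` turns duplex-tagged paired-end reads of a reporter target
region into error-corrected mutation calls and downstream summaries:

1. **Duplex consensus.** Reads are grouped into strand families by their
   molecular tags; each family is collapsed to a single-strand consensus
   sequence (SSCS); complementary families are combined into double-strand
   consensus sequences (DCS) in which a base is accepted only when both
   strands agree perfectly. Because the two strands of one source molecule
   acquire PCR and sequencing artifacts independently, requiring duplex
   agreement suppresses those artifacts by many orders of magnitude — the
   property that makes reporter-scale mutagenesis sequencing feasible at
   per-base mutation frequencies of 10^-7^ and below.
2. **Mutation calling.** DCS reads are placed on the reference by ungapped
   exact-seed alignment, piled up, and substitutions are called per column.
   Calls are collapsed to *unique mutations*: a mutation at a given genomic
   location is counted once, however many independent molecules carried it.
3. **High-resolution mutational spectra.** Unique mutations are classified
   into the 96 pyrimidine-centered trinucleotide channels, normalized by the
   trinucleotide composition of the sequenced target, optionally
   background-corrected by subtracting a vehicle-control spectrum, and
   compared to substitution signatures by cosine similarity.
4. **Probability-logo enrichment.** For a fixed substitution (by default
   G→A), 15-base windows centered on the mutated base are compared to all
   center-matched windows of the target; each (position, base) cell gets a
   signed binomial log-odds height with a Bonferroni-corrected significance
   bar.
5. **Reporter-assay statistics.** Mutant frequencies from colony counts
   (6-thioguanine-resistant over chloramphenicol-resistant titer), group
   fold changes, and exact Mann–Whitney U comparisons.

A seeded synthetic generator (`simulation_config()`, `simulate_molecules()`,
`simulate_reads()`, `simulate_gpt_counts()`) produces duplex libraries with
known injected truth so that every stage is testable without external data.

## The duplex consensus model

### Tag scheme and family geometry

Each source molecule receives a random tag pair (α, β), one arm per
fragment end, prepended in-sequence and separated from the insert by a fixed
5-nt spacer. Read pairs from the "top" strand observe the tag order (α, β);
pairs from the complementary strand observe (β, α). The family key is made
orientation-invariant by sorting the two tags (`canonical_family_key()`);
the observed order then labels the strand. Read 1 of one strand covers the
same fragment end, in the same orientation, as read 2 of the complementary
strand, so DCS formation is a direct per-position comparison of the two
consensus sequences with no re-orientation step. Families whose two tag arms
are identical have undefined strand and are dropped; with 12-nt tags this is
vanishingly rare.

### Consensus rules and their parameters

* `min_family_size` (default **3** reads per strand): families below the
  minimum yield no SSCS. The original consensus software this stage
  reimplements does not print its thresholds in the source publication;
  3 is that tool's conventional default and is exposed in every interface.
* `consensus_threshold` (default **0.7**): per position, the plurality base
  is accepted if its supporting fraction reaches the threshold; ties or
  sub-threshold support give N.
* DCS: a base is kept only where both SSCS agree and neither is N —
  "perfect agreement" implemented at base resolution. Disagreements are
  masked to N rather than discarding the whole read, which preserves read
  coordinates for the pileup; `reject_on_disagreement = TRUE` provides the
  whole-read alternative because the source method's choice between the two
  is not documented.
* Trimming (default 1-based read positions **1–8 and 120–137**): consensus
  read ends carry residual adapter/end-repair artifacts; the default ranges
  leave a 111-nt informative window in a 137-nt read. Trimming masks rather
  than cuts, again to preserve coordinates.

### Placement

DCS reads are placed by exact-match seeding on 20-mers tiled across every
non-N run (so that an isolated substitution inside one seed cannot defeat
placement), in both orientations, followed by ungapped extension scored as
identity over non-N positions; placements below `min_identity = 0.9` are
dropped as unmapped. This placer is exact for the substitution-only reads
the simulator produces and keeps the package dependency-free; externally
produced coordinate-sorted alignments can be piled up directly through
`pileup()` for real, indel-containing data, and gapped alignment is out of
scope.

## Spectrum construction

Channels use the pyrimidine-centered convention (`A[C>T]G` …): a purine
reference base is mapped through the reverse complement of its context, so
the 192 raw (ref, alt, context) combinations collapse exactly two-to-one
onto 96 channels. Normalization divides each channel's count proportion by
the strand-collapsed relative frequency of its trinucleotide in the target
and rescales to sum one: a context that is rare in the target but
frequently mutated is thereby up-weighted to a per-opportunity rate.
Background subtraction operates on normalized frequencies with clamping at
zero, then renormalizes — subtract-then-normalize, the order used for
baseline-corrected signature comparison; a counts-scale subtraction mode
exists because the scale matching between treated and control libraries is
a judgement call. Multi-animal group spectra average per-animal normalized
frequencies by default (`average_spectra()`), with a `pool_counts` switch.

Purine-centered display (`plot(s, purine_centered = TRUE)`) relabels
channels on the opposite strand for GC→AT-dominated spectra, the convention
often used for reporter-region figures; the stored object is always
pyrimidine-centered for direct comparability with signature catalogues.

## Probability-logo statistics

For foreground count k of base b at position j among n(fg) windows, with
background probability p equal to that base's frequency at j among the
n(bg) center-matched target windows:

* overrepresentation: P = Pr[X ≥ k], X ~ Binomial(n(fg), p), height
  = log10((1−P)/P) (positive);
* underrepresentation: P = Pr[X ≤ k], height negated;
* k/n = p gives height 0.

Tails are computed in log space from exact binomial tail sums — no normal
approximation and no capping, so extreme cells report their true magnitude
(heights in the hundreds are meaningful, not saturated). The significance
bar is the log-odds of the Bonferroni-corrected level: with α = 0.05 over
14 variable positions × 4 bases = 56 cells, log10((1−α′)/α′) = 3.05. The
56-cell count is the unique choice consistent with that printed bar (60
tests would give 3.08).

Two numerical guards: a background cell with zero observed frequency but
non-zero foreground would give an infinite height, so p is floored at
1/(n(bg)+1) with a warning; and the fixed center position is excluded from
the table entirely.

**Null model.** The calibration check treats the null foreground as a
context-indifferent *set of unique mutations*. Unique mutations occupy
distinct genomic sites, so the matched null draws n(fg) windows from the
background **without replacement**. Under that hypergeometric null the
binomial bar is conservative and a clean logo is the overwhelmingly likely
outcome. Had the null been an iid (with-replacement) draw, the ±bar — which
corresponds to one-directional α/56 per cell — would flag some cell in
either direction in roughly 2α of replicates; that is a property of the
published bar convention, not of this implementation, and the package's
tests verify both the distinct-site calibration and the invariant that the
expected fraction of falsely significant cells stays below α.

## The synthetic generator

The generator emulates the study design the analysis targets, and its
defaults are the study conditions:

| parameter | default | meaning |
|---|---|---|
| target | ~6.4 kb region (any FASTA accepted) | reporter-scale sequencing target |
| `fragment_length_range` | 300–350 bp | sonication size window |
| `read_length` | 137 nt | consensus-visible bases per read end |
| `tag_length` | 12 nt per arm | duplex tag |
| `family_size_distribution` | Poisson, mean 5, min 0 | reads per strand family |
| `per_base_error_rate` | 1e-3 | strand-level artifact rate |
| `mutation_rate` | 1e-4 per molecule-base | true mutation load (set per experiment) |

True mutations are injected by first drawing a 96-channel from the
configured spectrum and then a concrete site uniformly among the reference
positions inside the fragment whose trinucleotide context matches that
channel on either strand — so the expected recovered spectrum equals the
configured one, and channels without matching sites are renormalized away
with a warning. Per-strand artifacts are independent across reads and
strands, which is exactly the error class duplex agreement must remove.
The family-size distribution is a modeling choice (real library chemistry
is not documented at that level); it is exposed in the configuration, and
`family_size_min = 0` deliberately produces strands with no reads so the
unpaired-SSCS path is exercised.

What the generator does **not** model: PCR jackpot trees, quality-score
error profiles, GC/coverage bias, indels, tag errors beyond uniform
substitution. Consequently a passing recovery test demonstrates the
*logic* of consensus, calling, normalization and enrichment — not
robustness to every artifact class of real libraries.

The reporter-assay simulator draws per-animal chloramphenicol titers
lognormally and 6-TG counts as Poisson around titer × true mutant
frequency × a gamma overdispersion factor (mean 1), a standard
hierarchical model for fluctuation-assay counts.

## Statistical choices

* **Mann–Whitney U**: exact two-sided p by full enumeration of all
  C(na+nb, na) group labelings with midranks; two-sided p is twice the
  smaller tail, capped at 1. For two groups of five, complete separation
  gives 0.0079 and a single crossing 0.0159 — the exact small-sample
  values, which a normal approximation would not reproduce. Enumeration is
  limited to 12 observations per group.
* **Unique-mutation key**: (region, position, alt) by default, so two
  different alternate alleles at one site remain distinct spectrum events;
  `dedup_by = "position"` gives the stricter one-per-site reading. Both are
  supported because "a mutation at a given location is counted once" does
  not fix the allele question.
* **No depth/VAF thresholds on calls**: every DCS base is an independent
  molecule; clonal expansion is handled by the uniqueness collapse.

## Problem sizes used in the tests

The end-to-end recovery checks simulate an 8-animal cohort of 500 molecules
each (mutation rate 5e-3 per molecule-base, strand artifact rate 1e-3) on a
6382-nt synthetic target — about 3,000–3,500 pooled unique mutations, the
scale at which a 96-channel spectrum is well determined while per-animal
unique-site saturation stays mild. Error suppression is checked over >1e5
informative DCS bases with zero injected mutations, and truth-set equality
over a 500-molecule run with zero artifacts. These sizes were chosen as the
smallest cohorts at which the corresponding statistics are stable.

## Known limitations

* Substitution-only throughout (simulator, placer, caller); indels and
  multi-nucleotide variants are out of scope.
* Tags must match exactly; there is no tag-error correction or clustering,
  so reads with tag substitutions found singleton families (as in the
  original approach).
* The built-in placer is not a general aligner; real data should be aligned
  externally and fed in as placements.
* Signature vectors are inputs; the package neither derives nor refits
  signatures (no deconvolution).
* Spectra from very small mutation sets are noisy; `normalize_spectrum()`
  flags channels whose context is absent from the target rather than
  imputing them.
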