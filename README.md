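# duplexspectra

Error-corrected mutagenesis sequencing of a reporter target region, from raw
duplex-tagged reads to high-resolution mutational spectra (HRMS) and
sequence-context enrichment statistics.

Transgenic-rodent mutagenesis studies increasingly pair the classical
reporter selection assay (mutant frequency from 6-thioguanine-resistant vs
chloramphenicol-resistant colony counts) with duplex sequencing (DS) of the
reporter region, which reads out *all* point mutations without phenotypic
selection. DS tags both strands of every source DNA molecule; reads sharing
a tag are collapsed to single-strand consensus sequences (SSCS), and a base
is accepted only where the two complementary SSCS agree perfectly
(double-strand consensus, DCS). Strand-independent PCR/sequencing artifacts
vanish under that agreement rule, so mutation frequencies far below the raw
sequencer error rate become measurable.

`duplexspectra` reimplements this analysis as a tested, dependency-light R
package:

* **consensus** — tag parsing, strand-family grouping, SSCS (plurality with
  threshold, default family minimum 3, threshold 0.7), DCS
  (perfect-agreement masking), end trimming (default read bases 1–8 and
  120–137, leaving a 111-nt window per 137-nt read);
* **calling** — ungapped exact-seed placement, pileup, per-column
  substitution calls, collapse to unique mutations (a mutation at a given
  genomic location is counted once);
* **spectra** — 96-channel pyrimidine-centered trinucleotide spectra
  (`A[C>T]G`, …), normalization by target trinucleotide composition,
  background (vehicle-control) subtraction, cosine-similarity matrices
  against signature vectors;
* **probability logo** — for 15-base windows centered on a fixed mutated
  base, per-position/per-base signed binomial log-odds
  `height = log10((1-P)/P)` of the exact tail probability, with the
  Bonferroni bar `log10((1-α/56)/(α/56)) = 3.05` at α = 0.05 over 14
  positions × 4 bases;
* **assay statistics** — mutant frequencies, fold changes, and exact
  (full-enumeration, midrank) Mann–Whitney U tests, which reproduce the
  exact small-sample values p = 0.0079 (complete separation, 5 vs 5) and
  p = 0.0159 (one crossing);
* **synthetic generator** — seeded duplex libraries from any reference
  FASTA: 300–350 bp fragments, 12-nt tag pairs with the αβ/βα duplex
  convention, Poisson strand families, true mutations injected per a
  96-channel spectrum, independent per-strand artifacts, plus simulated
  reporter-assay colony counts; every run writes a truth table for
  validation.

Two synthetic signature fixtures ship with the package
(`inst/extdata/sbs11_like_synthetic.tsv`, an alkylation-like 5'-Pu-G
enriched GC→AT spectrum, and `cpg_control_synthetic.tsv`, a
CpG-deamination-like control). They are constructed look-alikes for
testing; real signature vectors are user-supplied 96-row TSVs.

## Worked example

A complete synthetic run — simulate a 400-molecule duplex library from a
6.4 kb random target with an SBS11-like mutation spectrum, build consensus,
call mutations, and compare the recovered spectrum to the generator:

```r
library(duplexspectra)

reg <- random_region(6382, seed = 101)
sig <- system.file("extdata", "sbs11_like_synthetic.tsv",
                   package = "duplexspectra")
sim <- simulation_config(read_signature(sig), n_molecules = 400,
                         mutation_rate = 5e-3, per_base_error_rate = 1e-3,
                         seed = 7)
cfg <- pipeline_config(list(reg), "demo_out", sim = sim,
                       signatures = c(sbs11_like = sig), seed = 7)
res <- run_pipeline(cfg)
res$consensus
#> <duplex_consensus>
#>   reads_in                     7874
#>   malformed                    36
#>   ...
#>   strand_families              1762
#>   sscs_built                   1344
#>   sscs_rejected_size           418
#>   sscs_unpaired                208
#>   dcs_built                    568
#>   masked_base_fraction         0.190899
res$spectrum
#> <spectrum96> demo: 307 mutations; top channels T[C>T]C=0.098 A[C>T]C=0.093 G[C>T]C=0.087
res$similarity
#> <cosine_matrix>
#>            sample sbs11_like
#> sample      1.000      0.983
#> sbs11_like  0.983      1.000
res$plogo
#> <plogo> center G, n(fg) = 242, n(bg) = 3180, threshold +/- 3.05
#> significant cells:
#>   G at -1: 45.0%, height 11.08
#>   T at -1: 8.3%, height -10.44
#>   C at -1: 12.4%, height -6.22
```

Reading the output: of 7,874 tagged reads, 1,762 strand families formed;
families under 3 reads were rejected, unpaired SSCS flagged and ignored,
and 568 DCS reads survived (the 0.19 masked fraction is dominated by the
end trimming). The 307 unique mutations reproduce the generator's spectrum
with cosine similarity 0.983, and the probability logo flags guanine
overrepresentation 5' of the mutated G (height 11.08, far beyond the
±3.05 bar) with corresponding pyrimidine depletion — the 5'-Pu-G context
preference the generator injected.

The output directory contains every stage artifact: tagged FASTQ, truth
TSV, DCS FASTQ, consensus report, unique-mutation TSV/VCF, composition and
spectrum TSVs, cosine matrix, logo table, and a manifest of filtering
counts.

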