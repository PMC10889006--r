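---
title: "Detecting spinal muscular atrophy from c.840 read counts: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spinal muscular atrophy from c.840 read counts: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smacaller)
```

## The problem

Spinal muscular atrophy (SMA) is a recessive neuromuscular disease caused by
the absence of functional SMN protein. Its most common molecular cause is the
loss of every functional copy of *SMN1*, usually through deletion or gene
conversion. *SMN1* has a ~99.9%-identical paralog, *SMN2*, that differs at the
c.840 coding position: *SMN1* carries a 'C' there (normal exon 7 splicing),
*SMN2* a 'T' (exon 7 skipped in most transcripts). Because the paralogs are
nearly identical, short-read aligners place reads at this locus ambiguously —
typically with mapping quality 0 — and standard variant callers cannot
genotype it.

The insight this package implements is that diagnosis does not require
resolving the alignment ambiguity. Pool the reads over *both* paralog
positions and ask a single question: among all reads overlapping c.840, what
fraction carries the 'C'? A genome with at least one intact *SMN1* copy
contributes 'C' reads roughly in proportion to its *SMN1* dosage; a genome
with zero functional *SMN1* copies produces essentially none, apart from
sequencing error. The method therefore reduces the whole locus to two
numbers per sample:

- **N** — base observations overlapping the c.840 position of *SMN1* plus
  *SMN2*;
- **r** — the subset of those observations with base 'C'.

## The decision rule

With adequate coverage (`min_coverage`, default N ≥ 14, inclusive), the
caller compares two binomial hypotheses for r:

- **H0 (SMA):** zero functional *SMN1* copies; each observation is 'C' only
  through a base-calling error, with probability ε (`base_error_rate`,
  default 0.005);
- **H1 (not SMA):** at least one *SMN1* copy; the smallest plausible 'C'
  fraction is one *SMN1* copy among four total SMN copies, θ
  (`carrier_c_fraction`, default 0.25).

The statistic is the base-10 log-likelihood ratio

$$
\mathrm{llr}_{10}(r, N) \;=\; r \log_{10}\frac{\varepsilon}{\theta}
\;+\; (N - r) \log_{10}\frac{1-\varepsilon}{1-\theta},
$$

positive values favouring H0. The call is *positive* iff llr10 > 0; an exact
tie is called negative, on the principle that a positive SMA report must rest
on positive evidence. The reported confidence is the phred-scaled magnitude
`min(10·|llr10|, max_confidence)`; the cap (default 1000) is cosmetic and
keeps output finite at very high N.

Setting llr10 = 0 gives a boundary that is **linear** in (r, N):
r = cN with

$$
c = \frac{\log_{10}\frac{1-\varepsilon}{1-\theta}}
         {\log_{10}\frac{1-\varepsilon}{1-\theta} -
          \log_{10}\frac{\varepsilon}{\theta}}
\approx 0.0674
$$

at the defaults — a sample is positive when fewer than ~6.7% of its c.840
observations carry 'C'. `decision_boundary_slope()` exposes c, and the test
suite verifies the closed form against sign changes of `classify()` on an
exhaustive (r, N) grid.

Why θ = 0.25? It is deliberately the *least* favourable SMA-negative
configuration (one *SMN1* copy in a 4-copy genome). Any genome with more
*SMN1* dosage pushes r/N further from the boundary, so the test is
conservative exactly where a false positive would be most damaging. Why
ε = 0.005? It reflects the post-quality-filter substitution error of modern
Illumina-style data; the base-quality floor of 13 in the pileup bounds the
per-observation error near 5%, and the bulk of retained bases are far better.
The rule is insensitive to moderate misspecification of either constant: both
enter only through logs, and the boundary slope moves slowly in them.

## Counting rules (the pileup contract)

Published descriptions of this family of methods rarely pin down the pileup
filters, so this package fixes them explicitly as its contract:

- exclude duplicate, secondary, supplementary, unmapped, and QC-fail records;
- **no mapping-quality filter** — MAPQ 0 is the norm at this locus, and any
  MAPQ cutoff would discard the data the method depends on;
- require base quality ≥ 13 at the pileup position (configurable);
- count one observation per *fragment* per position: when mates overlap the
  site, take the base from the mate with the higher base quality (ties:
  first encountered). Overlapping mates re-read the same molecule, so
  double-counting them would inflate N and bias both likelihoods;
- a deletion or reference skip spanning the position contributes nothing —
  there is no base observation;
- 'N' and other non-C/T calls count toward `n_other`, hence toward N but
  never toward r. Keeping them in N is conservative for the coverage gate
  and treats both hypotheses symmetrically.

On GRCh38, ALT contigs carry extra SMN copies. Only primary-assembly
positions are counted; if the alignment header contains chromosome 5 ALT
contigs, a warning notes that a non-ALT-aware aligner could divert reads
away from the counted positions.

## Coordinates and reference validation

Coordinates are stored 1-based (VCF/HGVS convention) and chromosome names
dialect-free; `"5"` and `"chr5"` resolve interchangeably against any header
or FASTA, in either direction. Built-in configurations cover GRCh37
(5:70247773 / 5:69372353) and GRCh38 (5:70951946 / 5:70076526).
`validate_reference_bases()` is the source of truth for any coordinate set:
it reads the single base at each position and demands 'C' at the *SMN1*
coordinate and 'T' at the *SMN2* coordinate.

T2T-CHM13 is supported through `derive_locus_config()`: a 61 bp window
centred on each known-build position is located as a unique exact match in
the target FASTA, and the derived pair must pass the base validation. Flank
matching is reference-version-proof, and the C/T check catches off-by-one
errors; we chose to ship the derivation rather than a coordinate pair that
the package could not itself verify. The derivation is exercised in the test
suite against an offset copy of the simulator's reference.

## What the simulator emulates — and what it does not

`build_mini_reference()` writes two 2 kb contigs that are identical except at
one aligned key site ('C' in paralog1, 'T' in paralog2) plus at most three
scattered distinguishing bases placed more than a read length away from the
key site. `simulate_sample()` then draws paired 150 bp fragments whose
paralog of origin is categorical in the copy numbers, injects independent
per-base miscalls (default 0.005, each error uniform over the three other
bases), and assigns each read to the contig best matching its post-error
sequence — with MAPQ 0 whenever the read window contains no distinguishing
base beyond the key site, which is every key-covering read. The number of
fragments covering the key site is Poisson(`mean_depth_per_copy` × total
copies), the simplest model in which coverage tracks total SMN copy number.
By default at most one mate covers the key site; `force_mate_overlap = TRUE`
makes both mates cover it, to exercise the pileup's deduplication path.
Identical specs (including seed) reproduce identical reads, and the
generator restores the caller's RNG state.

This emulates the features the method actually depends on: paralog ambiguity
at the key site, copy-number-proportional mixing of 'C' and 'T' reads,
base-calling error, and MAPQ 0. It does **not** model capture bias between
exome kits, indels, gene-conversion breakpoints, position-dependent error
profiles, GC effects, or real BWA behaviour over the full 28 kb gene. A pass
on simulated cohorts therefore demonstrates the correctness of the counting
and decision machinery under the stated sampling model — not the assay-level
accuracy on real sequencing data, which the original large-cohort validations
address.

Default simulator settings mirror the sequencing regime the method targets:
150 bp paired-end reads, ~15 key-site observations per gene copy (so a
normal 4-copy genome yields N ≈ 60, matching the 57–111 average reported
across real exome and genome cohorts), and copy numbers 0–5 per paralog, the
range observed in human genomes.

## Validation arithmetic

The evaluation module reproduces the bookkeeping used to assess callers of
this kind: `compute_ppv()` (TP/(TP+FP)); `nocall_rate()` with report-style
rendering (rates ≥ 0.1% round at one decimal; smaller rates keep three
decimals, truncated rather than rounded so a vanishing rate is never
inflated — the convention that reproduces all four published renderings);
`fisher_exact_two_sided()` for no-call-rate contrasts; and
`compare_call_sets()`, whose concordance denominator includes only samples
with a definite call in both sets — a coverage failure is tracked separately,
not counted as disagreement.

The Fisher test uses the point-probability two-sided definition: the sum over
the hypergeometric support of all table probabilities not exceeding the
observed one. Probabilities come from `dhyper(log = TRUE)` and are summed
with a relative tolerance of 1e-7 to keep ties stable; margins of hundreds of
thousands pose no numerical difficulty because the support itself stays
small. The test suite checks the implementation exhaustively against plain
`choose()` enumeration for every 2×2 table with total ≤ 20, and against
`stats::fisher.test` on random tables.

## Numerical and degenerate-input choices

- Coverage gate inclusive: N = 14 is callable, N = 13 is not; no-calls carry
  confidence 0.
- llr10 ties are negative calls (see above).
- Violated pileup-count invariants (e.g. r > N) are a contract error, never
  silently clamped.
- An alignment file with zero reads at both positions is a valid no-call
  (N = 0), and a simulated genome with zero total SMN copies yields a valid
  empty BAM — whole-locus deletion is data, not an error.
- Per-sample failures in a batch produce an `"error"` row and never abort
  the cohort; the run's exit status reflects whether any sample errored.
- The r-versus-N diagnostic plot uses a symmetric log scale, linear up to
  the coverage gate and logarithmic beyond (continuous, with matched slope
  at the joint), so the no-call box, the boundary, and deep-coverage
  negatives share one readable panel; the Cartesian-linear boundary
  appears curved there by construction.

## Problem sizes used in the automated validation

The test suite recovers simulated truth end to end on 1,000 samples per
copy-number configuration (depth 15 per copy, error 0.005), requiring ≥ 99%
positive calls when *SMN1* = 0 and ≥ 99.9% negative calls at the worst-case
1-of-4 configuration, excluding no-calls. The acceptance script re-runs the
pipeline on 500 samples per configuration plus a 100-individual paired
two-depth comparison, and recomputes the published-table arithmetic from
scratch. These sizes were chosen to give the binomial pass criteria
comfortable resolution while keeping a full run in minutes on one CPU.

## Known limitations

- Only the c.840 position is tested: variants elsewhere in *SMN1* (6–49% of
  SMA cases depending on ancestry) are invisible and yield false negatives.
- No carrier calling and no integer *SMN1*/*SMN2* copy-number estimation;
  the call is strictly zero-versus-nonzero functional *SMN1*.
- Accuracy claims transfer to Illumina-style, BWA-like-aligned data;
  other technologies or non-ALT-aware GRCh38 alignments may violate the
  counting assumptions.
- The simulator's scope is the decision machinery, not assay realism (see
  above).
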