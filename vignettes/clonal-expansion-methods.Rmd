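---
title: "Quantifying clonal expansion in CD4+ TCR-beta repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying clonal expansion in CD4+ TCR-beta repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrackr)
```

# The analysis in one paragraph

`clonetrackr` analyses T-cell receptor beta-chain (TCRβ) repertoires of
CD4+ T cells from two kinds of measurement: bulk 5′-RACE amplicon
sequencing (reads per clonotype, with PCR bias and sequencing error) and
single-cell sequencing of at most ~102 sorted cells per sample (cell
counts, treated as an error-free gold standard). The CDR3 nucleotide
sequence together with the V gene serves as a clone barcode. On top of
that identity the package computes the statistics of chronic clonal
expansion in rheumatoid-arthritis-style study designs: expanded-clone (EC)
rates at frequency thresholds, clone sharing between compartments,
FACS-size-corrected localisation of clones across CD4+ subsets,
longitudinal tracking of persistent clones across timepoints and tissues,
and single-cell mEC/EC/NEC classification. A synthetic repertoire
generator with known ground truth makes every stage testable end to end.

# Clone identity

A clone key is the pair (V gene with the allele suffix stripped, CDR3
nucleotide sequence): `TRBV12-3*01` and `TRBV12-3*02` with the same
junction are one clone, while junctions one nucleotide apart are different
clones. Nucleotide-level (not amino-acid) identity is used because
cross-platform and cross-tissue matching of individual clones requires the
stronger barcode; an amino-acid key would merge convergent rearrangements.
Matching on the allele-stripped V call tolerates allele-level differences
in how the two platforms annotate the same rearrangement.

# Functional reads and every denominator

All frequencies are computed over *functional* reads: junctions that are
in frame (length divisible by 3), whose translation contains no stop
codon, and that carry the conventional anchors — cysteine first, F or W
last. Nonproductive reads never enter any denominator. `filter_functional()`
applies the rule and is idempotent; `total_functional()` is the
denominator used everywhere.

# Expansion statistics

* **Clone frequency** — reads (or cells) of the clone divided by total
  functional reads of the sample.
* **EC call (bulk)** — a clone whose frequency *strictly exceeds* a
  threshold; 0.2% and 0.1% are the two conventional choices. "More than"
  is read as a strict inequality, so a clone sitting exactly on the
  threshold is not an EC. The **EC rate** is the cumulative read count of
  ECs over total functional reads.
* **Shared-clone rate** — for two samples of one subject, the shared set
  is the intersection of clone keys; each sample reports the cumulative
  count of shared clones over *its own* functional total. The denominator
  is per compartment, so the two rates differ in general.
* **Cohort comparison** — `compare_groups()` is the classical
  equal-variance two-sample t-test (two-sided, α = 0.05), with Welch's
  form behind a flag. When both groups are constant the t statistic
  degenerates; the limits (0 with p = 1 for equal means, ±∞ with p = 0
  otherwise) are reported explicitly rather than erroring.

# FACS-size-corrected subset distribution

In-subset frequencies are not comparable across subsets of very different
sizes, so the corrected contribution of a clone (or clone set) to subset
*s* is

    contribution(s) = in-subset frequency(s) × fraction_of_cd4(s)

where `fraction_of_cd4` is the FACS-measured share of the subset within
all CD4+ T cells. Contributions are therefore on the scale "fraction of
all CD4+ T cells". Because sequencing dropout means the contributions sum
to nothing fixed, normalised shares (contributions over their sum) are
reported alongside and used as the default plot. The four memory helper
subsets (Th1, Th17, Tfh, non-Th1/Th17/Tfh) are not forced to partition
the memory gate — the gating scheme leaves a CXCR3+CCR6+ corner
uncovered — so no renormalisation to a partition is ever applied; the
validator only warns when helper fractions exceed the memory fraction. A
clone set undetected in every subset yields an all-zero distribution with
a warning rather than an error, since dropout at realistic depths is
expected.

# Single-cell classification and clone tracking

In a single-cell sample of n ≤ ~102 cells, a clone observed **more than
once** is an EC; a clone observed exactly once is an NEC; the EC with the
highest cell count is the mEC. A tie for the maximum leaves the mEC
undesignated (the tie is reported) because the "most expanded clone" is
singular by definition and an arbitrary tie-break would silently change
downstream pooling.

`track_clones()` builds the clone × sample frequency matrix over all
samples of a subject, with explicit zeros for absences. A clone is
**persistent** when it meets the platform-appropriate EC criterion
(single-cell: ≥ 2 cells; bulk: frequency above the threshold) in at least
two timepoints of the same compartment (tissue × subset) — persistence
requires repeated *expansion*, not mere repeated detection. Persistent
clones get stable IDs `Ci.j`: *i* is the subject index (trailing digits
of the subject label), *j* ranks persistent clones by mean frequency
across all samples, descending, with lexicographic clone-key tie-breaks;
the ordering statistic is a package choice. Cross-tissue intersection
(`intersect_tissues()`) uses the most permissive presence rule — at least
one functional read in the synovium sample and in at least one PB
sample — because "detected" carries no threshold; the rule is
deliberately separate from the EC criterion.

# Platform concordance

`concordance()` pairs each clone of the single-cell gold sample with its
bulk frequency (0 when absent) and reports Spearman's rho with
average-rank tie handling, its p value, and detection sensitivity (the
fraction of gold clones with at least one bulk read). Rho is undefined
(NA) below two pairs or when either side is constant.

# Error correction and its evaluation

Bulk reads carry substitution errors that found spurious low-count
clonotypes one mismatch away from real clones. The correction stage is a
deliberately minimal, fully specified absorber: for every pair with the
same stripped V call and equal-length CDR3s at Hamming distance 1 where
the child count is at most `ratio_threshold` (default 0.01) times the
parent count, the child's reads move to the parent. Parents are taken in
descending count order; each child is absorbed once, by its largest
eligible parent, ties broken by lexicographic CDR3; chains resolve to the
ultimate parent (counts increase strictly along a chain, so there are no
cycles). Total reads are conserved and no new keys appear. Distance-1
candidates are found with a masked-position signature index rather than
all-pairs comparison, so correction is near-linear in table size.
Correction runs *before* functional filtering because an error can toggle
productivity in either direction. The algorithm is intentionally simple:
no quality scores, no indels — it exists to be evaluable, not to compete
with production correctors.

Evaluation against simulator ground truth reports spurious-clonotype
counts before/after, true-clone recall, the rate of reads assigned to the
*wrong true clone*, and Spearman's rho between observed and true clone
frequencies. Rho is computed over the **union** of observed and true
clonotypes (a spurious clonotype has true frequency 0; an undetected true
clone has observed frequency 0). Restricted to true clones only, the
correction is nearly rank-neutral — error reads leave each clone roughly
proportionally — and rho barely moves; over the union, rho directly
reflects the removal of spurious mass, which is what the correction is
for.

Two structural limits of the absorber are worth knowing. A singleton
child can only be absorbed by a parent with at least `1/ratio_threshold`
(by default 100) reads, so errors spawned by clones below that count
survive correction; and reads carrying two or more substitutions (~2% of
error reads at rate 0.001 over ~45 nt) are beyond Hamming distance 1.
Under heavy-tailed clone sizes these two classes bound the achievable
spurious-clonotype reduction at roughly 85–90% at depth 1e5.

# The synthetic repertoire generator

`build_ground_truth()` creates a latent clone population for a set of
compartments (tissue × subset × timepoint):

* **Clone sizes** follow a discrete power law (Zipf) with configurable
  exponent, default 1.5 — the standard stylisation of heavy-tailed
  repertoire structure. `n_dominant` designated persistent clones sit at
  the top of every memory-phenotype (non-naive) compartment at every
  timepoint; `dominant_freq` can pin their true frequencies exactly (for
  example 0.10/0.05/0.02), in which case the remaining clones are capped
  just below the smallest pinned frequency by water-filling so the
  designated clones genuinely are the compartment's top clones.
* **Subset structure**: each non-dominant clone has one "home" subset
  where it is always present, and appears in any other compartment with
  probability `share_prob` (default 0.10). This produces the observed
  pattern of mostly-unique subset repertoires with partial sharing.
  Presence is decided once per (tissue, subset) and held across
  timepoints; per-compartment frequencies get a log-normal jitter
  (`tail_jitter_sd`, default 0.3) so timepoints differ realistically.
* **CDR3s** are random in-frame 30–60 nt sequences built from non-stop
  codons, starting with TGT (Cys) and ending with a Phe codon, so
  simulator clonotypes are functional by construction.

`sample_bulk()` draws reads in three stages: a log-normal per-clone
amplification factor (sd `pcr_bias_sd`, applied once, then renormalised)
models PCR bias; a multinomial draw of `depth` reads models sampling; and
i.i.d. per-base substitution at `substitution_rate` (no indels) mutates
individual reads, which then found or join clonotypes carrying the
parent's V call — errors are confined to the CDR3 by design, so the
observed/true clonotype mapping stays well defined. With both noise
parameters at zero the sampler is exactly multinomial. `sample_cells()`
is a plain multinomial draw of cells with no error, matching the
gold-standard role of single-cell sequencing. Every sampled read's true
clone is retained in a hidden provenance attribute used only by the
truth-based evaluators, and every operation takes one explicit integer
seed with no global RNG state.

What the generator does **not** emulate: V(D)J recombination biology
(junctions are random strings, not IMGT-derived), indels and chimeric
reads, UMI structure, alpha chains, cell-sorting impurities, and any
transcriptional phenotype. Consequently, passing tests demonstrate that
the statistics are computed correctly and behave as designed under
realistic sampling noise — not that the biological conclusions of any
particular study would replicate on real data.

# Numerical and design choices

* Strict `>` at EC thresholds; boundary clones excluded.
* mEC ties are refused, not broken.
* Absorption tie-breaks: largest parent, then lexicographic CDR3 —
  deterministic output for identical input.
* Water-filling cap for pinned dominants at 0.9 × min(dominant
  frequency); if the tail is too small to absorb its mass under the cap,
  the tail is made uniform and a warning is raised.
* Normalised shares are reported to 1 within 1e-12; distribution
  additivity is exact on rational inputs up to double rounding.
* Degenerate inputs (empty samples, zero functional reads, unknown
  compartments, platform mismatches, subject mismatches) raise classed
  conditions (`clonetrackr_error_*`) so callers can handle them
  programmatically.

# Problem sizes used by the test suite and acceptance script

The package's own validation uses deliberately desk-scale instances:
toy tables of 2–40 clones for oracle equivalence (200 tables), truths of
100–2000 clones, bulk depths of 1e4–1e5 reads, single-cell samples of
20–102 cells, and seed batteries of 20–100 replicates. These sizes make
every property measurable in seconds while keeping the binomial/multinomial
noise regimes honest; richness is otherwise arbitrary, since no
clone-richness figures exist to calibrate against. In the cohort-comparison
demonstration, oligoclonal subjects are modelled as pinned dominants
(0.10/0.05/0.02) over a Zipf-1.5 background of 1000 clones, and polyclonal
controls as a flat heavy tail (exponent 0.5) over 20000 clones.

# Known limitations

* Statistical power to flag a clone persistent from 102-cell samples
  drops quickly with true frequency: a clone at 2% is seen ≥ 2 times in a
  102-cell draw with probability ≈ 0.61, so it satisfies the persistence
  rule in ≥ 2 of 3 timepoints only ≈ 66% of the time. Persistence calls
  on single-cell data are reliable for clones at roughly 5% and above.
* The error corrector's reduction of spurious clonotypes is bounded by
  the singleton/low-count-parent and multi-error classes described above.
* Counts are raw duplicates; there is no UMI support.
* No diversity indices; the package computes expansion statistics only.
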