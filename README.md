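# clonetrackr

Clonal-expansion analysis for T-cell receptor beta (TCRβ) repertoires of
CD4+ T cells. The package is aimed at immunologists studying chronic
antigen-driven expansion — for example persistent clones in rheumatoid
arthritis — from two complementary measurements: bulk 5′-RACE TCRβ
sequencing (reads per clonotype, subject to PCR bias and sequencing
error) and single-cell sequencing of up to ~102 sorted cells per sample
(cell counts, treated as the error-free gold standard).

A clone is identified by its allele-stripped V gene plus CDR3 nucleotide
sequence. With *f(c)* the frequency of clone *c* among reads with
functional CDR3s (in frame, no stop codon, C…F/W anchors), the package
computes:

* **EC rate** (bulk): clones with *f(c) > t* (strictly; *t* = 0.2% or
  0.1%) are expanded clones; the EC rate is Σ reads of ECs / total
  functional reads.
* **Shared-clone rate**: for samples A, B of one subject, the shared set
  is the clone-key intersection; each sample reports shared reads over
  its own functional total.
* **FACS-size-corrected subset distribution**: contribution of a clone
  set to subset *s* = in-subset frequency × FACS fraction of *s* among
  all CD4+ T cells, reported raw and as normalised shares.
* **Single-cell classification**: a clone seen in > 1 cell is an EC, in
  exactly 1 cell an NEC, and the highest-count EC is the mEC (ties are
  refused, not broken).
* **Clone tracking**: a clone × sample frequency matrix across
  timepoints, tissues, subsets and platforms; clones satisfying the EC
  criterion in ≥ 2 timepoints of one compartment are *persistent* and get
  stable IDs `Ci.j` ranked by mean frequency.
* **Platform concordance and error correction**: Spearman agreement of
  single-cell vs bulk frequencies, plus a Hamming-distance-1,
  ratio-thresholded absorber of spurious error clonotypes with
  truth-based evaluation on simulated data.

A synthetic repertoire generator (Zipf clone sizes, designated dominant
clones, subset-restricted placement, log-normal PCR bias, per-base
substitution error, hidden read provenance) makes every stage testable
without external data. See `vignettes/clonal-expansion-methods.Rmd` for
the full model description and design choices.

## Worked example

```r
library(clonetrackr)

# a ground-truth memory compartment with three designated persistent
# clones at 10%, 5% and 2%, observed at three timepoints
compartments <- data.frame(tissue = "PB", subset = "memory",
                           timepoint = c("T1", "T2", "T3"))
truth <- build_ground_truth(n_clones = 1000, n_dominant = 3,
                            tail_exponent = 1.5, compartments = compartments,
                            seed = 42, dominant_freq = c(0.10, 0.05, 0.02))

# three single-cell samples of 102 cells, then mEC/EC/NEC calls
cells <- lapply(1:3, function(i)
  sample_cells(truth, "PB", "memory", paste0("T", i), n_cells = 102,
               seed = 100 + i))
head(tidy(classify_single_cell(cells[[1]]))[, c("clone_key", "cells", "label")], 4)
#>   clone_key                                                 cells label
#> 1 TRBV5-2|TGTTCGCTGATCATCTATGACGACCGTTTC                        9 mEC
#> 2 TRBV12-1|TGTGGAGGTCTCACGTCCATTCCACGCCTAAACTGCAGGTTT           4 EC
#> 3 TRBV21-1|TGTATAAATGATTCGAGAAGGGCCACACCACGCATTTTC              4 EC
#> 4 TRBV21-1|TGTGGAACGATATCTATGGATCCCCAAAAGGGCGGAAGTAATCCTTTC     4 EC
```

The mEC here is a designated dominant clone: 9 of 102 cells ≈ 8.8%
against a true frequency of 10%. Tracking the three timepoints:

```r
trk <- track_clones(cells)
glance(trk)
#>   subject_id n_clones n_samples n_persistent ec_threshold
#> 1 RA1             122         3           18        0.002
head(trk$clones[trk$clones$persistent, c("clone_id", "mean_frequency")], 3)
#>   clone_id mean_frequency
#> 1 C1.1             0.0915
#> 2 C1.2             0.0294
#> 3 C1.3             0.0294
autoplot(trk)   # timepoint-vs-frequency line plot, one line per persistent clone
```

122 distinct clones were seen across the three draws; 18 met the EC
criterion (≥ 2 cells) at ≥ 2 timepoints and received `C1.j` IDs in
mean-frequency order. On the bulk side, with realistic noise:

```r
bulk <- sample_bulk(truth, "PB", "memory", "T1", depth = 1e5,
                    noise = noise_model(substitution_rate = 0.001,
                                        pcr_bias_sd = 0.5, seed = 7))
corrected <- correct_errors(bulk, ratio_threshold = 0.01)
c(before = nrow(bulk), after = nrow(corrected))
#> before  after
#>   3876   1676
glance(call_ecs(filter_functional(corrected), threshold = 0.002))
#>   sample_id             threshold n_ec ec_rate total_functional
#> 1 RA1_PB_memory_T1_bulk     0.002   67   0.810            99867
glance(concordance(cells[[1]], bulk))
#>   n_gold n_matched sensitivity   rho  p_value
#> 1     63        63           1 0.658 4.67e-9
```

Error correction collapsed 2200 spurious one-mismatch clonotypes into
their parents; 67 clones exceed 0.2% of functional reads and together
carry 81% of them; every clone seen in the 102-cell gold sample was
recovered by bulk sequencing, with rank agreement ρ = 0.66 at 102 cells
of resolution.

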