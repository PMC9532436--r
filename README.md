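# gdtcr — paired single-cell γδ TCR repertoire analysis

`gdtcr` is an R package for analysing paired single-cell (and bulk) γδ
T-cell receptor repertoires of the developing human thymus. It is aimed at
immunologists who have per-cell CDR3 tables (AIRR Rearrangement TSV or 10x
`filtered_contig_annotations.csv`) plus cell-level labels (subject, age,
cluster, maturation group, effector type) and want the repertoire statistics
this field reports, with the transcriptomic side (clustering, trajectories)
deliberately out of scope.

## What it computes

For each rearranged chain, the junction nucleotide sequence (IMGT
convention: conserved Cys codon through conserved Phe/Trp codon) is
decomposed into germline-templated V/D/J parts, palindromic (P) nucleotides
at untrimmed germline ends, and non-templated (N) additions inserted by TdT:

```
junction = V-prefix | P | N1 | D | N2 | P | J-suffix,
v + j + Σd + ΣP + N = junction length
```

The decomposition minimises N (maximising templated+P coverage, exact
matching only) with deterministic tie-breaks, so inferred N is a
conservative estimate of TdT activity. On top of this the package computes:

* **Publicity** of a CDR3 amino-acid sequence: the number of single-cell +
  bulk datasets containing it (0 = private to one dataset; with the standard
  design of 9 single-cell + 10 bulk repertoires the maximum is 19).
* **Vγ9Vδ2 classification** (paired TRGV9/TRDV2 TCR) per cell.
* **V-gene usage**, **chain detection** and **double-δ** rates, CDR3 length
  summaries and the 0.2/0.8 quantile display clamps.
* **Public CDR3 tagging** (the canonical fetal public δ and γ sequences) and
  **position-5 hydrophobicity** of TRDV2 junctions.
* **γ/δ pairing preferences** of public sequences, with paired t-tests.
* **Group contrasts** on subject-level means: paired exact Wilcoxon
  (immature/maturing vs effector), one-way ANOVA with Tukey or Holm–Šidák
  post hoc (effector types, lineages, with a Friedman/Dunn alternative),
  and Spearman correlations with gestational age.

A first-class simulator (`simulate_repertoire()`) generates the whole study
design — 6 fetal subjects (14–22.9 wk), 3 pediatric subjects, 10 bulk
repertoires, 68%/52% chain detection, 2.3% double-δ cells, age-dependent
Poisson N additions, germline-convergent public clonotypes with effector
bias and 0.8/0.2 γ-pairing weights — together with a complete ground-truth
ledger, so the entire pipeline is testable offline.

## Worked example

```r
library(gdtcr)

cfg   <- simulation_config(seed = 42, cells_per_subject = 600L,
                           bulk_clones_per_subject = 200L)
sim   <- simulate_repertoire(cfg)
cells <- tag_public_sequences(assemble_cells(do.call(rbind, sim$sc),
                                             sim$metadata))
cells
#> gdtcr cell set: 5400 cells, 6506 productive chains (3741 TRD / 2765 TRG)
#>   datasets: FT1, FT2, FT3, FT4, FT5, FT6, PNT1, PNT2, PNT3

r <- chain_detection_rates(cells)
# delta detection 66.9%, gamma 51.2%, double-delta 2.4%

feats <- junction_features(cells$chains, synthetic_germline())
trdv2 <- subset(feats, locus == "TRD" & sub("\\*.*", "", v_call) == "TRDV2" &
                  !no_germline & compartment == "fetal")

maturation_contrast(trdv2, "n_additions_total")
# mean N additions (TRDV2): I-M 1.19 vs EFF 0.84, exact signed-rank p = 0.0312

mn <- aggregate(n_additions_total ~ subject_id + age_value, trdv2, mean)
age_trend(mn, "n_additions_total")
# Spearman rho(mean N, gestational age) = 1.00, p = 0.0028

pub <- compute_publicity(repertoire_collection(sc = sim$sc, bulk = sim$bulk))
publicity_lookup(pub, "TRD", "CACDTGGYWDTRQMFF")
#> [1] 19

pairing_test(pairing_fractions(cells))
#>     delta_tag n_subjects  mean_diff     t      p_value computable
#> 1  lgdt_delta          9     -16.20 -3.67      0.00629       TRUE
#> 2 type1_delta          9      41.47  6.34      0.00022       TRUE
#> 3 type2_delta          9       2.56  0.53      0.60945       TRUE
```

Reading: effector cells carry fewer N additions than immature/maturing cells
(paired exact Wilcoxon across the 6 fetal subjects), subject mean N rises
monotonically with gestational age (the TdT trend), the canonical public δ
sequence is found in all 19 datasets, and the type-1-associated public δ
group pairs preferentially with the TRGV8 public γ while the
hydrophobic-position-5 group prefers the TRGV9 one — each recovered from the
simulator's configured generative structure.

Real data enter through `read_airr()` / `read_tenx_contigs()` +
`read_cell_metadata()` + `read_germline_fasta()` in place of the simulator;
a thin command-line dispatcher over the same functions ships in
`inst/scripts/gdtcr.R`. Note that the bundled germline FASTA is a synthetic
fixture (see the methods vignette); supply an IMGT-derived reference for
real analyses.

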