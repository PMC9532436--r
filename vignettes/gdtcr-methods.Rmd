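---
title: "Methods: paired gamma-delta TCR repertoire analysis with gdtcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired gamma-delta TCR repertoire analysis with gdtcr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdtcr)
```

## Scope and rationale

`gdtcr` analyses paired single-cell gamma-delta T-cell receptor (TCR)
repertoires of the developing human thymus, together with bulk repertoire
tables used to strengthen clonotype-sharing statistics. The package covers
the repertoire side of such studies only: chains are read from AIRR
Rearrangement TSV or 10x contig-annotation CSV files, matched to cells by
barcode, and analysed against cell-level labels (cluster, maturation group,
effector type, lineage) that are *consumed as input*. Transcriptome
processing — mapping, integration, clustering, trajectory inference — is out
of scope; the simulator emits labels directly so that every stage of the
pipeline can be exercised and validated without any external download.

The quantities the package computes per chain and per cell are the ones this
field reports:

* **N additions** — non-templated nucleotides inserted by TdT at the V-D,
  D-J or V-J joints. Low N counts are the hallmark of fetal, germline-
  convergent rearrangements, because TdT activity rises with gestational age.
* **CDR3 (junction) length** in nucleotides, under the IMGT junction
  convention: the junction includes both the conserved cysteine codon and the
  conserved phenylalanine/tryptophan codon, so a printed 16-amino-acid
  junction such as `CACDTGGYWDTRQMFF` is 48 nt long.
* **Publicity** — the number of repertoire datasets in which an identical
  junction amino-acid sequence occurs.
* **Vg9Vd2 status** — whether a cell pairs a TRGV9 gamma chain with a TRDV2
  delta chain, the defining TCR of the major innate-like human subset.
* **Public-tag membership and gamma/delta pairing preferences** of the
  canonical fetal public CDR3 sequences.

## Junction decomposition

`decompose()` partitions a junction nucleotide sequence into:

* a **V contribution**: an exact prefix of the V segment's junction template
  (the suffix of the V gene from the conserved Cys codon) matched as a prefix
  of the junction;
* a **J contribution**: an exact suffix of the J template (the prefix of the
  J gene through the conserved Phe/Trp codon) matched as a suffix;
* up to `max_d` (default 2, for tandem-D rearrangements) interior **D
  matches**, exact substring matches of at least `min_d_match` (default 3)
  nucleotides — matching is always exact because somatic hypermutation is
  absent in TCRs;
* **P nucleotides**: palindromic extensions, read as the reverse complement
  of the adjacent germline end, recognised only when that end is untrimmed
  and up to `max_p` (default 3) nucleotides;
* **N additions**: every remaining nucleotide.

The components always satisfy `v + j + sum(d) + sum(P) + N = length`.

### Objective and tie-breaks

The decomposition minimises the N count — equivalently, it maximises
templated-plus-P coverage — and breaks ties by preferring more templated
nucleotides, then a longer V match, then a longer J match, then the leftmost
and longest D matches, which makes the output deterministic. Two numerical
choices deserve explanation:

* **P is maximised, not minimised.** Given equal templated coverage, the
  engine assigns as many P nucleotides as the palindrome rule allows. The
  alternative (prefer fewer P) systematically inflates N: a chain whose true
  rearrangement used a palindromic extension would be scored as having
  non-templated insertions it never had. Keeping N conservative is what makes
  the anti-inflation guarantee below possible.
* **P is recognised at the V 3' and J 5' ends only.** Claiming P at interior
  D-segment ends can *trade away* templated coverage (a D match shortened by
  one nucleotide may open a two-nucleotide palindrome), which breaks the
  guarantee that inferred templated coverage never falls below the truth.
  Interior palindromes therefore remain in the N count; this makes inferred N
  an upper bound, never an underestimate, of the decomposer's uncertainty.

With these rules, for every chain the simulator emits, inferred N additions
never exceed the generative (ledger) N, and inferred templated+P coverage
never falls below the ledger's — both are asserted over the full simulated
bundle in the test suite. A counterexample worth recording: ground truth
itself is occasionally not coverage-optimal, because germline D nucleotides
adjacent to an untrimmed J can coincidentally spell that J's palindromic
extension; in such chains the engine reports one fewer templated nucleotide
and one fewer N than the ledger, which is why the guarantee is stated on N
and on total coverage rather than on the raw templated count.

The implementation is a branch-and-bound search in C++ over V/J match
lengths and clipped maximal D match intervals. The test suite contains an
algorithmically independent pure-R oracle that enumerates every legal
partition; the two agree exactly (templated total and N count) on hundreds of
random recombination-style junctions up to 33 nt.

### Allele handling

Gene calls such as `TRDV2*01` are collapsed to the gene level before germline
lookup; the analysis never attempts allele-level genotyping.

## Publicity

`compute_publicity()` counts, for each (locus, junction amino-acid) key, the
number of datasets — single-cell and bulk pooled — containing it. The level
is that count when the sequence occurs in two or more datasets and 0 when it
is private to one dataset. This *self-inclusive* convention is the only one
consistent with both printed extremes of a 19-dataset design (a private
sequence scores 0; a sequence in all 9 single-cell plus 10 bulk repertoires
scores 19): counting only *other* datasets would cap the range at 18.
Publicity is keyed on the amino-acid sequence, V-gene-agnostic, because
sharing is defined on the CDR3 itself; bulk files belonging to one subject
(e.g. sorted Vg9Vd2 and non-Vg9Vd2 fractions) are merged into a single
dataset before counting, since publicity asks whether a *subject* carries
the sequence.

## Position-5 hydrophobicity

"Position 5" of a delta CDR3 is counted with the leading conserved cysteine
excluded — the sixth residue of the printed junction. This is the only
convention under which the canonical public sequences classify correctly:
glycine (neutral) at position 5 of `CACDTGGY(S)WDTRQMFF` and `CACDWGSS...`,
and valine/leucine/tryptophan (hydrophobic) at position 5 of the
`CACD(T)(V/I)LGDT...` and `CACDYWGSS...` families. The hydrophobic set
defaults to {V, L, I, M, F, W} and is configurable.

## Pairing analysis

`pairing_fractions()` quantifies how the public delta groups partition
between the two canonical public gamma chains (`CALWEVQELGKKIKVF` on
TRGV9-TRGJP and `CATWDTTGWFKIF` on TRGV8-TRGJP1). Percentages are
**gamma-anchored**: the denominator is the number of cells containing a
TRDV2 delta chain paired with the given public gamma chain, which is the
definition that matches how such panels are reported. Gamma-chain identity
requires the junction amino-acid sequence *and* the stated V and J genes.
Cells carrying both public gamma chains are counted in both denominators and
flagged (an exclusion switch is provided); a delta-anchored partner split is
also returned because it is the quantity a simulation-recovery check can
compare against configured pairing weights. `pairing_test()` runs the
two-tailed paired t-test across subjects between the V8- and V9-paired
percentages.

## Group contrasts

The subject is the experimental unit everywhere: chain- or cell-level values
are first averaged per subject and group, and tests run on subject-level
means, so duplicating all cells of a subject changes nothing (tested).

* Immature/maturing vs effector: Wilcoxon matched-pairs signed-rank test,
  with the exact sign-flip null distribution (convolution over midranks, so
  ties are handled exactly) for up to 25 subjects and the normal
  approximation beyond.
* Effector types: one-way ANOVA with Tukey HSD, in ordinary or matched
  (subject-blocked) mode; unbalanced subjects are excluded only in matched
  mode, and that behaviour is logged.
* Age trends: two-tailed Spearman rank correlation against gestational
  (weeks) or postnatal (years) age; at least 4 subjects are required and a
  constant metric yields an explicit not-computable sentinel rather than a
  number.
* Lineage tag abundance: per subject and lineage label (effector clusters
  excluded), the fraction of TRDV2 cells carrying a public tag, compared by
  matched one-way ANOVA with Holm-Sidak post hoc. Because small per-subject
  percentage panels often fail normality, a Shapiro-Wilk gate at alpha 0.05
  selects between that result and a Friedman test with Dunn post hoc — both
  are always reported, the gate only marks which one is selected.
* The 0.2/0.8 quantile rule used to clamp CDR3-length colour scales in
  figures is exposed as `cdr3_length_display_limits()`, computed on all
  pooled TRDV2 chains.

## The synthetic study

`simulate_repertoire()` generates the full study design as its defaults: 6
fetal subjects spanning 14-22.9 gestational weeks, 3 pediatric subjects (4,
4.5, 11 years), 2,000 cells per single-cell subject, and 10 bulk
repertoires (3 fetal, 7 pediatric). Per-cell structure:

* **Chain detection**: a cell has at least one delta chain with probability
  0.68 and a gamma chain with probability 0.52; 2.3% of all cells carry two
  productive delta chains (the two junctions are forced to differ). These are
  the detection rates the analysis is designed around.
* **De novo rearrangement**: V and J drawn from configured usage
  (fetal TRD usage is TRDV2-dominated at 0.74, with TRDV1/TRDV3 and an
  "Others" gene; postnatal usage shifts toward TRDV1), geometric trims
  (p = 0.45), and for TRD one D segment (two with probability 0.12); D
  remnants shorter than `min_d_match + 1` are dropped entirely so that the
  ledger's templated account stays within the decomposer's search space.
  P extensions occur with probability 0.25 at untrimmed V/J ends (1-2 nt).
  N additions are Poisson with mean `1 + 0.45 * (age_weeks - 14)` for fetal
  subjects and 8 for postnatal ones: a single-parameter stand-in for
  age-increasing TdT activity, adequate because only rank correlations with
  age are asserted downstream. Unproductive draws (frame, stop codons) are
  rejected and redrawn, mirroring productive-only retention.
* **Public clonotypes**: with probability 0.22 (fetal; 0.05 postnatal) a
  chain is drawn from the recipe table of canonical public sequences, each
  germline-convergent with at most one non-templated nucleotide. Public
  delta chains draw their gamma partner from the configured 0.8/0.2 pairing
  weights (the TGGY family prefers the TRGV8 public gamma, the
  hydrophobic-position-5 LGDT family and the YWGSS variant prefer the TRGV9
  one). Every public clonotype is additionally seeded into each bulk
  dataset, so public sequences are shared across repertoires by construction.
* **Labels**: the effector fraction falls linearly with gestational age
  (0.50 at 14 wk, slope -0.02/wk); among effector cells the type-3 share
  falls (0.60 at 14 wk, -0.04/wk), the type-1 share rises (0.15 at 14 wk,
  +0.04/wk) and type-2-like takes the remainder, reproducing the wave-like
  pattern the analysis is meant to detect. Public chains re-weight the label
  probabilities multiplicatively (type-1-associated sequences toward the
  type-1 cluster, and all publics away from the immature pool), which is a
  phenomenological knob, not a mechanism. Immature cells receive lineage
  labels L1-L3, with the type-1-associated tag biased 3x toward L1.

Everything emitted is covered by a ground-truth ledger (true segments,
trims, P and N counts, publicity and pairing recipes), which is what the
anti-inflation and parameter-recovery tests compare against.

**What the simulator does not emulate**: transcriptomes and genuine cluster
structure (labels are drawn, not inferred), clonal expansion within a
subject, allele-level variation, sequencing error, cross-subject age
confounders, and thymic selection. Passing tests therefore demonstrate that
the pipeline's statistics recover known generative structure of the right
kind and magnitude — not that any biological claim about real data is
reproduced.

### Germline fixture

The bundled germline set (`synthetic_germline()`, also shipped as
`inst/extdata/germline_synthetic.fasta`) is **synthetic**: segment names
follow TRD/TRG locus nomenclature, but the junction-proximal sequences were
designed so that the canonical public CDR3 amino-acid sequences recombine
from germline with at most one N nucleotide, and so that TRGJP is longer
than every other TRGJ segment (the property that lengthens TRGV9 junctions).
One liberty: the `...WDTTRQMFF`-ending public sequences are carried by a
fixture TRDJ2 segment, since no single J template can end in both
`WDTRQMFF` and `WDTTRQMFF`. Analyses that require real references should
supply an IMGT-derived FASTA in the documented header format.

## Problem sizes and determinism

The test suite and the acceptance script run the simulator at the scales the
checks need: the full 9-subject + 10-bulk bundle at 2,000 cells/subject for
the anti-inflation sweep (~30,000 chains), a 12-fetal-subject, 2,000
cells/subject study for parameter recovery, and reduced-depth bundles for
unit tests. All randomness flows from a single integer seed; re-running with
the same seed reproduces every output file byte-identically (hash-checked in
the tests).

## Known limitations

* Exact-match decomposition cannot see through sequencing errors; a single
  substitution inside a templated region inflates N. Error modelling is out
  of scope.
* Publicity treats datasets as exchangeable units; it does not model
  sampling depth, so a deep bulk repertoire and a shallow single-cell one
  count equally.
* The decomposer's N is a lower bound on the true insertion count in the
  rare chains where germline nucleotides coincidentally spell a palindromic
  extension (see above); this direction of error is deliberate.
* The double-delta convention (both chains contribute to per-chain
  statistics, flagged so a primary-chain mode can be selected downstream)
  follows the package's own choice; studies quantify double expressors but
  rarely state how they were pooled.
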