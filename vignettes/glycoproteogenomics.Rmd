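---
title: "Predicting splice-driven N-glycosite changes and integrating surface-proteome evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting splice-driven N-glycosite changes and integrating surface-proteome evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycosequon)
```

## The problem

N-linked glycosylation is templated at the sequence level: a glycan can be
attached to an asparagine only inside the sequon N-x-S/T, where x is any
residue except proline. Alternative splicing rewrites protein sequence, so
it can delete a sequon, move it to a new coordinate, or create one that the
canonical protein never had — with direct consequences for cell-surface
glycoproteins, whose detection by glycocapture proteomics depends on those
very sites. This package implements the computational side of that
analysis for sequence collections such as RNA-seq-predicted isoform
libraries from differentiating cardiomyocytes: sequon scanning, canonical
versus isoform comparison, surface-prediction filtering, motif enrichment
testing, and the integration of transcript and glycopeptide evidence.

## Sequon model

`find_sequons()` reports every tripeptide N-x-Z with x ∉ {P, X} and Z drawn
from the requested motif classes. Choices worth stating explicitly:

* **Only x ≠ P is enforced.** The consensus carries no constraint at the
  residue following the sequon, so a proline at +3 does not disqualify a
  site.
* **Unknown residues never assert a site.** An `X` at the x or third
  position disqualifies the window, because a sequon cannot be claimed
  from unknown sequence. An `X` elsewhere is irrelevant.
* **NxC and NxV are optional classes, off by default.** They exist so the
  canonical and non-canonical classes can be contrasted in enrichment
  analyses; on their own they are weak evidence of glycosylation, and the
  default scan is NxS/NxT only.
* **Coordinates are 1-based on the Asn** throughout all tables and files,
  matching conventional protein-site reporting ("N227").
* Overlapping sequons (as in `NNSS`) are each reported.

## Canonical–isoform comparison

The classification of a sequon as retained, shifted, lost or gained needs
a correspondence between canonical and isoform coordinates. Exon
structure is not recoverable from protein sequences alone, so the
correspondence is computed by **global pairwise alignment** (BLOSUM62,
affine gap open 11 / extend 1 — the standard protein setting), via
`Biostrings::pairwiseAlignment()`. Terminal truncations surface as
terminal gaps; the dynamic-programming traceback is deterministic, so the
position map is reproducible.

Classification rules (`classify_pair()`):

* A canonical sequon whose Asn aligns to an isoform position that also
  carries a sequon is **retained** if the absolute coordinate is equal and
  **shifted** otherwise. The decision uses the Asn coordinate only — the x
  and +2 residues may differ, because a site is identified by its Asn.
* A canonical sequon whose Asn is deleted, or whose aligned Asn no longer
  completes a sequon (e.g. the x became proline), is **lost**: the site no
  longer exists, whether or not the asparagine survives.
* An isoform sequon whose Asn is an insertion, or aligns to a canonical
  position without a sequon, is **gained**.

Every sequon of both sequences lands in exactly one row, which gives the
conservation identity *retained + shifted + lost = canonical sequon
count* per pair; this is asserted for every simulated pair in the test
suite. Proteins with several isoforms are classified pair by pair;
protein-level summaries (`summarize_changes()`) deduplicate by canonical
id. Because published tallies of "differing sites" can be counted per
site or per site×isoform, the summary reports both `total_differing_sites`
(per pair) and `n_unique_differing_sites` (deduplicated).

## Synthetic data: what it emulates, and what it does not

`simulate_isoforms()` derives each isoform from its canonical sequence by
one of four splice-style events — internal deletion, internal insertion,
terminal truncation, segment substitution — and labels every sequon
directly from the event's coordinate arithmetic. The labels are therefore
an **alignment-free oracle**: agreement between `classify_pair()` and the
generator is a genuine two-route check, not a self-comparison. A pair is
flagged *unambiguous* when every sequon is at least 3 residues clear of
the event footprint (or wholly inside a removed/inserted segment); for
those the alignment must recover the labels exactly, while
junction-adjacent sequons may legitimately admit more than one
correspondence.

Default generator settings describe the kind of study the pipeline is
meant for: 200–2000 proteins of length ~N(400, 100) (minimum 50), uniform
residue composition, event sizes 3 + Poisson(27), RNA-seq over
differentiation days 15/30/45/60 with 3 replicates per day,
negative-binomial counts with log-normal baseline means (meanlog
log 100, sdlog 1) and dispersion 0.1, 10% of genes planted with a 16-fold
change (the magnitude corresponding to the |log2FC| = 4 volcano
threshold), Poisson(20) spectral counts with per-day detection 0.8 and a
25% late-onset fraction, and SPC scores drawn with ~25% of genes at 3–4.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: real residue composition and domain
structure (uniform composition makes alignments easier than homologous
real pairs), frameshift translation and NMD (frameshifts are modeled only
as truncations), multiple simultaneous splice events per isoform,
correlated library-size or batch effects in counts, and
peptide-detectability bias in PSMs.

## Statistical choices

**Motif enrichment.** The source analyses state only that NxC/NxV occur
at a lower-than-expected rate in predicted surface proteins, without
defining "expected", so the null is made explicit here: per-sequence
residue shuffling, which preserves each protein's composition and length
exactly. The p-value is two-sided and empirical with the add-one
correction, p = (1 + #{|c − mean| ≥ |obs − mean|}) / (B + 1), which
avoids p = 0 and is standard permutation practice. A closed-form i.i.d.
null (`analytic_expected()`, (L−2)·f_N·(1−f_P)·f_Z) is provided and
tested against the permutation null — including exhaustive enumeration of
all arrangements of a toy sequence — so the two routes validate each
other. Calibration is checked by generating whole datasets under the null
and verifying the rejection rate at α = 0.05 stays in [0.03, 0.07]
(500 datasets of 30 shuffled 400-mers, 199 permutations each).

**Differential abundance.** The volcano tables use a Welch t-test on
log2(count + 1) across replicates and log2FC = log2(mean + 1) −
log2(mean_ref + 1), with the joint significance gate *raw p < 0.05 and
|log2FC| > 4*. No external differential-expression model is wrapped: the
claims downstream are threshold-level, and a transparent test keeps the
calibration verifiable (type-I error on null negative-binomial
simulations sits inside [0.03, 0.07]). Notable decisions:

* **No multiple-testing correction in the flag** (the thresholds are on
  raw p); a BH-adjusted column is emitted alongside for users.
* **Zero-variance groups report a missing p**, not p = 1 — identical
  replicate vectors carry no evidence for a t-test, and p = 1 would feign
  confidence.
* **Raw counts are the default scale** (`normalize = "none"`), with
  per-sample CPM as a toggle. When strong fold changes are planted
  asymmetrically, per-sample CPM shifts every gene's log2FC by the
  library-size ratio and drags genuinely changed genes off the |log2FC|
  gate; on equal-depth designs the two scales agree. For real libraries
  of unequal depth, turn CPM on.
* Genes with fewer than 10 total counts are excluded before testing.

A note on detection power at the threshold: a planted fold change of
exactly 16 puts the true |log2FC| exactly at the strict > 4 gate, so the
estimate exceeds it only when sampling noise pushes it over — roughly
half the time, symmetrically, for any replicate number. Planted effects
clearly above the gate (e.g. 32-fold) are detected with high power; the
test suite demonstrates both behaviors.

**Evidence profiles.** Transcript counts are averaged over technical
replicates per day, paired with spectral counts, and each modality is
divided by its per-protein maximum, so profiles are comparable shapes in
[0, 1]. An all-zero profile is returned as zeros with `detected = FALSE`
rather than 0/0. Concordance is the sign of the Spearman correlation over
shared timepoints (≥ 3 required), plus a discordance flag when one
modality is silent while the other's raw maximum exceeds a floor
(default 10) — the pattern of proteins with robust mRNA but no
glycopeptide evidence, or vice versa.

**SPC annotation.** Surface prediction consensus scores (0–4) are consumed
from a user-supplied table; 3–4 is the high-confidence surface filter.
Missing genes are marked missing and excluded by the filter — a score of
0 also covers GPI-anchored and ECM proteins, so neither "0" nor "absent"
is evidence of intracellular localization. Gene matching is exact first,
case-insensitive second.

## Determinism

Every stochastic routine takes an explicit seed, restores the caller's
RNG state, and is a pure function of (config, seed); simulated FASTA
files, change tables and pipeline JSON summaries are byte-identical
across reruns. Pipeline outputs embed the seed and a config fingerprint.

## Validation scale

The shipped test suite validates the scanner against an independent
regex-lookahead oracle on 1000 random sequences of length 50–2000 (all
four motif classes), classification against generator truth on 500 pairs
per event type, permutation-null calibration on 500 datasets, and volcano
calibration on 2000-gene simulations — sizes chosen to make Monte-Carlo
error small relative to the tolerances being asserted.
`scripts/acceptance.R` recomputes the same quantities from scratch from a
single seed.

## Known limitations

* Position correspondence is sequence-alignment-based; true exon-coordinate
  mapping can disagree near junctions with repeats.
* The sequon is necessary, not sufficient: occupancy is not modeled, so
  "gained" means a candidate site, not a glycosylated one.
* NxC/NxV enrichment contrasts inherit whatever biases the user's surface
  and intracellular set definitions carry.
* The Welch-on-log2 test is deliberately simple; for real RNA-seq with few
  replicates, a shrinkage-based model will be more powerful (at the cost
  of the transparent calibration demonstrated here).
* XLSX supplements must be exported to TSV/CSV before
  `read_isoform_table()` can consume them.
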