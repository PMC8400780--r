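---
title: "Methods: targeted PRM quantitation of isomeric haptoglobin N-glycopeptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted PRM quantitation of isomeric haptoglobin N-glycopeptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoPRM)
```

## The problem and the model

Serum haptoglobin carries N-glycans at four asparagines; three of them
(Asn184, Asn207, Asn241) can be monitored as tryptic/Glu-C glycopeptides
(`MVSHHNLTTGATLINE`, `NLFLNHSE`, `VVLHPNYSQVDIGLIK`). In hepatocellular
carcinoma (HCC) developing on a cirrhotic liver, the site-specific glycome
of Asn207 shifts: sialylated (non-fucosylated) glycoforms lose relative
abundance while sialylated-fucosylated glycoforms gain it. A targeted
LC-PRM-MS assay resolves, per site, glycan *compositions* (written as
four-digit codes counting HexNAc-Hex-Fuc-Neu5Ac, so `5-6-1-3` is
HexNAc5 Hex6 Fuc1 Neu5Ac3) and, chromatographically, their *isomers* -
same composition, different structure, separated in retention time.

glycoPRM implements this assay as a desk-scale, fully testable pipeline:

1. **Mass model** - peptide, glycan, precursor and fragment-ion masses on
   a single monoisotopic scale; precursor m/z is
   $(M_\text{pep} + M_\text{glycan} + z \cdot m_p)/z$. The quantifier set
   per target is the Y-ion ladder Y1 (peptide + HexNAc) through the
   trimannosyl core (six ions); oxonium ions are carried as diagnostic,
   non-quantifier entries.
2. **Target list** - the packaged glycoform inventory expands to 72
   isomer entries over 41 (site, composition) glycoforms.
3. **Synthetic cohort** - patients with the clinical structure of the
   study cohorts plus ground-truth relative abundances, rendered into
   PRM-style fragment chromatograms.
4. **Quantitation** - extracted-ion-chromatogram peak detection and
   trapezoidal integration, the desk equivalent of vendor peak-area
   software.
5. **Statistics** - per-site normalization, class summaries,
   gender-balanced differential testing with Bonferroni correction, PCA,
   and ROC/AUC marker evaluation.

## Mass scale and charge-state rule

Constants are the standard monoisotopic residue masses (HexNAc 203.079373,
Hex 162.052824, Fuc 146.057909, Neu5Ac 291.095417; water 18.010565, proton
1.007276). None of the three site peptides contains cysteine, so no fixed
modification applies. With this scale the assay's reference precursor
values reproduce exactly at four decimals:

```{r}
precursor_mz("Asn207", "5-6-0-3", 3) # 1278.8295
precursor_mz("Asn207", "5-6-0-2", 3) # 1181.7977
```

Reference *fragment* m/z values in the assay documentation differ from
theory by a few mDa (1-4 ppm); fragment identity is therefore asserted at
10 ppm rather than at printed precision, and EIC matching uses a 10 ppm
tolerance. Charge states follow a deterministic predicate: 4+ for
tri-/tetra-antennary sialylated glycoforms at Asn241 (at least three
HexNAc antennae beyond the chitobiose core and at least one Neu5Ac),
3+ otherwise.

## What the synthetic generator emulates

The generator's defaults are the study conditions the pipeline is
validated against:

* **Cohort**: 15 cirrhosis (3M/12F) and 15 HCC (7M/8F) patients; HCC TNM
  stage proportions 47/0/40/13 percent, allocated at n = 15 by largest
  remainder to 7/0/6/2; log-normal AFP with medians 2.9 (cirrhosis) and
  6.0 ng/mL (HCC). The AFP log-sd (1.0 natural-log units) is a free
  parameter - only medians are specified by the study - chosen as a
  realistic serum-marker spread; it is a convention, not a claim about the
  cohort.
* **Glycome**: per-site class means. Asn207 is calibrated to the study's
  pie summaries - cirrhosis (sialylated, sialylated-fucosylated, other) =
  (87.2, 12.1, 0.7) percent, HCC = (77.5, 21.7, 0.8) percent. Asn184 and
  Asn241 show no significant class changes in the study, so their class
  means are equal across groups; the values used (90/8.5/1.5 and
  92/6/2 percent) are sialylated-dominant profiles typical of serum
  glycoproteins, chosen once as plausible fixtures. Within a class the
  mean is split equally across glycoforms, reshaped by per-glycoform
  effect weights: the HCC allocation is tilted toward `Asn207|5-6-1-2`
  (x1.3) and `Asn207|5-6-1-3` (x1.5) and away from `Asn207|5-6-0-1`
  (x0.8) and `Asn207|5-6-0-2` (x0.85), mirroring the study's heat-map
  directions while leaving class totals untouched.
* **Noise**: logistic-normal abundance noise (Gaussian with sd 0.15 on log
  abundances, renormalized per site) preserves the compositional
  structure; sd 0 degenerates to the exact group means.
* **Peak model**: Gaussian peaks with sigma = 0.3 min; isomers of one
  composition spaced 2.0 min apart; six fragment traces per target with
  intensity split (0.35, 0.20, 0.15, 0.12, 0.10, 0.08); baseline 50
  counts; 5 percent multiplicative intensity noise; total rendered area
  per site 1e7 counts x min; time grid 40-90 min sampled every 0.02 min.
  Expected retention times are fixture conventions: glycoform cluster
  centers are spread evenly inside each site's elution window (Asn184
  42-54, Asn207 40-60, Asn241 61-88 min), ordered so small, lightly
  sialylated compositions elute first.

What the generator does **not** emulate: isotope envelopes, co-isolation
interference, retention-time drift between runs, peak tailing,
heteroscedastic detector noise, or missing patients. Passing recovery
tests therefore demonstrates the internal consistency of the quantitation
chain under idealized chromatography - not robustness to real-data
pathologies such as mis-aligned or overlapping peaks across samples.

## Numerical choices in quantitation

* EICs sum stored traces within 10 ppm of the target fragment m/z,
  confined to the owning precursor's trace group (as in PRM acquisition),
  restricted to the expected retention time +/- 3 min.
* Quantitation runs on the *composite* trace (pointwise sum of the six
  fragment EICs) rather than on six independently integrated fragments:
  apexes and boundaries then agree across fragments by construction.
* Peak detection: local maxima of a lightly smoothed composite (5-point
  moving average), kept above 5 percent of the tallest apex, merged
  within 0.8 min (taller apex wins). Vendor software's smoothing and
  bounding settings are not published; this valley/1-percent convention
  is validated only against synthetic truth.
* Boundaries: adjacent peaks split at the inter-apex valley; outer bounds
  stop where the signal falls to 1 percent of apex height above the trace
  floor. Integration is trapezoidal with a local linear baseline (the
  chord between boundary intensities), floored at zero. Because every
  rendered peak shares one sigma, the small constant fraction of area
  outside the bounds cancels in per-site normalization.
* Isomer identity is positional: detected peaks are labelled 1..k by
  ascending retention time. With more apexes than expected the tallest
  are kept (extras logged); with fewer, each detected peak is matched to
  the nearest expected retention time and the remaining isomers are
  reported as zero area with a flag - never silently dropped.
* Degenerate inputs: all-flat traces yield no peaks; a zero-total
  patient-site cannot be normalized and is flagged rather than divided.

On noise-free renderings the chain recovers ground-truth relative
abundances to better than 1 percent per entry, and with default noise the
Asn207 class means are recovered to within a few tenths of a percentage
point over 20 replicate cohorts (the acceptance script recomputes this).

## Statistical design choices

* **Gender balancing**: the cirrhosis arm is female-heavy, so both arms
  are subsampled to the identical gender composition of maximal size
  (all of the scarcer gender kept in each column: 3M/8F per arm for the
  default cohort); three such subsets are drawn on a seeded stream.
* **Tests**: Welch's two-sided t-test (the HCC arm is the more variable
  one) plus the Wilcoxon rank-sum test as a robustness companion;
  Bonferroni correction with n = 3. A feature is called significant when
  its corrected t-test p-value is below 0.05 in *all three* subsets - the
  strictest reading of "significant despite the gender factor"; any/
  majority rules are available by configuration. How the original
  analysis combined the three subsets is not stated; the all-subsets rule
  is this package's declared choice, and it makes the procedure
  conservative (type-I error well under alpha in the test suite's null
  simulations).
* **ROC**: AUC as the tie-aware Mann-Whitney statistic; DeLong confidence
  intervals by default (bootstrap optional). Markers lower in HCC are
  auto-flipped (flip recorded) so AUC is always reported above 0.5.
* **Marker combination**: in-sample binary logistic regression on
  standardized features with AFP log-transformed, scored by the linear
  predictor - deliberately mirroring an SPSS-style workflow, and
  acknowledged as optimistic since no cross-validation is claimed. Ridge
  fallback (glmnet, alpha = 0) handles perfect separation.
* **PCA**: mean-centering with Pareto scaling (the MarkerView convention;
  autoscaling optional), computed by SVD.

The study's patient-level results (its exact p-values and AUCs, and the
17-to-4 narrowing of candidate markers) depend on the real cohort, which
is not packaged; the package validates the *machinery* against generator
truth instead: injected Asn207 effects are detected in >= 90 percent of
seeded cohorts while Asn184 null features stay quiet, and AFP +
glycopeptide panels beat AFP alone with the same directionality as the
published ordering (0.98 vs 0.85).

## Problem sizes and reproducibility

All validation runs at desk scale, chosen to keep the whole suite fast
while leaving the study conditions untouched: 30-patient cohorts, 20
replicate cohorts for class-mean recovery, 50 seeded cohorts for power
and panel-ordering checks, 1000 features for null calibration, and
10,000 draws for AFP medians. Every random stage (cohort sampling,
abundance noise, chromatogram noise, subset draws) descends from a single
configured seed; identical configuration plus seed gives bit-identical
datasets, tables and CSV artifacts, and each pipeline run writes a
manifest (seed, config hash, versions) sufficient to reproduce it.

## Known limitations

* Compositions only: no antenna-branching or linkage inference, and no
  core-vs-branch fucose localization - isomers are positional
  (chromatographic) entities.
* The fixture retention-time layout is a convention, not a prediction;
  real elution order within a window may differ.
* In-sample AUCs for combined markers are optimistic by design.
* The synthetic cohort's idealized chromatography means recovery results
  bound implementation error, not field performance on raw data.
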