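# glycoPRM

Targeted LC-PRM-MS quantitation of site-specific isomeric N-glycopeptides
of serum haptoglobin, for distinguishing cirrhosis from hepatocellular
carcinoma (HCC).

## Who this is for

Glycoproteomics groups running (or planning) parallel-reaction-monitoring
assays on haptoglobin glycopeptides, and methodologists who want a fully
reproducible, synthetic-data-driven reference implementation of the
analysis chain: transition-list construction, chromatogram quantitation,
compositional normalization, and marker statistics. Everything runs at
desk scale with no external data.

## The assay in brief

Haptoglobin carries N-glycans at Asn184, Asn207 and Asn241, monitored as
the tryptic/Glu-C peptides `MVSHHNLTTGATLINE`, `NLFLNHSE` and
`VVLHPNYSQVDIGLIK`. Glycan compositions are written as four-digit codes
counting HexNAc-Hex-Fuc-Neu5Ac (`5-6-1-3` = HexNAc5 Hex6 Fuc1 Neu5Ac3);
a long C18 gradient additionally resolves *isomers* of one composition as
separate peaks. Precursors are computed as

    m/z = (M_peptide + M_glycan + z * m_proton) / z

on the standard monoisotopic scale, and each target is quantified on six
Y-ion fragments (Y1 = peptide + HexNAc, then the chitobiose/trimannosyl
core ladder). Peak areas are normalized per glycosylation site to
relative abundances; cirrhosis-vs-HCC markers are evaluated with
gender-balanced t/Wilcoxon tests (Bonferroni n = 3), PCA, and single- and
combined-marker ROC/AUC (DeLong confidence intervals, in-sample logistic
combination).

The package covers 72 isomer entries over 41 glycoforms (13 entries at
Asn184, 43 at Asn207, 16 at Asn241) and ships a synthetic-cohort
generator whose defaults match the study conditions: 15 cirrhosis
(3M/12F) vs 15 HCC (7M/8F) patients, log-normal AFP with medians
2.9/6.0 ng/mL, and an Asn207 glycome shifting from 87.2% sialylated /
12.1% sialylated-fucosylated in cirrhosis to 77.5% / 21.7% in HCC.

## Worked example

```r
library(glycoPRM)

targets <- build_target_list()          # 72 isomer entries from the inventory
precursor_mz("Asn207", "5-6-0-3", 3)    # 1278.8295

cohort <- generate_cohort(cohort_config(seed = 1), targets)
qt  <- quantify_cohort(cohort)          # render + integrate chromatograms
rel <- normalize_by_site(qt)
glycome_class_summary(rel, cohort$patients, "Asn207")
#>     site     group                  class fraction
#> 1 Asn207 cirrhosis                  other  0.00671
#> 2 Asn207 cirrhosis             sialylated  0.87138
#> 3 Asn207 cirrhosis sialylated_fucosylated  0.12190
#> 4 Asn207       HCC                  other  0.00778
#> 5 Asn207       HCC             sialylated  0.77475
#> 6 Asn207       HCC sialylated_fucosylated  0.21747
```

The recovered class fractions are the pipeline's estimate of the Asn207
glycome shift (compare the generating means 87.2/12.1 and 77.5/21.7
percent). Differential testing across three gender-balanced subsets
flags Asn207 glycoforms - led by the sialylated-fucosylated isomers of
`5-6-1-3` - and leaves the null sites quiet:

```r
subsets <- gender_balanced_subsets(cohort$patients, stats_config(subset_seed = 1))
dt <- differential_tests(rel, cohort$patients, subsets)
head(dt$summary[dt$summary$significant, ])
#>             feature max_t_p_corrected significant
#> 53 Asn207|5-6-1-3|2           7.3e-11        TRUE
#> 37 Asn207|5-6-1-2|1           8.0e-10        TRUE
#> 48 Asn207|5-6-1-3|1           1.0e-07        TRUE
#> ...                                    (all flagged features are Asn207)

labels <- cohort$patients$group == "HCC"
roc_auc(log(cohort$patients$afp_ng_ml), labels)
#> AUC 0.720 (95% CI 0.526-0.914), 15 pos / 15 neg
f <- targets$target_key[targets$site_id == "Asn207" &
                        targets$glycan_code == "5-6-1-3"]
combine_markers(cbind(afp = cohort$patients$afp_ng_ml,
                      rel$values[, f]), labels)$roc
#> AUC 1.000 (95% CI 1.000-1.000), 15 pos / 15 neg
```

On this synthetic cohort AFP alone discriminates modestly (AUC 0.72)
while the AFP + Asn207 `5-6-1-3` panel separates the groups completely -
the same ordering the assay is designed to exploit. `run_pipeline()`
chains all stages and writes the CSV artifacts plus a manifest;
`exec/glycoprm` exposes `build-targets`, `simulate` and `run-all` from
the shell.

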