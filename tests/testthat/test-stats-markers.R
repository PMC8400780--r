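targets <- build_target_list()

test_that("gender balancing matches both groups to identical ratios", {
  cohort <- generate_cohort(cohort_config(seed = 1), targets)
  subsets <- gender_balanced_subsets(cohort$patients,
                                     stats_config(subset_seed = 5))
  expect_length(subsets, 3L)
  for (ids in subsets) {
    sub <- cohort$patients[cohort$patients$patient_id %in% ids, ]
    counts <- table(sub$group, sub$gender)
    # 3M/8F in both arms: all cirrhosis males kept, 4 cirrhosis females and
    # 4 HCC males dropped
    expect_equal(as.integer(counts["cirrhosis", c("M", "F")]), c(3L, 8L))
    expect_equal(as.integer(counts["HCC", c("M", "F")]), c(3L, 8L))
  }
  # subsets differ only in which majority-gender patients were dropped
  expect_gt(length(unique(vapply(subsets, paste, character(1),
                                 collapse = ","))), 1L)

  # already-balanced groups: the full cohort in every subset
  bal <- data.frame(
    patient_id = sprintf("P%02d", 1:20),
    group = rep(c("cirrhosis", "HCC"), each = 10),
    gender = rep(rep(c("M", "F"), each = 5), 2)
  )
  subs_bal <- gender_balanced_subsets(bal, stats_config())
  for (ids in subs_bal) expect_setequal(ids, bal$patient_id)

  # a group lacking one gender cannot be ratio-matched
  bad <- bal
  bad$gender[bad$group == "HCC"] <- "F"
  expect_error(gender_balanced_subsets(bad, stats_config()), "lack one gender")
})

test_that("differential tests control error and detect injected effects", {
  # null features: raw t-test false-positive rate near alpha, the
  # three-subset Bonferroni procedure flags (far) fewer
  set.seed(41)
  cohort <- generate_cohort(cohort_config(seed = 2), targets)
  n_feat <- 400
  null_x <- matrix(rlnorm(30 * n_feat, 0, 0.3), nrow = 30,
                   dimnames = list(cohort$patients$patient_id,
                                   paste0("f", seq_len(n_feat))))
  subsets <- gender_balanced_subsets(cohort$patients,
                                     stats_config(subset_seed = 3))
  dt <- differential_tests(null_x, cohort$patients, subsets, stats_config())
  raw_fp <- mean(dt$per_subset$t_p[dt$per_subset$subset == 1] < 0.05)
  expect_gt(raw_fp, 0.02)
  expect_lt(raw_fp, 0.09)
  expect_lte(mean(dt$summary$significant), 0.05)
  # Bonferroni monotonicity, capped at one
  expect_true(all(dt$per_subset$t_p_corrected >= dt$per_subset$t_p))
  expect_true(all(dt$per_subset$t_p_corrected <= 1))

  # identical group values: p = 1, flagged, not significant
  const_x <- matrix(0.5, 30, 1,
                    dimnames = list(cohort$patients$patient_id, "const"))
  dtc <- differential_tests(const_x, cohort$patients, subsets, stats_config())
  expect_true(all(dtc$per_subset$t_p == 1))
  expect_true(all(dtc$per_subset$flag == "constant_or_missing"))
  expect_false(any(dtc$summary$significant))

  # injected Asn207 effect vs Asn184 null, against generator truth
  hits <- 0L
  fp184 <- 0L
  n_seeds <- 10L
  f184 <- targets$target_key[targets$site_id == "Asn184"]
  f207 <- targets$target_key[targets$glycan_code == "5-6-1-3" &
                               targets$site_id == "Asn207"]
  for (s in seq_len(n_seeds)) {
    ch <- generate_cohort(cohort_config(seed = 100 + s), targets)
    subs <- gender_balanced_subsets(ch$patients,
                                    stats_config(subset_seed = s))
    res <- differential_tests(truth_as_rel(ch), ch$patients, subs,
                              stats_config())
    sig <- res$summary$feature[res$summary$significant]
    if (all(f207 %in% sig)) hits <- hits + 1L
    fp184 <- fp184 + sum(f184 %in% sig)
  }
  expect_gte(hits / n_seeds, 0.9)
  # per-feature false flags on the null site stay rare
  expect_lte(fp184 / (n_seeds * length(f184)), 0.05)
})

test_that("AUC equals exhaustive pair counting and is rank-invariant", {
  expect_equal(roc_auc(c(0.9, 0.4, 0.5, 0.1),
                       c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  # perfect separation and all-tied scores
  expect_equal(roc_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)

  # exhaustive pair-counting oracle on random small inputs
  set.seed(53)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    scores <- sample(1:6, n, replace = TRUE) / 2
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    conc <- 0
    total <- 0
    for (p in which(labels)) for (q in which(!labels)) {
      conc <- conc + (scores[p] > scores[q]) + 0.5 * (scores[p] == scores[q])
      total <- total + 1
    }
    r <- roc_auc(scores, labels)
    expect_equal(max(conc / total, 1 - conc / total), r$auc)
    # monotone transform invariance
    r2 <- roc_auc(exp(2 * scores), labels)
    expect_equal(r2$auc, r$auc)
    # complement identity before auto-flip
    u <- glycoPRM:::auc_mann_whitney(scores, labels)
    u_neg <- glycoPRM:::auc_mann_whitney(-scores, labels)
    expect_equal(u + u_neg, 1)
  }
})

test_that("DeLong confidence intervals agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(61)
  for (i in 1:5) {
    scores <- c(rnorm(15, 1), rnorm(15))
    labels <- rep(c(TRUE, FALSE), each = 15)
    r <- roc_auc(scores, labels)
    ref <- pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE,
                                  direction = "<"), method = "delong")
    expect_equal(r$auc, as.numeric(ref[2]), tolerance = 1e-9)
    expect_equal(r$ci_low, max(0, as.numeric(ref[1])), tolerance = 1e-6)
    expect_equal(r$ci_high, min(1, as.numeric(ref[3])), tolerance = 1e-6)
    expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  }
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("marker orientation is auto-flipped and recorded", {
  # a marker lower in HCC discriminates after flipping
  scores <- c(1, 2, 3, 8, 9, 10)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  r <- roc_auc(scores, labels)
  expect_true(r$flipped)
  expect_equal(r$auc, 1)
})

test_that("combined markers behave like the single marker when alone", {
  set.seed(71)
  x <- matrix(rnorm(30), ncol = 1, dimnames = list(NULL, "m1"))
  labels <- x[, 1] + rnorm(30, 0, 0.8) > 0
  single <- roc_auc(x[, 1], labels)
  comb <- combine_markers(x, labels)
  expect_equal(comb$roc$auc, single$auc, tolerance = 1e-9)
})

test_that("combined AFP + glycopeptide panels beat AFP alone", {
  sc <- stats_config()
  wins <- 0L
  noise_shift <- numeric(0)
  n_seeds <- 10L
  f207 <- targets$target_key[targets$glycan_code == "5-6-1-3" &
                               targets$site_id == "Asn207"]
  for (s in seq_len(n_seeds)) {
    ch <- generate_cohort(cohort_config(seed = 200 + s), targets)
    labels <- ch$patients$group == "HCC"
    afp_auc <- roc_auc(log(ch$patients$afp_ng_ml), labels, sc)$auc
    feat <- cbind(afp = ch$patients$afp_ng_ml,
                  ch$truth[, f207, drop = FALSE])
    comb <- combine_markers(feat, labels, sc)
    if (comb$roc$auc >= afp_auc) wins <- wins + 1L
    # adding a pure-noise feature barely moves the in-sample AUC
    feat_noise <- cbind(feat, noise = rnorm(nrow(feat)))
    comb_noise <- combine_markers(feat_noise, labels, sc)
    noise_shift <- c(noise_shift, abs(comb_noise$roc$auc - comb$roc$auc))
  }
  expect_gte(wins / n_seeds, 0.9)
  expect_lt(median(noise_shift), 0.05)
})

test_that("perfect separation falls back to a ridge fit", {
  x <- cbind(a = c(rep(0, 10), rep(10, 10)), b = rnorm(20))
  labels <- rep(c(FALSE, TRUE), each = 10)
  comb <- combine_markers(x, labels)
  expect_true(comb$ridge)
  expect_equal(comb$roc$auc, 1)
})

test_that("PCA has orthonormal loadings and separates only Asn207", {
  # variance along one axis only: PC1 explains ~everything
  set.seed(81)
  x1 <- cbind(rnorm(20, sd = 5), rnorm(20, sd = 1e-4), rnorm(20, sd = 1e-4))
  p1 <- pca_scores(x1, stats_config(), n_components = 3)
  expect_gt(p1$explained_variance[1], 0.95)
  expect_true(all(diff(p1$explained_variance) <= 1e-12))
  expect_equal(crossprod(p1$loadings), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # scores have diagonal covariance
  cv <- cov(p1$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)

  skip_if_not_installed("cluster")
  sep207 <- 0L
  sil_diff <- numeric(0)
  n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    ch <- generate_cohort(cohort_config(seed = 300 + s), targets)
    labels <- as.integer(ch$patients$group == "HCC") + 1L
    sil <- vapply(c("Asn207", "Asn184"), function(site) {
      p <- pca_scores(ch$truth[, targets$site_id == site], stats_config())
      d <- as.matrix(dist(p$scores))
      mean(cluster::silhouette(labels, dmatrix = d)[, 3])
    }, numeric(1))
    if (sil[["Asn207"]] > 0) sep207 <- sep207 + 1L
    sil_diff <- c(sil_diff, sil[["Asn207"]] - sil[["Asn184"]])
  }
  expect_gte(sep207 / n_seeds, 0.8)
  expect_true(all(sil_diff > 0))
})
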