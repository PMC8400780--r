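#' Marker statistics configuration
#'
#' @param alpha Significance level.
#' @param n_subsets Number of gender-balanced subsets tested.
#' @param bonferroni_n Bonferroni multiplier applied to raw p-values.
#' @param subset_seed Seed for the subset sampling streams.
#' @param roc_ci_level Confidence level for AUC intervals.
#' @param roc_ci_method `"delong"` or `"bootstrap"` (percentile, 2000
#'   resamples).
#' @param pca_scaling `"pareto"` (default, MarkerView convention) or
#'   `"autoscale"`.
#' @param welch Use Welch's unequal-variance t-test (default) rather than
#'   the pooled-variance Student's t.
#' @param subset_rule How significance combines across subsets:
#'   `"all"` (default: corrected p below alpha in every subset),
#'   `"any"`, or `"majority"`.
#' @return A list of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.05, n_subsets = 3L, bonferroni_n = 3L,
                         subset_seed = 1L, roc_ci_level = 0.95,
                         roc_ci_method = c("delong", "bootstrap"),
                         pca_scaling = c("pareto", "autoscale"),
                         welch = TRUE,
                         subset_rule = c("all", "any", "majority")) {
  stopifnot(alpha > 0, alpha < 1, n_subsets >= 1, bonferroni_n >= 1,
            roc_ci_level > 0, roc_ci_level < 1)
  structure(
    list(alpha = alpha, n_subsets = as.integer(n_subsets),
         bonferroni_n = as.integer(bonferroni_n),
         subset_seed = as.integer(subset_seed),
         roc_ci_level = roc_ci_level,
         roc_ci_method = match.arg(roc_ci_method),
         pca_scaling = match.arg(pca_scaling),
         welch = welch, subset_rule = match.arg(subset_rule)),
    class = "stats_config"
  )
}

#' Gender-balanced patient subsets
#'
#' The cirrhosis arm of the study is female-heavy (3M/12F) while the HCC
#' arm is nearly balanced (7M/8F); comparing them directly risks gender
#' confounding. This procedure subsamples both groups, without
#' replacement, to the identical gender composition of maximal achievable
#' size - each group keeps `min` of the available males and `min` of the
#' available females across groups (3M/8F per arm for the default cohort)
#' - and repeats the draw `n_subsets` times on a seeded stream, so the
#' subsets differ only in which majority-gender patients are dropped.
#'
#' @param patients Patient data.frame with `patient_id`, `group`,
#'   `gender`.
#' @param config A [stats_config()].
#' @return A list of `n_subsets` character vectors of patient ids. After
#'   balancing, the M:F ratio is exactly equal across groups in every
#'   subset.
#' @export
gender_balanced_subsets <- function(patients, config = stats_config()) {
  groups <- unique(patients$group)
  stopifnot(length(groups) == 2L)
  counts <- table(factor(patients$group, groups),
                  factor(patients$gender, c("M", "F")))
  if (any(counts == 0)) {
    lacking <- groups[apply(counts == 0, 1, any)]
    stop("group(s) ", paste(lacking, collapse = ", "),
         " lack one gender entirely; gender-ratio matching needs both ",
         "genders in both groups (target per-group composition would be ",
         "min males : min females across groups)")
  }
  m <- min(counts[, "M"])
  f <- min(counts[, "F"])
  set.seed(config$subset_seed)
  lapply(seq_len(config$n_subsets), function(i) {
    ids <- unlist(lapply(groups, function(grp) {
      males <- patients$patient_id[patients$group == grp &
                                     patients$gender == "M"]
      females <- patients$patient_id[patients$group == grp &
                                       patients$gender == "F"]
      c(if (length(males) == m) males else sample(males, m),
        if (length(females) == f) females else sample(females, f))
    }))
    sort(ids)
  })
}

#' Differential glycoform tests across gender-balanced subsets
#'
#' Per feature and subset: a two-sided two-sample t-test (Welch by
#' default) and a Wilcoxon rank-sum test on relative abundances, with
#' Bonferroni correction (`corrected = min(1, raw * bonferroni_n)`). A
#' feature is significant when its corrected t-test p-value is below alpha
#' in every subset (the default `"all"` rule). Features constant in both
#' groups of a subset get p = 1 and a flag.
#'
#' @param rel A `rel_abundance_table` (or plain matrix patients x
#'   features).
#' @param patients Patient data.frame with `patient_id`, `group`.
#' @param subsets List of patient-id vectors from
#'   [gender_balanced_subsets()].
#' @param config A [stats_config()].
#' @return A list: `per_subset` (data.frame `feature`, `subset`, `t_p`,
#'   `wilcoxon_p`, `t_p_corrected`, `wilcoxon_p_corrected`, `flag`) and
#'   `summary` (data.frame `feature`, `max_t_p_corrected`, `significant`).
#' @export
differential_tests <- function(rel, patients, subsets,
                               config = stats_config()) {
  x <- if (inherits(rel, "rel_abundance_table")) rel$values else rel
  stopifnot(is.matrix(x))
  grp_of <- patients$group[match(rownames(x), patients$patient_id)]
  groups <- unique(patients$group)
  per <- list()
  for (s in seq_along(subsets)) {
    ids <- intersect(subsets[[s]], rownames(x))
    g <- grp_of[match(ids, rownames(x))]
    if (min(table(g)) < 2L) stop("subset ", s, " has fewer than 2 patients ",
                                 "in a group")
    for (j in seq_len(ncol(x))) {
      a <- x[ids[g == groups[1]], j]
      b <- x[ids[g == groups[2]], j]
      flag <- "ok"
      if (stats::sd(c(a, b)) == 0 || anyNA(c(a, b))) {
        tp <- wp <- 1
        flag <- "constant_or_missing"
      } else {
        tp <- stats::t.test(a, b, var.equal = !config$welch)$p.value
        wp <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
      }
      per[[length(per) + 1L]] <- data.frame(
        feature = colnames(x)[j], subset = s, t_p = tp, wilcoxon_p = wp,
        stringsAsFactors = FALSE, flag = flag
      )
    }
  }
  per <- do.call(rbind, per)
  per$t_p_corrected <- pmin(1, per$t_p * config$bonferroni_n)
  per$wilcoxon_p_corrected <- pmin(1, per$wilcoxon_p * config$bonferroni_n)

  agg <- function(p, rule) switch(rule,
    all = max(p), any = min(p),
    majority = sort(p)[ceiling(length(p) / 2)])
  feats <- unique(per$feature)
  crit <- vapply(feats, function(f)
    agg(per$t_p_corrected[per$feature == f], config$subset_rule), numeric(1))
  summary <- data.frame(feature = feats, max_t_p_corrected = unname(crit),
                        significant = unname(crit) < config$alpha,
                        stringsAsFactors = FALSE)
  list(per_subset = per, summary = summary)
}

# Mann-Whitney AUC with 0.5 credit for ties: mean over all (pos, neg)
# pairs of 1/0.5/0 for concordant/tied/discordant scores.
auc_mann_whitney <- function(scores, labels) {
  r <- rank(scores)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# DeLong placement-value variance for a single AUC.
delong_ci <- function(scores, labels, level) {
  pos <- scores[labels]
  neg <- scores[!labels]
  auc <- auc_mann_whitney(scores, labels)
  v10 <- vapply(pos, function(p) mean((p > neg) + 0.5 * (p == neg)),
                numeric(1))
  v01 <- vapply(neg, function(q) mean((pos > q) + 0.5 * (pos == q)),
                numeric(1))
  var_auc <- stats::var(v10) / length(pos) + stats::var(v01) / length(neg)
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(max(var_auc, 0))
  c(low = max(0, auc - half), high = min(1, auc + half))
}

#' ROC area under the curve with confidence interval
#'
#' AUC computed as the Mann-Whitney U statistic divided by
#' `n_pos * n_neg`, with half credit for ties; the confidence interval is
#' DeLong's nonparametric interval by default (percentile bootstrap as the
#' alternative). Orientation follows the study convention that larger
#' scores indicate HCC; a marker discriminating in the opposite direction
#' is automatically flipped and the flip recorded.
#'
#' @param scores Numeric marker values.
#' @param labels Logical (or two-level) vector; `TRUE`/second level = HCC
#'   (positive class).
#' @param config A [stats_config()].
#' @return A list of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`, `flipped`.
#' @examples
#' roc_auc(c(0.9, 0.4, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc # 0.75
#' @export
roc_auc <- function(scores, labels, config = stats_config()) {
  if (!is.logical(labels)) {
    u <- unique(as.character(labels))
    if (length(u) != 2L) stop("labels must have exactly two levels")
    pos <- if ("HCC" %in% u) "HCC" else u[2]
    labels <- as.character(labels) == pos
  }
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels)) stop("both classes must be present")
  flipped <- FALSE
  auc <- auc_mann_whitney(scores, labels)
  if (auc < 0.5) {
    scores <- -scores
    auc <- auc_mann_whitney(scores, labels)
    flipped <- TRUE
  }
  ci <- if (config$roc_ci_method == "delong") {
    delong_ci(scores, labels, config$roc_ci_level)
  } else {
    boots <- replicate(2000, {
      i <- sample(seq_along(scores), replace = TRUE)
      if (any(labels[i]) && !all(labels[i])) {
        auc_mann_whitney(scores[i], labels[i])
      } else NA_real_
    })
    stats::quantile(boots, c((1 - config$roc_ci_level) / 2,
                             1 - (1 - config$roc_ci_level) / 2),
                    na.rm = TRUE, names = FALSE)
  }
  structure(list(auc = auc, ci_low = min(ci[1], auc),
                 ci_high = max(ci[2], auc),
                 n_pos = sum(labels), n_neg = sum(!labels),
                 flipped = flipped, ci_level = config$roc_ci_level),
            class = "roc_result")
}

#' @exportS3Method base::print
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.0f%% CI %.3f-%.3f), %d pos / %d neg%s\n",
              x$auc, 100 * x$ci_level, x$ci_low, x$ci_high, x$n_pos,
              x$n_neg, if (x$flipped) " [orientation flipped]" else ""))
  invisible(x)
}

#' Combine markers with in-sample logistic regression
#'
#' Fits a binary logistic model on standardized features (AFP, when
#' present, is entered log-transformed) and scores each patient with the
#' linear predictor; the combined AUC is computed in-sample on the fitting
#' cohort, mirroring an SPSS-style binary-logistic workflow, and is
#' therefore optimistic. Missing feature values are imputed with the
#' feature median (logged). Under perfect separation the fit falls back to
#' a ridge-penalized logistic regression.
#'
#' @param features Matrix or data.frame (patients x markers).
#' @param labels Logical vector, `TRUE` = HCC.
#' @param config A [stats_config()].
#' @param afp_col Name of the AFP column to log-transform, or `NULL`.
#' @return A list of class `combined_marker`: `score` (linear predictor),
#'   `roc` (a `roc_result`), `coefficients`, `imputed` (count of imputed
#'   cells), `ridge` (logical fallback indicator).
#' @export
combine_markers <- function(features, labels, config = stats_config(),
                            afp_col = intersect("afp", colnames(features))) {
  x <- as.matrix(features)
  stopifnot(nrow(x) == length(labels), ncol(x) >= 1L)
  if (length(afp_col)) {
    for (cc in afp_col) x[, cc] <- log(x[, cc])
  }
  imputed <- 0L
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) {
      x[miss, j] <- stats::median(x[, j], na.rm = TRUE)
      imputed <- imputed + sum(miss)
    }
  }
  xs <- scale(x)
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  y <- as.integer(labels)

  ridge <- FALSE
  fit <- suppressWarnings(stats::glm(y ~ xs, family = stats::binomial()))
  separated <- !fit$converged ||
    any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)
  if (separated && ncol(xs) >= 2L) {
    ridge <- TRUE
    gfit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                           lambda = 1e-2, standardize = FALSE)
    beta <- as.numeric(gfit$beta)
    score <- as.numeric(xs %*% beta) + gfit$a0
    coefs <- c(intercept = as.numeric(gfit$a0),
               stats::setNames(beta, colnames(xs)))
  } else {
    beta <- stats::coef(fit)
    beta[is.na(beta)] <- 0
    score <- as.numeric(cbind(1, xs) %*% beta)
    coefs <- stats::setNames(beta, c("intercept", colnames(x)))
  }
  structure(
    list(score = score, roc = roc_auc(score, labels, config),
         coefficients = coefs, imputed = imputed, ridge = ridge),
    class = "combined_marker"
  )
}

#' Principal component analysis with Pareto scaling
#'
#' Mean-centers the patients x features matrix, applies Pareto scaling
#' (division by the square root of each feature's standard deviation; the
#' MarkerView convention) or autoscaling, and computes principal
#' components by singular value decomposition. Loadings are orthonormal
#' and explained variance is non-increasing.
#'
#' @param x Matrix patients x features (e.g. one site's columns of a
#'   `rel_abundance_table$values`).
#' @param config A [stats_config()].
#' @param n_components Number of components to keep (truncated at the
#'   matrix rank).
#' @return A list of class `pca_result`: `scores`, `loadings`,
#'   `explained_variance` (proportions), `scaling`.
#' @export
pca_scores <- function(x, config = stats_config(), n_components = 2L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 3L)
  xc <- scale(x, center = TRUE, scale = FALSE)
  sd <- apply(x, 2, stats::sd)
  div <- switch(config$pca_scaling,
                pareto = sqrt(sd),
                autoscale = sd)
  div[div == 0] <- 1
  xs <- sweep(xc, 2, div, "/")
  sv <- svd(xs)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  k <- min(n_components, rank)
  ev <- sv$d^2 / sum(sv$d^2)
  structure(
    list(scores = sv$u[, seq_len(k), drop = FALSE] %*%
           diag(sv$d[seq_len(k)], k, k),
         loadings = sv$v[, seq_len(k), drop = FALSE],
         explained_variance = ev[seq_len(k)],
         scaling = config$pca_scaling,
         truncated = k < n_components),
    class = "pca_result"
  )
}
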