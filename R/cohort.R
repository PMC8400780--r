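#' Synthetic cohort configuration
#'
#' Assembles (and validates) the full configuration of the synthetic study:
#' cohort composition (group sizes, gender counts, TNM stage mix, AFP
#' model), per-site glycome class-mean profiles per group, per-glycoform
#' effect weights, compositional noise, and the chromatographic peak model
#' used to render PRM fragment traces.
#'
#' Defaults encode the study conditions the pipeline is validated against:
#' 15 cirrhosis (3M/12F) vs 15 HCC (7M/8F) patients; HCC TNM stage mix
#' 47/0/40/13 percent (largest-remainder allocation 7/0/6/2 at n = 15);
#' log-normal AFP with group medians 2.9 and 6.0 ng/mL; Asn207 class means
#' (sialylated, sialylated-fucosylated, other) of (87.2, 12.1, 0.7) percent
#' in cirrhosis shifting to (77.5, 21.7, 0.8) percent in HCC, while Asn184
#' and Asn241 class means are identical across groups.
#'
#' @param gender_counts Named list per group of `c(M = , F = )` counts.
#' @param tnm_proportions HCC stage proportions over I-IV (sum to 1).
#' @param afp_median Named vector of group AFP medians, ng/mL.
#' @param afp_log_sd Standard deviation of log(AFP); the AFP model is
#'   log-normal so the distribution median equals `afp_median`.
#' @param class_means Per-site, per-group named vectors of mean relative
#'   abundance for the classes `sialylated`, `sialylated_fucosylated`,
#'   `other` (each summing to 1).
#' @param effect_weights Named list per group of multiplicative weights
#'   keyed by `"site|code"`; weights reshape how a class mean is allocated
#'   across the class's glycoforms (renormalized within class, so class
#'   totals are untouched). Defaults tilt the HCC allocation toward the
#'   fucosylated-sialylated Asn207 glycoforms 5-6-1-2/5-6-1-3 and away from
#'   the tri-antennary sialylated 5-6-0-1/5-6-0-2.
#' @param abundance_log_sd Logistic-normal noise: Gaussian sd on log
#'   abundances before per-site renormalization.
#' @param peak_sigma Gaussian peak sd, minutes.
#' @param isomer_spacing Retention-time spacing of isomer apexes, minutes.
#' @param sampling_interval Chromatogram sampling interval, minutes.
#' @param time_range Chromatogram time grid limits, minutes.
#' @param fragment_split Proportions of a target's total signal carried by
#'   its six quantifier fragments (sums to 1).
#' @param baseline Additive baseline level, counts.
#' @param noise_sd Multiplicative intensity noise sd.
#' @param total_scale Total rendered peak area per site per patient,
#'   counts x minutes.
#' @param seed Integer seed; identical config + seed give an identical
#'   dataset.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(
    gender_counts = list(cirrhosis = c(M = 3, F = 12), HCC = c(M = 7, F = 8)),
    tnm_proportions = c(I = 0.47, II = 0, III = 0.40, IV = 0.13),
    afp_median = c(cirrhosis = 2.9, HCC = 6.0),
    afp_log_sd = 1.0,
    class_means = list(
      Asn184 = list(
        cirrhosis = c(sialylated = 0.900, sialylated_fucosylated = 0.085,
                      other = 0.015),
        HCC = c(sialylated = 0.900, sialylated_fucosylated = 0.085,
                other = 0.015)
      ),
      Asn207 = list(
        cirrhosis = c(sialylated = 0.872, sialylated_fucosylated = 0.121,
                      other = 0.007),
        HCC = c(sialylated = 0.775, sialylated_fucosylated = 0.217,
                other = 0.008)
      ),
      Asn241 = list(
        cirrhosis = c(sialylated = 0.920, sialylated_fucosylated = 0.060,
                      other = 0.020),
        HCC = c(sialylated = 0.920, sialylated_fucosylated = 0.060,
                other = 0.020)
      )
    ),
    effect_weights = list(
      cirrhosis = c(),
      HCC = c("Asn207|5-6-1-2" = 1.3, "Asn207|5-6-1-3" = 1.5,
              "Asn207|5-6-0-1" = 0.8, "Asn207|5-6-0-2" = 0.85)
    ),
    abundance_log_sd = 0.15,
    peak_sigma = 0.3,
    isomer_spacing = 2.0,
    sampling_interval = 0.02,
    time_range = c(40, 90),
    fragment_split = c(0.35, 0.20, 0.15, 0.12, 0.10, 0.08),
    baseline = 50,
    noise_sd = 0.05,
    total_scale = 1e7,
    seed = 1L) {
  config <- list(
    gender_counts = gender_counts, tnm_proportions = tnm_proportions,
    afp_median = afp_median, afp_log_sd = afp_log_sd,
    class_means = class_means, effect_weights = effect_weights,
    abundance_log_sd = abundance_log_sd, peak_sigma = peak_sigma,
    isomer_spacing = isomer_spacing, sampling_interval = sampling_interval,
    time_range = time_range, fragment_split = fragment_split,
    baseline = baseline, noise_sd = noise_sd, total_scale = total_scale,
    seed = as.integer(seed)
  )
  validate_cohort_config(config)
  class(config) <- "cohort_config"
  config
}

validate_cohort_config <- function(config) {
  with(config, {
    stopifnot(
      all(c("cirrhosis", "HCC") %in% names(gender_counts)),
      all(vapply(gender_counts, function(g) all(g >= 0) && sum(g) >= 1,
                 logical(1)))
    )
    if (any(tnm_proportions < 0) || abs(sum(tnm_proportions) - 1) > 1e-8) {
      stop("tnm_proportions must be non-negative and sum to 1")
    }
    if (any(afp_median <= 0) || afp_log_sd < 0) {
      stop("AFP model requires positive medians and non-negative log-sd")
    }
    for (site in names(class_means)) for (grp in names(class_means[[site]])) {
      cm <- class_means[[site]][[grp]]
      if (any(cm < 0) || abs(sum(cm) - 1) > 1e-8) {
        stop("class means for ", site, "/", grp,
             " must be non-negative and sum to 1")
      }
    }
    if (peak_sigma <= 0) stop("peak_sigma must be positive")
    if (any(fragment_split < 0) || abs(sum(fragment_split) - 1) > 1e-8) {
      stop("fragment_split must be non-negative and sum to 1")
    }
    if (abundance_log_sd < 0 || noise_sd < 0) {
      stop("noise standard deviations must be non-negative")
    }
  })
  invisible(TRUE)
}

#' Simulate AFP concentrations
#'
#' Log-normal draws whose distribution median equals the configured group
#' median; with `afp_log_sd = 0` every draw equals the median.
#'
#' @param group `"cirrhosis"` or `"HCC"`.
#' @param config A [cohort_config()].
#' @param n Number of draws (uses the current RNG stream).
#' @return Numeric vector of AFP concentrations, ng/mL.
#' @export
simulate_afp <- function(group, config = cohort_config(), n = 1L) {
  med <- config$afp_median[[match.arg(group, names(config$afp_median))]]
  stats::rlnorm(n, meanlog = log(med), sdlog = config$afp_log_sd)
}

# Largest-remainder integer allocation of n patients across stage
# proportions (e.g. 47/0/40/13 % at n = 15 -> 7/0/6/2).
allocate_tnm <- function(proportions, n) {
  raw <- proportions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(proportions))
}

# Per-entry mean relative abundances for one group: class means allocated
# across the site's isomer entries, equal within class up to per-glycoform
# effect weights (renormalized within class).
group_mean_profile <- function(targets, config, group) {
  means <- numeric(nrow(targets))
  w_cfg <- config$effect_weights[[group]]
  for (sid in unique(targets$site_id)) {
    in_site <- targets$site_id == sid
    cm <- config$class_means[[sid]][[group]]
    if (is.null(cm)) stop("no class means configured for ", sid, "/", group)
    for (cls in names(cm)) {
      sel <- in_site & targets$glycan_class == cls
      if (!any(sel)) next
      w <- rep(1, sum(sel))
      if (length(w_cfg)) {
        hit <- match(targets$form_key[sel], names(w_cfg))
        w[!is.na(hit)] <- w_cfg[hit[!is.na(hit)]]
      }
      means[sel] <- cm[[cls]] * w / sum(w)
    }
    # any class absent from the site: renormalize what is present
    means[in_site] <- means[in_site] / sum(means[in_site])
  }
  means
}

#' Generate a synthetic patient cohort with ground-truth glycoform profiles
#'
#' Samples patient metadata (gender, TNM stage, AFP) and per-patient
#' ground-truth relative abundances for every isomer entry in the target
#' list. Abundance noise is logistic-normal: per-entry group means are
#' multiplied by `exp(N(0, abundance_log_sd))` and renormalized per site,
#' so profiles remain compositional; with zero noise every patient equals
#' the group mean profile exactly.
#'
#' @param config A [cohort_config()].
#' @param targets Target list from [build_target_list()].
#' @return A list of class `glyco_cohort` with elements `patients`
#'   (data.frame: `patient_id`, `group`, `gender`, `afp_ng_ml`,
#'   `tnm_stage`, `render_seed`), `truth` (matrix patients x isomer entries
#'   of true relative abundances, rows summing to 1 per site), `targets`
#'   and `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1), build_target_list())
#' table(cohort$patients$group, cohort$patients$gender)
#' @export
generate_cohort <- function(config = cohort_config(),
                            targets = build_target_list()) {
  stopifnot(nrow(targets) >= 1L)
  validate_cohort_config(config)
  set.seed(config$seed)

  groups <- names(config$gender_counts)
  patients <- do.call(rbind, lapply(groups, function(grp) {
    g <- config$gender_counts[[grp]]
    n <- sum(g)
    data.frame(
      patient_id = sprintf("%s%02d", if (grp == "HCC") "H" else "C",
                           seq_len(n)),
      group = grp,
      gender = rep(c("M", "F"), times = c(g[["M"]], g[["F"]])),
      stringsAsFactors = FALSE
    )
  }))
  patients$afp_ng_ml <- NA_real_
  for (grp in groups) {
    sel <- patients$group == grp
    patients$afp_ng_ml[sel] <- simulate_afp(grp, config, sum(sel))
  }
  patients$tnm_stage <- NA_character_
  hcc <- which(patients$group == "HCC")
  if (length(hcc)) {
    counts <- allocate_tnm(config$tnm_proportions, length(hcc))
    stages <- rep(names(counts), times = counts)
    patients$tnm_stage[hcc] <- sample(stages)
  }
  patients$render_seed <- sample.int(.Machine$integer.max - 1L,
                                     nrow(patients))

  mean_profiles <- lapply(groups, function(grp)
    group_mean_profile(targets, config, grp))
  names(mean_profiles) <- groups

  truth <- matrix(NA_real_, nrow(patients), nrow(targets),
                  dimnames = list(patients$patient_id, targets$target_key))
  site_of <- targets$site_id
  for (i in seq_len(nrow(patients))) {
    mu <- mean_profiles[[patients$group[i]]]
    a <- mu * exp(stats::rnorm(length(mu), 0, config$abundance_log_sd))
    for (sid in unique(site_of)) {
      sel <- site_of == sid
      a[sel] <- a[sel] / sum(a[sel])
    }
    truth[i, ] <- a
  }

  structure(
    list(patients = patients, truth = truth, targets = targets,
         config = config),
    class = "glyco_cohort"
  )
}

#' @exportS3Method base::print
print.glyco_cohort <- function(x, ...) {
  cat("Synthetic PRM cohort:", nrow(x$patients), "patients (",
      paste(sprintf("%s n=%d", names(table(x$patients$group)),
                    as.integer(table(x$patients$group))), collapse = ", "),
      "),", ncol(x$truth), "isomer entries\n")
  invisible(x)
}
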