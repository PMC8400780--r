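#' Run the full synthetic PRM analysis pipeline
#'
#' Chains every stage end to end: build the target list, generate the
#' synthetic cohort, render and quantify chromatograms, normalize per
#' site, summarize glycome classes, run the gender-balanced differential
#' tests, and compute single- and combined-marker ROC results. All
#' randomness flows from the configured seed, so two runs with the same
#' configuration produce identical numeric outputs. When `out_dir` is
#' given, the documented CSV artifacts plus a JSON manifest (seed, config
#' hash, package version) are written there.
#'
#' @param config Run configuration from [default_run_config()].
#' @param out_dir Optional output directory (created if missing).
#' @param write_chromatograms Also write per-patient chromatogram fixture
#'   CSVs (large; off by default).
#' @return A list with `targets`, `cohort`, `quant` (`quant_table`),
#'   `rel` (`rel_abundance_table`), `class_summary`, `tests`,
#'   `roc_single`, `roc_combined`, `pca` (per site), `subsets`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL,
                         write_chromatograms = FALSE) {
  targets <- build_target_list(isomer_spacing = config$cohort$isomer_spacing)
  cohort <- generate_cohort(config$cohort, targets)
  quant <- quantify_cohort(cohort, config$quant)
  rel <- normalize_by_site(quant)
  patients <- cohort$patients

  class_summary <- do.call(rbind, lapply(unique(targets$site_id), function(s)
    glycome_class_summary(rel, patients, s)))
  subsets <- gender_balanced_subsets(patients, config$stats)
  tests <- differential_tests(rel, patients, subsets, config$stats)

  labels <- patients$group[match(rownames(rel$values),
                                 patients$patient_id)] == "HCC"
  afp <- patients$afp_ng_ml[match(rownames(rel$values),
                                  patients$patient_id)]
  roc_single <- list(AFP = roc_auc(log(afp), labels, config$stats))
  sig <- tests$summary$feature[tests$summary$significant]
  for (f in sig) {
    roc_single[[f]] <- roc_auc(rel$values[, f], labels, config$stats)
  }
  roc_combined <- NULL
  if (length(sig)) {
    feat <- cbind(afp = afp, rel$values[, sig, drop = FALSE])
    roc_combined <- combine_markers(feat, labels, config$stats)
  }
  pca <- lapply(stats::setNames(nm = unique(targets$site_id)), function(s)
    pca_scores(rel$values[, rel$columns$site_id == s, drop = FALSE],
               config$stats))

  result <- list(targets = targets, cohort = cohort, quant = quant,
                 rel = rel, class_summary = class_summary, tests = tests,
                 roc_single = roc_single, roc_combined = roc_combined,
                 pca = pca, subsets = subsets)
  if (!is.null(out_dir)) {
    write_pipeline_artifacts(result, config, out_dir, write_chromatograms)
  }
  result
}

write_pipeline_artifacts <- function(result, config, out_dir,
                                     write_chromatograms = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_transition_csv(result$targets, fp("transitions.csv"),
                       rt_window = config$quant$rt_window)
  write_cohort_metadata(result$cohort$patients, fp("cohort_metadata.csv"))
  write_value_table_csv(result$quant, fp("peak_areas.csv"))
  write_value_table_csv(result$rel, fp("relative_abundance.csv"))
  utils::write.csv(result$class_summary, fp("class_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(result$tests$per_subset, fp("tests_per_subset.csv"),
                   row.names = FALSE)
  utils::write.csv(result$tests$summary, fp("tests_summary.csv"),
                   row.names = FALSE)
  roc_df <- do.call(rbind, lapply(names(result$roc_single), function(nm) {
    r <- result$roc_single[[nm]]
    data.frame(marker = nm, auc = r$auc, ci_low = r$ci_low,
               ci_high = r$ci_high, stringsAsFactors = FALSE)
  }))
  if (!is.null(result$roc_combined)) {
    r <- result$roc_combined$roc
    roc_df <- rbind(roc_df, data.frame(
      marker = "AFP + significant glycopeptides", auc = r$auc,
      ci_low = r$ci_low, ci_high = r$ci_high, stringsAsFactors = FALSE))
  }
  utils::write.csv(roc_df, fp("roc.csv"), row.names = FALSE)
  if (write_chromatograms) {
    dir.create(fp("chromatograms"), showWarnings = FALSE)
    for (pid in result$cohort$patients$patient_id) {
      cs <- render_patient(result$cohort, config$cohort, pid)
      write_chromatograms_csv(cs, fp("chromatograms",
                                     paste0(pid, ".csv")))
    }
  }
  write_run_config(config, fp("run_config.yaml"))
  manifest <- list(
    seed = config$seed,
    config_sha1 = config_hash(config),
    package = "glycoPRM",
    version = as.character(utils::packageVersion("glycoPRM")),
    r_version = R.version.string,
    created = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}

config_hash <- function(config) {
  raw <- config
  for (el in c("cohort", "quant", "stats")) raw[[el]] <- unclass(raw[[el]])
  # stable content hash without extra dependencies: sum of a serialized form
  txt <- yaml::as.yaml(raw, precision = 15)
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 977)) %%
            .Machine$integer.max)
}
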