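#' Write and read the transition list CSV
#'
#' One row per isomer entry: `site_id`, `peptide`, `glycan_code`,
#' `isomer_index`, `n_isomers`, `charge`, `precursor_mz`,
#' `fragment_mzs` (semicolon-joined, 4 decimals), `expected_rt_min`,
#' `rt_window_min`. m/z values are monoisotopic and serialized at 4
#' decimals; retention times are minutes; isomer indices are 1-based.
#'
#' @param targets Target list from [build_target_list()].
#' @param path Output file.
#' @param rt_window Acquisition retention-time half-window recorded in the
#'   file, minutes.
#' @return `path`, invisibly.
#' @export
write_transition_csv <- function(targets, path, rt_window = 3) {
  df <- data.frame(
    site_id = targets$site_id,
    peptide = targets$peptide,
    glycan_code = targets$glycan_code,
    isomer_index = targets$isomer_index,
    n_isomers = targets$n_isomers,
    charge = targets$charge,
    precursor_mz = sprintf("%.4f", targets$precursor_mz),
    fragment_mzs = vapply(targets$fragment_mzs, function(z)
      paste(sprintf("%.4f", z), collapse = ";"), character(1)),
    expected_rt_min = targets$expected_rt,
    rt_window_min = rt_window,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transition_csv
#' @return For `read_transition_csv`: a target-list data.frame in the
#'   layout of [build_target_list()] (glycan composition columns and keys
#'   reconstructed; fragment m/z values as stored).
#' @export
read_transition_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "peptide", "glycan_code", "isomer_index", "n_isomers",
            "charge", "precursor_mz", "fragment_mzs", "expected_rt_min")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("transition CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  comp <- parse_glycan_code(df$glycan_code)
  out <- data.frame(
    site_id = df$site_id, peptide = df$peptide,
    glycan_code = df$glycan_code,
    hexnac = comp$hexnac, hex = comp$hex, fuc = comp$fuc, neuac = comp$neuac,
    glycan_class = classify_glycan(comp),
    n_isomers = as.integer(df$n_isomers),
    isomer_index = as.integer(df$isomer_index),
    charge = as.integer(df$charge),
    precursor_mz = as.numeric(df$precursor_mz),
    expected_rt = df$expected_rt_min,
    stringsAsFactors = FALSE
  )
  out$fragment_mzs <- lapply(strsplit(df$fragment_mzs, ";", fixed = TRUE),
                             as.numeric)
  out$form_key <- paste(out$site_id, out$glycan_code, sep = "|")
  out$target_key <- paste(out$form_key, out$isomer_index, sep = "|")
  out[c("target_key", "form_key", "site_id", "peptide", "glycan_code",
        "hexnac", "hex", "fuc", "neuac", "glycan_class", "n_isomers",
        "isomer_index", "charge", "precursor_mz", "expected_rt",
        "fragment_mzs")]
}

#' Write and read the per-patient chromatogram fixture CSV
#'
#' Long portable format, one row per (trace, time point): `time_min`,
#' `fragment_mz`, `intensity`, `target_key` (the `"site|code"` glycoform
#' key owning the trace), `fragment_label`. Intensities must be
#' non-negative; violations are reported with their row coordinates.
#'
#' @param chromset A `chromatogram_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_chromatograms_csv <- function(chromset, path) {
  stopifnot(inherits(chromset, "chromatogram_set"))
  tr <- chromset$traces
  n_t <- length(chromset$time)
  df <- data.frame(
    time_min = rep(chromset$time, times = nrow(tr)),
    fragment_mz = rep(sprintf("%.4f", tr$fragment_mz), each = n_t),
    intensity = as.vector(chromset$intensity),
    target_key = rep(tr$form_key, each = n_t),
    fragment_label = rep(tr$fragment_label, each = n_t),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chromatograms_csv
#' @param patient_id Patient id to attach to the reconstructed set.
#' @return For `read_chromatograms_csv`: a `chromatogram_set`.
#' @export
read_chromatograms_csv <- function(path, patient_id = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(fragment_mz = "character"))
  need <- c("time_min", "fragment_mz", "intensity", "target_key")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("chromatogram fixture is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  bad <- which(df$intensity < 0 | is.na(df$intensity))
  if (length(bad)) {
    stop("invalid intensity at row ", bad[1] + 1L, ", column 'intensity' of ",
         path, " (", df$intensity[bad[1]], ")")
  }
  if (!"fragment_label" %in% names(df)) df$fragment_label <- df$fragment_mz
  key <- paste(df$target_key, df$fragment_label, sep = "|")
  ukey <- unique(key)
  time <- sort(unique(df$time_min))
  intensity <- matrix(NA_real_, length(time), length(ukey),
                      dimnames = list(NULL, ukey))
  for (k in ukey) {
    sub <- df[key == k, , drop = FALSE]
    intensity[match(sub$time_min, time), k] <- sub$intensity
  }
  if (anyNA(intensity)) {
    stop("chromatogram fixture ", path, " has traces on inconsistent ",
         "time grids")
  }
  first <- df[match(ukey, key), , drop = FALSE]
  code <- sub("^[^|]+\\|", "", first$target_key)
  traces <- data.frame(
    trace_id = ukey,
    form_key = first$target_key,
    site_id = sub("\\|.*$", "", first$target_key),
    glycan_code = code,
    fragment_label = first$fragment_label,
    fragment_mz = as.numeric(first$fragment_mz),
    stringsAsFactors = FALSE
  )
  structure(list(patient_id = patient_id, time = time,
                 intensity = intensity, traces = traces),
            class = "chromatogram_set")
}

#' Cohort metadata CSV
#'
#' Columns `patient_id`, `group`, `gender`, `afp_ng_ml`, `tnm_stage`
#' (empty for cirrhosis patients).
#'
#' @param patients Patient data.frame (from [generate_cohort()]).
#' @param path File path.
#' @return `path` invisibly; `read_cohort_metadata` returns the
#'   data.frame.
#' @export
write_cohort_metadata <- function(patients, path) {
  df <- patients[c("patient_id", "group", "gender", "afp_ng_ml", "tnm_stage")]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_metadata
#' @export
read_cohort_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("patient_id", "group", "gender", "afp_ng_ml", "tnm_stage")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("cohort metadata is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  bad <- which(!(is.na(df$tnm_stage) == (df$group == "cirrhosis")))
  if (length(bad)) {
    stop("cohort metadata row ", bad[1] + 1L, ": tnm_stage must be empty ",
         "exactly for cirrhosis patients")
  }
  df
}

#' Write a patients-by-entries value table as CSV
#'
#' Used for both peak-area (`quant_table`) and relative-abundance
#' (`rel_abundance_table`) matrices: first column `patient_id`, one column
#' per isomer entry key (`site|code|isomer`). Areas and abundances are
#' written at full precision.
#'
#' @param x A `quant_table` or `rel_abundance_table`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_value_table_csv <- function(x, path) {
  m <- if (inherits(x, "rel_abundance_table")) x$values else x$areas
  df <- data.frame(patient_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_value_table_csv
#' @return For `read_value_table_csv`: a numeric matrix with patient-id
#'   rownames.
#' @export
read_value_table_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$patient_id
  m
}

#' Run configuration file
#'
#' The full pipeline configuration (cohort model, quantitation parameters,
#' statistics settings, seed) round-trips losslessly through a single YAML
#' file. Acquisition metadata (collision energy 25 eV, the 100-min LC
#' gradient) is carried as provenance only.
#'
#' @param config A list as produced by [default_run_config()].
#' @param path YAML file path.
#' @return `path` invisibly; `read_run_config` returns the configuration
#'   list with class attributes restored.
#' @export
write_run_config <- function(config, path) {
  raw <- config
  for (el in c("cohort", "quant", "stats")) raw[[el]] <- unclass(raw[[el]])
  # yaml drops names of atomic vectors; store named vectors as maps
  yamlify <- function(x) {
    if (is.list(x)) lapply(x, yamlify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(yamlify(raw), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  config <- raw
  config$cohort <- do.call(cohort_config, simplify_cfg(raw$cohort))
  config$quant <- do.call(quant_params, raw$quant)
  config$stats <- do.call(stats_config, raw$stats)
  config
}

simplify_cfg <- function(cc) {
  # yaml reads named numeric vectors back as lists; restore vectors
  cc$gender_counts <- lapply(cc$gender_counts, unlist)
  cc$tnm_proportions <- unlist(cc$tnm_proportions)
  cc$afp_median <- unlist(cc$afp_median)
  cc$class_means <- lapply(cc$class_means, function(s) lapply(s, unlist))
  cc$effect_weights <- lapply(cc$effect_weights, unlist)
  cc$time_range <- unlist(cc$time_range)
  cc$fragment_split <- unlist(cc$fragment_split)
  cc
}

#' Default pipeline run configuration
#'
#' @param seed Master seed for the run.
#' @return A list with elements `cohort` ([cohort_config()]), `quant`
#'   ([quant_params()]), `stats` ([stats_config()]), `seed`, and
#'   `acquisition` provenance (collision energy, gradient note).
#' @export
default_run_config <- function(seed = 1L) {
  list(
    cohort = cohort_config(seed = seed),
    quant = quant_params(),
    stats = stats_config(subset_seed = seed),
    seed = as.integer(seed),
    acquisition = list(collision_energy_ev = 25,
                       gradient = "100-min C18 nano-LC gradient, 60 C")
  )
}
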