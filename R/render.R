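#' Render PRM fragment chromatograms for a synthetic cohort
#'
#' For every isomer entry and each of its six quantifier fragments, renders
#' a Gaussian elution peak at the isomer's expected retention time with
#' peak height `total_scale * abundance * fragment_split / (sigma *
#' sqrt(2*pi))` (so the peak area is `total_scale * abundance *
#' fragment_split`), on a shared time grid, plus an additive baseline and
#' multiplicative intensity noise. Traces are stored per (glycoform,
#' fragment), mirroring PRM acquisition where each precursor has its own
#' MS2 fragment traces: glycoforms that share fragment m/z values never mix.
#'
#' @param cohort A [generate_cohort()] result.
#' @param config The cohort's [cohort_config()] (defaults to
#'   `cohort$config`).
#' @param patient_ids Patients to render (default all).
#' @return Named list of `chromatogram_set` objects, one per patient: each
#'   has `time` (minutes), `intensity` (matrix time x traces) and `traces`
#'   (data.frame `trace_id`, `form_key`, `site_id`, `glycan_code`,
#'   `fragment_label`, `fragment_mz`).
#' @export
render_chromatograms <- function(cohort, config = cohort$config,
                                 patient_ids = NULL) {
  stopifnot(inherits(cohort, "glyco_cohort"))
  if (is.null(patient_ids)) patient_ids <- cohort$patients$patient_id
  out <- lapply(patient_ids, function(pid) render_patient(cohort, config, pid))
  names(out) <- patient_ids
  out
}

render_patient <- function(cohort, config, patient_id) {
  p <- match(patient_id, cohort$patients$patient_id)
  if (is.na(p)) stop("unknown patient: ", patient_id)
  targets <- cohort$targets
  time <- seq(config$time_range[1], config$time_range[2],
              by = config$sampling_interval)
  split <- config$fragment_split

  forms <- targets[!duplicated(targets$form_key), , drop = FALSE]
  n_frag <- lengths(forms$fragment_mzs)
  traces <- data.frame(
    trace_id = paste(rep(forms$form_key, n_frag),
                     unlist(lapply(forms$fragment_mzs, names)), sep = "|"),
    form_key = rep(forms$form_key, n_frag),
    site_id = rep(forms$site_id, n_frag),
    glycan_code = rep(forms$glycan_code, n_frag),
    fragment_label = unlist(lapply(forms$fragment_mzs, names)),
    fragment_mz = unlist(forms$fragment_mzs),
    stringsAsFactors = FALSE
  )
  rownames(traces) <- NULL

  sigma <- config$peak_sigma
  height0 <- config$total_scale / (sigma * sqrt(2 * pi))
  intensity <- matrix(0, length(time), nrow(traces),
                      dimnames = list(NULL, traces$trace_id))
  # signal: loop isomer entries, add Gaussians into the form's fragment cols
  first_col <- match(paste(forms$form_key,
                           vapply(forms$fragment_mzs,
                                  function(z) names(z)[1], character(1)),
                           sep = "|"), traces$trace_id)
  names(first_col) <- forms$form_key
  for (e in seq_len(nrow(targets))) {
    a <- cohort$truth[p, targets$target_key[e]]
    if (a <= 0) next
    rt <- targets$expected_rt[e]
    lo <- max(1L, findInterval(rt - 8 * sigma, time))
    hi <- min(length(time), findInterval(rt + 8 * sigma, time) + 1L)
    if (hi < lo) next
    g <- exp(-((time[lo:hi] - rt)^2) / (2 * sigma^2))
    cols <- first_col[[targets$form_key[e]]] +
      seq_len(n_frag[match(targets$form_key[e], forms$form_key)]) - 1L
    for (j in seq_along(cols)) {
      intensity[lo:hi, cols[j]] <- intensity[lo:hi, cols[j]] +
        height0 * a * split[j] * g
    }
  }

  set.seed(cohort$patients$render_seed[p])
  intensity <- intensity + config$baseline
  if (config$noise_sd > 0) {
    intensity <- intensity *
      pmax(0, 1 + stats::rnorm(length(intensity), 0, config$noise_sd))
  }

  structure(
    list(patient_id = patient_id, time = time, intensity = intensity,
         traces = traces),
    class = "chromatogram_set"
  )
}

#' @exportS3Method base::print
print.chromatogram_set <- function(x, ...) {
  cat("PRM chromatogram set for", x$patient_id, "-", ncol(x$intensity),
      "fragment traces x", length(x$time), "time points (",
      min(x$time), "-", max(x$time), "min )\n")
  invisible(x)
}
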