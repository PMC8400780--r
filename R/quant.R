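#' Quantitation parameters
#'
#' Desk equivalents of the PRM acquisition and peak-picking settings: a
#' +/-3 min retention-time window and +/-2 Da precursor mass range (the
#' precursor range is acquisition provenance, recorded but not used when
#' quantifying rendered traces), 10 ppm fragment m/z matching, and the
#' peak boundary convention (split at the valley between apexes, otherwise
#' stop where the signal falls to 1 percent of the apex above the local
#' baseline floor).
#'
#' @param rt_window Retention-time half-window, minutes.
#' @param precursor_mass_range Precursor half-range, Da (provenance only).
#' @param fragment_ppm_tol Fragment m/z matching tolerance, ppm.
#' @param peak_min_prominence Minimum apex height as a fraction of the
#'   tallest apex in the extracted window.
#' @param min_isomer_separation Minimum apex separation, minutes; closer
#'   local maxima are merged into the taller one.
#' @param boundary_apex_frac Boundary threshold as a fraction of apex
#'   height above the trace floor.
#' @param smooth_points Odd number of points for the moving-average
#'   smoother applied before apex detection (integration always uses the
#'   raw trace).
#' @return A list of class `quant_params`.
#' @export
quant_params <- function(rt_window = 3, precursor_mass_range = 2,
                         fragment_ppm_tol = 10, peak_min_prominence = 0.05,
                         min_isomer_separation = 0.8,
                         boundary_apex_frac = 0.01, smooth_points = 5L) {
  stopifnot(rt_window > 0, precursor_mass_range > 0, fragment_ppm_tol > 0,
            peak_min_prominence > 0, min_isomer_separation > 0,
            boundary_apex_frac > 0, smooth_points >= 1)
  structure(
    list(rt_window = rt_window, precursor_mass_range = precursor_mass_range,
         fragment_ppm_tol = fragment_ppm_tol,
         peak_min_prominence = peak_min_prominence,
         min_isomer_separation = min_isomer_separation,
         boundary_apex_frac = boundary_apex_frac,
         smooth_points = as.integer(smooth_points)),
    class = "quant_params"
  )
}

new_eic <- function(time, intensity, mz, missing = FALSE) {
  structure(list(time = time, intensity = intensity, mz = mz,
                 missing = missing), class = "eic")
}

#' Extract a fragment ion chromatogram
#'
#' Restricts the stored traces to `expected_rt +/- rt_window` (or an
#' explicit `window`), summing every trace whose fragment m/z lies within
#' `fragment_ppm_tol` of the target m/z. In PRM each precursor owns its
#' fragment traces, so matching is confined to one glycoform's trace group
#' when `form_key` is given.
#'
#' @param chromset A `chromatogram_set` from [render_chromatograms()] or
#'   [read_chromatograms_csv()].
#' @param mz Target fragment m/z.
#' @param params [quant_params()].
#' @param expected_rt Window center, minutes (ignored if `window` given).
#' @param form_key Optional `"site|code"` key restricting the trace group.
#' @param window Optional explicit `c(start, end)` window, minutes.
#' @return An `eic` object: `time`, `intensity`, `mz`, and a `missing`
#'   flag set when no stored trace matches the target m/z.
#' @export
extract_eic <- function(chromset, mz, params = quant_params(),
                        expected_rt = NULL, form_key = NULL, window = NULL) {
  stopifnot(inherits(chromset, "chromatogram_set"))
  if (is.null(window)) {
    if (is.null(expected_rt)) stop("either expected_rt or window is required")
    window <- expected_rt + c(-1, 1) * params$rt_window
  }
  sel_t <- chromset$time >= window[1] & chromset$time <= window[2]
  tr <- chromset$traces
  cand <- if (is.null(form_key)) seq_len(nrow(tr)) else
    which(tr$form_key == form_key)
  hit <- cand[abs(tr$fragment_mz[cand] - mz) / mz * 1e6 <=
                params$fragment_ppm_tol]
  if (!length(hit)) {
    return(new_eic(chromset$time[sel_t], rep(0, sum(sel_t)), mz,
                   missing = TRUE))
  }
  y <- rowSums(chromset$intensity[sel_t, hit, drop = FALSE])
  new_eic(chromset$time[sel_t], y, mz)
}

running_mean <- function(y, k) {
  if (k <= 1L || length(y) < k) return(y)
  f <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  na <- is.na(f)
  f[na] <- y[na]
  f
}

#' Detect isomer peaks in a composite EIC
#'
#' Local maxima above `peak_min_prominence` of the tallest apex (after
#' light smoothing), merged within `min_isomer_separation`, indexed 1..k by
#' ascending apex retention time. Peak boundaries follow the
#' valley-or-1-percent-of-apex rule: adjacent peaks split at the
#' inter-apex valley; outer bounds stop where the trace falls to
#' `boundary_apex_frac` of the apex height above the trace floor.
#'
#' @param eic An `eic` (typically the pointwise sum of a target's six
#'   fragment EICs).
#' @param params [quant_params()].
#' @return A data.frame with columns `isomer_index`, `apex_rt`,
#'   `apex_intensity`, `left`, `right` (boundary times); zero rows when the
#'   trace carries no detectable peak.
#' @export
detect_isomer_peaks <- function(eic, params = quant_params()) {
  y <- running_mean(eic$intensity, params$smooth_points)
  n <- length(y)
  empty <- data.frame(isomer_index = integer(0), apex_rt = numeric(0),
                      apex_intensity = numeric(0), left = numeric(0),
                      right = numeric(0))
  if (n < 3L || max(y) <= 0) return(empty)
  thr <- params$peak_min_prominence * max(y)
  is_max <- c(FALSE, y[2:(n - 1)] >= y[1:(n - 2)] &
                y[2:(n - 1)] > y[3:n], FALSE)
  cand <- which(is_max & y >= thr)
  if (!length(cand)) return(empty)
  # merge maxima closer than min_isomer_separation, keeping the taller
  keep <- integer(0)
  for (i in cand[order(y[cand], decreasing = TRUE)]) {
    if (!length(keep) ||
        all(abs(eic$time[i] - eic$time[keep]) >=
              params$min_isomer_separation)) {
      keep <- c(keep, i)
    }
  }
  apex <- sort(keep)
  floor_y <- min(y)

  k <- length(apex)
  left_idx <- right_idx <- integer(k)
  for (j in seq_len(k)) {
    th <- floor_y + params$boundary_apex_frac * (y[apex[j]] - floor_y)
    # valley limits toward the neighboring apexes
    llim <- if (j > 1L) {
      (apex[j - 1L]:apex[j])[which.min(y[apex[j - 1L]:apex[j]])]
    } else 1L
    rlim <- if (j < k) {
      (apex[j]:apex[j + 1L])[which.min(y[apex[j]:apex[j + 1L]])]
    } else n
    below <- which(y[llim:apex[j]] <= th)
    left_idx[j] <- if (length(below)) llim + max(below) - 1L else llim
    below <- which(y[apex[j]:rlim] <= th)
    right_idx[j] <- if (length(below)) apex[j] + min(below) - 1L else rlim
  }
  data.frame(
    isomer_index = seq_len(k),
    apex_rt = eic$time[apex],
    apex_intensity = eic$intensity[apex],
    left = eic$time[left_idx],
    right = eic$time[right_idx]
  )
}

#' Integrate a peak with local linear baseline subtraction
#'
#' Trapezoidal integral of intensity minus the chord drawn between the
#' boundary intensities (Xcalibur-style local baseline), floored at zero.
#' Boundary intensities are linearly interpolated, so bounds need not fall
#' on grid points.
#'
#' @param eic An `eic`.
#' @param bounds `c(left, right)` boundary times, minutes.
#' @return Peak area, intensity x minutes.
#' @export
integrate_peak <- function(eic, bounds) {
  if (length(bounds) != 2L || bounds[1] >= bounds[2]) {
    stop("bounds must be c(left, right) with left < right")
  }
  t0 <- eic$time
  inside <- t0 > bounds[1] & t0 < bounds[2]
  yl <- stats::approx(t0, eic$intensity, bounds[1], rule = 2)$y
  yr <- stats::approx(t0, eic$intensity, bounds[2], rule = 2)$y
  tt <- c(bounds[1], t0[inside], bounds[2])
  yy <- c(yl, eic$intensity[inside], yr)
  base <- yl + (yr - yl) * (tt - bounds[1]) / (bounds[2] - bounds[1])
  d <- yy - base
  area <- sum(diff(tt) * (d[-1] + d[-length(d)]) / 2)
  max(area, 0)
}

#' Quantify one glycoform target across its isomers
#'
#' Builds the composite EIC (pointwise sum of the target's six fragment
#' EICs over the window spanning all expected isomer retention times),
#' detects isomer peaks, and integrates each on the composite. Isomer
#' identity is assigned by retention-time order (isomer 1 elutes first);
#' when more apexes are detected than `n_isomers` the tallest are kept and
#' the extras logged, and when fewer are detected each peak is matched to
#' its nearest expected retention time, with undetected isomers reported
#' as zero area and flagged - never dropped.
#'
#' @param chromset A `chromatogram_set`.
#' @param target_rows The target-list rows of one glycoform (all isomer
#'   entries of a single `form_key`).
#' @param params [quant_params()].
#' @return A data.frame with one row per expected isomer: `target_key`,
#'   `isomer_index`, `area`, `apex_rt` (`NA` when undetected) and `flag`
#'   (`"ok"`, `"not_detected"`, `"missing_traces"`, or
#'   `"extra_peaks:<n>"`).
#' @export
quantify_target <- function(chromset, target_rows, params = quant_params()) {
  stopifnot(nrow(target_rows) >= 1L,
            length(unique(target_rows$form_key)) == 1L)
  target_rows <- target_rows[order(target_rows$isomer_index), , drop = FALSE]
  n_iso <- target_rows$n_isomers[1]
  window <- c(min(target_rows$expected_rt) - params$rt_window,
              max(target_rows$expected_rt) + params$rt_window)
  frag <- target_rows$fragment_mzs[[1]]
  eics <- lapply(frag, function(mz)
    extract_eic(chromset, mz, params, form_key = target_rows$form_key[1],
                window = window))
  if (all(vapply(eics, function(e) e$missing, logical(1)))) {
    return(data.frame(target_key = target_rows$target_key,
                      isomer_index = target_rows$isomer_index,
                      area = 0, apex_rt = NA_real_,
                      flag = "missing_traces", stringsAsFactors = FALSE))
  }
  composite <- new_eic(eics[[1]]$time,
                       Reduce(`+`, lapply(eics, `[[`, "intensity")),
                       mz = NA_real_)
  peaks <- detect_isomer_peaks(composite, params)

  out <- data.frame(target_key = target_rows$target_key,
                    isomer_index = target_rows$isomer_index,
                    area = 0, apex_rt = NA_real_, flag = "not_detected",
                    stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L) return(out)

  extra <- nrow(peaks) - n_iso
  if (extra > 0L) {
    keep <- order(peaks$apex_intensity, decreasing = TRUE)[seq_len(n_iso)]
    peaks <- peaks[sort(keep), , drop = FALSE]
  }
  # assign detected peaks to expected isomer slots
  if (nrow(peaks) == n_iso) {
    slot <- seq_len(n_iso)
  } else {
    slot <- integer(nrow(peaks))
    free <- seq_len(n_iso)
    for (j in seq_len(nrow(peaks))) {
      pick <- free[which.min(abs(target_rows$expected_rt[free] -
                                   peaks$apex_rt[j]))]
      slot[j] <- pick
      free <- setdiff(free, pick)
    }
  }
  for (j in seq_len(nrow(peaks))) {
    i <- slot[j]
    out$area[i] <- integrate_peak(composite,
                                  c(peaks$left[j], peaks$right[j]))
    out$apex_rt[i] <- peaks$apex_rt[j]
    out$flag[i] <- if (extra > 0L) paste0("extra_peaks:", extra) else "ok"
  }
  out
}

#' Build the per-patient quantitation table
#'
#' Runs [quantify_target()] for every glycoform and patient, assembling
#' the complete patients x isomer-entries peak-area matrix together with
#' apex retention times and per-cell flags. Deterministic given its
#' inputs; the patient order of `chromsets` does not affect contents.
#'
#' @param chromsets Named list of `chromatogram_set` objects (names =
#'   patient ids).
#' @param targets Target list from [build_target_list()].
#' @param params [quant_params()].
#' @return A list of class `quant_table`: `areas` and `apex_rt` (matrices
#'   patients x isomer entries), `flags` (character matrix), `columns`
#'   (target metadata: `target_key`, `site_id`, `glycan_code`,
#'   `glycan_class`, `isomer_index`).
#' @export
build_quant_table <- function(chromsets, targets, params = quant_params()) {
  pids <- sort(names(chromsets))
  columns <- targets[c("target_key", "form_key", "site_id", "glycan_code",
                       "glycan_class", "isomer_index")]
  areas <- matrix(NA_real_, length(pids), nrow(targets),
                  dimnames = list(pids, targets$target_key))
  apex <- areas
  flags <- matrix(NA_character_, length(pids), nrow(targets),
                  dimnames = dimnames(areas))
  forms <- unique(targets$form_key)
  for (pid in pids) {
    cs <- chromsets[[pid]]
    if (!inherits(cs, "chromatogram_set")) {
      stop("chromatogram set for patient '", pid, "' is unreadable")
    }
    for (fk in forms) {
      rows <- targets[targets$form_key == fk, , drop = FALSE]
      q <- quantify_target(cs, rows, params)
      areas[pid, q$target_key] <- q$area
      apex[pid, q$target_key] <- q$apex_rt
      flags[pid, q$target_key] <- q$flag
    }
  }
  structure(list(areas = areas, apex_rt = apex, flags = flags,
                 columns = columns),
            class = "quant_table")
}

#' Render and quantify a cohort patient-by-patient
#'
#' Convenience wrapper chaining [render_chromatograms()] and
#' [build_quant_table()] one patient at a time, so only a single patient's
#' chromatograms are ever held in memory.
#'
#' @param cohort A [generate_cohort()] result.
#' @param params [quant_params()].
#' @return A `quant_table`.
#' @export
quantify_cohort <- function(cohort, params = quant_params()) {
  stopifnot(inherits(cohort, "glyco_cohort"))
  targets <- cohort$targets
  pids <- cohort$patients$patient_id
  qt <- NULL
  for (pid in pids) {
    cs <- render_patient(cohort, cohort$config, pid)
    one <- build_quant_table(stats::setNames(list(cs), pid), targets, params)
    if (is.null(qt)) {
      qt <- one
    } else {
      qt$areas <- rbind(qt$areas, one$areas)
      qt$apex_rt <- rbind(qt$apex_rt, one$apex_rt)
      qt$flags <- rbind(qt$flags, one$flags)
    }
  }
  ord <- order(rownames(qt$areas))
  qt$areas <- qt$areas[ord, , drop = FALSE]
  qt$apex_rt <- qt$apex_rt[ord, , drop = FALSE]
  qt$flags <- qt$flags[ord, , drop = FALSE]
  qt
}

#' @exportS3Method base::print
print.quant_table <- function(x, ...) {
  cat("PRM quantitation table:", nrow(x$areas), "patients x",
      ncol(x$areas), "isomer entries;",
      sum(x$flags != "ok", na.rm = TRUE), "flagged cells\n")
  invisible(x)
}
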