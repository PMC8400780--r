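targets <- build_target_list()

test_that("EIC extraction clips to the window and honors ppm tolerance", {
  cfg <- fast_config(seed = 2, abundance_log_sd = 0, noise_sd = 0)
  cohort <- generate_cohort(cfg, targets)
  cs <- render_chromatograms(cohort, patient_ids = "C01")[["C01"]]
  row <- targets[targets$target_key == "Asn207|4-5-0-1|1", ]
  mz <- row$fragment_mzs[[1]][["Y1"]]
  eic <- extract_eic(cs, mz, expected_rt = row$expected_rt,
                     form_key = row$form_key)
  expect_false(eic$missing)
  expect_true(all(abs(eic$time - row$expected_rt) <= 3 + 1e-9))
  # trace identical to the stored column inside the window
  col <- cs$intensity[, paste0(row$form_key, "|Y1")]
  sel <- abs(cs$time - row$expected_rt) <= 3
  expect_identical(eic$intensity, unname(col[sel]))

  # +5 ppm matches at 10 ppm tolerance, +50 ppm does not
  eic5 <- extract_eic(cs, mz * (1 + 5e-6), expected_rt = row$expected_rt,
                      form_key = row$form_key)
  expect_false(eic5$missing)
  eic50 <- extract_eic(cs, mz * (1 + 50e-6), expected_rt = row$expected_rt,
                       form_key = row$form_key)
  expect_true(eic50$missing)
  expect_true(all(eic50$intensity == 0))
})

test_that("peak detection finds apexes and splits at valleys", {
  # single Gaussian: one peak at its mean
  one <- gaussian_eic(1000, 50)
  p1 <- detect_isomer_peaks(one)
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$apex_rt, 50, tolerance = 0.02)

  # two equal Gaussians 4 sigma apart: two peaks, valley-split at midpoint
  two <- gaussian_eic(c(1000, 1000), c(50, 51.2))
  p2 <- detect_isomer_peaks(two)
  expect_equal(nrow(p2), 2L)
  expect_equal(p2$right[1], 50.6, tolerance = 0.05)
  expect_equal(p2$left[2], 50.6, tolerance = 0.05)

  # all-flat trace: no peaks
  flat <- gaussian_eic(0, 50, baseline = 0)
  expect_equal(nrow(detect_isomer_peaks(flat)), 0L)
})

test_that("integration matches closed forms", {
  # rectangle of height h over width w with zero baseline
  t <- seq(0, 10, by = 0.01)
  y <- ifelse(t >= 2 & t <= 5, 100, 0)
  rect <- glycoPRM:::new_eic(t, y, mz = 1)
  expect_equal(integrate_peak(rect, c(1.5, 5.5)), 300, tolerance = 0.01)

  # noise-free Gaussian with +/-4 sigma bounds: A * sigma * sqrt(2*pi)
  g <- gaussian_eic(5000, 50, sigma = 0.3, by = 0.005)
  area <- integrate_peak(g, c(50 - 1.2, 50 + 1.2))
  expect_equal(area, 5000 * 0.3 * sqrt(2 * pi), tolerance = 0.005)

  # flat nonzero baseline integrates to zero after baseline subtraction
  flat <- gaussian_eic(0, 50, baseline = 200)
  expect_equal(integrate_peak(flat, c(45, 55)), 0)

  expect_error(integrate_peak(g, c(51, 50)), "left < right")
})

test_that("areas are linear in intensity and stable under grid refinement", {
  g1 <- gaussian_eic(2000, 50, by = 0.02)
  g2 <- gaussian_eic(4000, 50, by = 0.02)
  a1 <- integrate_peak(g1, c(48.5, 51.5))
  a2 <- integrate_peak(g2, c(48.5, 51.5))
  expect_equal(a2 / a1, 2, tolerance = 1e-9)
  g_fine <- gaussian_eic(2000, 50, by = 0.01)
  expect_equal(integrate_peak(g_fine, c(48.5, 51.5)), a1, tolerance = 0.005)
})

test_that("quantify_target reports per-isomer areas against truth", {
  cfg <- fast_config(seed = 3, abundance_log_sd = 0, noise_sd = 0)
  cohort <- generate_cohort(cfg, targets)
  cs <- render_chromatograms(cohort, patient_ids = "H01")[["H01"]]
  rows <- targets[targets$form_key == "Asn207|5-6-0-3", ]
  q <- quantify_target(cs, rows)
  expect_equal(q$isomer_index, 1:3)
  truth <- cohort$truth["H01", rows$target_key]
  # proportional to generator truth within 1 percent
  ratio <- q$area / (cfg$total_scale * truth)
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 0.01)
  expect_true(all(q$flag == "ok"))

  # doubling every fragment intensity doubles every area
  cs2 <- cs
  cs2$intensity <- cs$intensity * 2
  q2 <- quantify_target(cs2, rows)
  expect_equal(q2$area, 2 * q$area, tolerance = 1e-6)
})

test_that("extra apexes beyond n_isomers keep the tallest and are logged", {
  rows <- targets[targets$form_key == "Asn184|4-5-1-1", ]
  stopifnot(nrow(rows) == 1L)
  # synthesize a chromatogram with TWO apexes for this 1-isomer target
  t <- seq(40, 60, by = 0.01)
  y <- 3000 * exp(-((t - rows$expected_rt)^2) / (2 * 0.3^2)) +
    1500 * exp(-((t - rows$expected_rt - 2)^2) / (2 * 0.3^2))
  frag <- rows$fragment_mzs[[1]]
  cs <- structure(list(
    patient_id = "X", time = t,
    intensity = matrix(rep(y / 6, 6), ncol = 6,
                       dimnames = list(NULL, paste0(rows$form_key, "|",
                                                    names(frag)))),
    traces = data.frame(
      trace_id = paste0(rows$form_key, "|", names(frag)),
      form_key = rows$form_key, site_id = rows$site_id,
      glycan_code = rows$glycan_code, fragment_label = names(frag),
      fragment_mz = unname(frag), stringsAsFactors = FALSE)),
    class = "chromatogram_set")
  q <- quantify_target(cs, rows)
  expect_equal(nrow(q), 1L)
  expect_equal(q$apex_rt, rows$expected_rt, tolerance = 0.05) # taller apex
  expect_match(q$flag, "extra_peaks:1")
})

test_that("missing fragment traces give zero areas with a flag", {
  cfg <- fast_config(seed = 3, abundance_log_sd = 0, noise_sd = 0)
  cohort <- generate_cohort(cfg, targets)
  cs <- render_chromatograms(cohort, patient_ids = "C01")[["C01"]]
  rows <- targets[targets$form_key == "Asn207|5-6-0-3", ]
  cs$traces$fragment_mz[cs$traces$form_key == rows$form_key[1]] <- 1.0
  q <- quantify_target(cs, rows)
  expect_true(all(q$area == 0))
  expect_true(all(q$flag == "missing_traces"))
})

test_that("the quant table has full shape and is order-invariant", {
  cfg <- fast_config(seed = 12)
  cohort <- generate_cohort(cfg, targets)
  pids <- c("C01", "H02", "H05")
  chroms <- render_chromatograms(cohort, patient_ids = pids)
  qt <- build_quant_table(chroms, targets)
  expect_s3_class(qt, "quant_table")
  expect_equal(dim(qt$areas), c(3L, 72L))
  expect_true(all(qt$areas >= 0))
  qt_rev <- build_quant_table(rev(chroms), targets)
  expect_identical(qt$areas, qt_rev$areas)

  expect_error(build_quant_table(list(C01 = "nope"), targets), "unreadable")
})

test_that("quantify-normalize on a noise-free cohort recovers truth", {
  cfg <- fast_config(seed = 10, abundance_log_sd = 0, noise_sd = 0)
  cohort <- generate_cohort(cfg, targets)
  cohort$patients <- cohort$patients[1:4, ]
  cohort$truth <- cohort$truth[1:4, , drop = FALSE]
  qt <- quantify_cohort(cohort)
  rel <- normalize_by_site(qt)
  rel_err <- abs(rel$values / cohort$truth - 1)
  expect_lt(max(rel_err), 0.01)
})
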