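# Shared fixtures: independent mass oracle and fast configurations.

# Independent residue-sum oracle for mass tests, written directly from
# standard monoisotopic tables (kept separate from the package's constants
# on purpose).
oracle_masses <- list(
  aa = c(A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694,
         C = 103.00919, E = 129.04259, Q = 128.05858, G = 57.02146,
         H = 137.05891, I = 113.08406, L = 113.08406, K = 128.09496,
         M = 131.04049, F = 147.06841, P = 97.05276, S = 87.03203,
         T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841),
  hexnac = 203.07937, hex = 162.05282, fuc = 146.05791, neuac = 291.09542,
  water = 18.010565, proton = 1.007276
)

oracle_peptide_mass <- function(seq) {
  sum(oracle_masses$aa[strsplit(seq, "")[[1]]]) + oracle_masses$water
}

oracle_glycan_mass <- function(n, h, f, s) {
  n * oracle_masses$hexnac + h * oracle_masses$hex +
    f * oracle_masses$fuc + s * oracle_masses$neuac
}

ppm_diff <- function(a, b) abs(a - b) / b * 1e6

# Coarser time grid for rendering-heavy tests; every other default kept.
fast_config <- function(seed = 1L, sampling_interval = 0.05, ...) {
  cohort_config(seed = seed, sampling_interval = sampling_interval, ...)
}

# Wrap a truth matrix as a rel_abundance_table so the statistics layer can
# be exercised directly against generator ground truth.
truth_as_rel <- function(cohort) {
  structure(
    list(values = cohort$truth,
         columns = cohort$targets[c("target_key", "form_key", "site_id",
                                    "glycan_code", "glycan_class",
                                    "isomer_index")],
         flags = NULL),
    class = "rel_abundance_table"
  )
}

# Single synthetic Gaussian trace as an eic.
gaussian_eic <- function(amps, rts, sigma = 0.3, from = 40, to = 60,
                         by = 0.01, baseline = 0) {
  t <- seq(from, to, by = by)
  y <- rep(baseline, length(t))
  for (i in seq_along(amps)) {
    y <- y + amps[i] * exp(-((t - rts[i])^2) / (2 * sigma^2))
  }
  glycoPRM:::new_eic(t, y, mz = 1000)
}
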