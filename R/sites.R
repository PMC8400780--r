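#' Haptoglobin glycosylation sites
#'
#' The three tryptic/Glu-C site peptides of serum haptoglobin that the
#' targeted assay monitors, with their monoisotopic peptide masses and the
#' chromatographic elution windows within which their glycoforms elute
#' (Asn184: 42-54 min, Asn207: 40-60 min, Asn241: 61-88 min). The fourth
#' site (Asn211) is not covered by the assay.
#'
#' @return A data.frame with columns `site_id`, `peptide`,
#'   `peptide_mass` (Da), `window_start`, `window_end` (minutes).
#' @examples
#' glyco_sites()
#' @export
glyco_sites <- function() {
  sites <- data.frame(
    site_id = c("Asn184", "Asn207", "Asn241"),
    peptide = c("MVSHHNLTTGATLINE", "NLFLNHSE", "VVLHPNYSQVDIGLIK"),
    window_start = c(42, 40, 61),
    window_end   = c(54, 60, 88),
    stringsAsFactors = FALSE
  )
  sites$peptide_mass <- vapply(sites$peptide, peptide_mass, numeric(1))
  sites[c("site_id", "peptide", "peptide_mass", "window_start", "window_end")]
}

site_info <- function(site_id) {
  sites <- glyco_sites()
  i <- match(site_id, sites$site_id)
  if (anyNA(i)) {
    stop("unknown glycosylation site(s): ",
         paste(site_id[is.na(i)], collapse = ", "))
  }
  sites[i, , drop = FALSE]
}

#' Precursor m/z of a glycopeptide
#'
#' `(peptide_mass + glycan_mass + charge * proton) / charge` on the
#' monoisotopic scale.
#'
#' @param site_id One of `"Asn184"`, `"Asn207"`, `"Asn241"`.
#' @param comp Glycan composition (code string, length-4 vector, or
#'   composition data.frame).
#' @param charge Positive integer charge state.
#' @return Precursor m/z.
#' @examples
#' precursor_mz("Asn207", "5-6-0-3", 3) # 1278.8295
#' @export
precursor_mz <- function(site_id, comp, charge) {
  if (!is.numeric(charge) || any(charge < 1) || any(charge != round(charge))) {
    stop("charge must be a positive integer")
  }
  if (is.character(comp)) comp <- parse_glycan_code(comp)
  pep <- site_info(site_id)$peptide_mass
  (pep + glycan_mass(comp) + charge * .glyco_masses$proton) / charge
}

#' Glycopeptide Y-ion series and oxonium marker ions
#'
#' Builds the singly protonated Y-ion ladder used for PRM quantitation:
#' Y0 (bare peptide), Y1 (peptide + HexNAc), then the chitobiose/trimannosyl
#' core ladder Y1 + HexNAc, + Hex, + Hex, + Hex, + HexNAc + Hex. The six
#' ladder ions above Y0 are the default quantifier set; compositions too
#' small to supply a ladder step yield a truncated series. Standard oxonium
#' ions (HexNAc, Neu5Ac and their water losses) are appended for residues
#' present in the composition, flagged as non-quantifiers.
#'
#' @inheritParams precursor_mz
#' @return A data.frame with columns `label`, `mz`, `quantifier` (logical),
#'   ordered Y0 upward then oxonium ions.
#' @examples
#' y_ion_series("Asn207", "5-6-0-3")
#' @export
y_ion_series <- function(site_id, comp) {
  if (is.character(comp)) comp <- parse_glycan_code(comp)
  comp <- as_composition(comp)
  stopifnot(nrow(comp) == 1L)
  s <- .glyco_masses$sugar
  pep <- site_info(site_id)$peptide_mass

  # ladder steps beyond Y0, with the residue budget each consumes
  steps <- data.frame(
    label = c("Y1", "Y2", "Y2+Hex", "Y2+2Hex", "Y2+3Hex", "Y3+4Hex"),
    dm = c(s[["hexnac"]], s[["hexnac"]], s[["hex"]], s[["hex"]], s[["hex"]],
           s[["hexnac"]] + s[["hex"]]),
    need_hexnac = c(1, 2, 2, 2, 2, 3),
    need_hex    = c(0, 0, 1, 2, 3, 4),
    stringsAsFactors = FALSE
  )
  keep <- steps$need_hexnac <= comp$hexnac & steps$need_hex <= comp$hex
  # ladder is cumulative: stop at the first missing step
  keep <- cumprod(keep) == 1
  mz <- pep + .glyco_masses$proton + cumsum(steps$dm)
  out <- data.frame(
    label = c("Y0", steps$label[keep]),
    mz = c(pep + .glyco_masses$proton, mz[keep]),
    quantifier = c(FALSE, rep(TRUE, sum(keep))),
    stringsAsFactors = FALSE
  )

  ox <- .oxonium_ions
  ox_keep <- c(comp$hexnac > 0, comp$hexnac > 0, comp$neuac > 0, comp$neuac > 0)
  if (any(ox_keep)) {
    out <- rbind(out, data.frame(
      label = names(ox)[ox_keep], mz = unname(ox[ox_keep]),
      quantifier = FALSE, stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  out
}
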