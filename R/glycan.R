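#' Parse a four-digit glycan composition code
#'
#' Glycan compositions are written as four dash-separated non-negative
#' integers "a-b-c-d" counting HexNAc, Hex, Fuc and Neu5Ac residues, in that
#' order (e.g. "5-6-1-3" = HexNAc5 Hex6 Fuc1 Neu5Ac3). Parsing is
#' vectorized; formatting back with [format_glycan_code()] reproduces the
#' input exactly.
#'
#' @param code Character vector of composition codes.
#' @return A data.frame with one row per code and integer columns `hexnac`,
#'   `hex`, `fuc`, `neuac`, plus the original `code`.
#' @examples
#' parse_glycan_code("5-6-1-3")
#' @export
parse_glycan_code <- function(code) {
  stopifnot(is.character(code), length(code) >= 1L)
  parts <- strsplit(code, "-", fixed = TRUE)
  rows <- lapply(seq_along(code), function(i) {
    p <- parts[[i]]
    if (length(p) != 4L) {
      stop("malformed glycan code '", code[i], "': expected 4 dash-separated ",
           "integers, got ", length(p), " token(s)")
    }
    ok <- grepl("^[0-9]+$", p)
    if (!all(ok)) {
      stop("malformed glycan code '", code[i], "': token '", p[!ok][1],
           "' is not a non-negative integer")
    }
    as.integer(p)
  })
  m <- do.call(rbind, rows)
  data.frame(
    hexnac = m[, 1], hex = m[, 2], fuc = m[, 3], neuac = m[, 4],
    code = code, stringsAsFactors = FALSE
  )
}

#' Format a glycan composition as its four-digit code
#'
#' @param comp A data.frame with columns `hexnac`, `hex`, `fuc`, `neuac`
#'   (as returned by [parse_glycan_code()]), or a numeric vector of length 4.
#' @return Character vector of "a-b-c-d" codes.
#' @export
format_glycan_code <- function(comp) {
  comp <- as_composition(comp)
  paste(comp$hexnac, comp$hex, comp$fuc, comp$neuac, sep = "-")
}

# Coerce length-4 vectors / lists to the canonical composition data.frame.
as_composition <- function(comp) {
  if (is.numeric(comp) && length(comp) == 4L) {
    comp <- data.frame(hexnac = comp[1], hex = comp[2], fuc = comp[3],
                       neuac = comp[4])
  }
  stopifnot(all(c("hexnac", "hex", "fuc", "neuac") %in% names(comp)))
  if (any(unlist(comp[c("hexnac", "hex", "fuc", "neuac")]) < 0)) {
    stop("glycan composition counts must be non-negative")
  }
  comp
}

#' Monoisotopic glycan mass
#'
#' Sum of monosaccharide residue masses for a composition; the all-zero
#' composition has mass 0 (bare peptide).
#'
#' @inheritParams format_glycan_code
#' @return Numeric vector of neutral glycan masses in Da.
#' @examples
#' glycan_mass(parse_glycan_code("5-6-0-3"))
#' @export
glycan_mass <- function(comp) {
  comp <- as_composition(comp)
  s <- .glyco_masses$sugar
  comp$hexnac * s[["hexnac"]] + comp$hex * s[["hex"]] +
    comp$fuc * s[["fuc"]] + comp$neuac * s[["neuac"]]
}

#' Classify a glycan composition into the three marker classes
#'
#' Compositions are grouped as `sialylated` (Neu5Ac present, no fucose),
#' `sialylated_fucosylated` (both present) or `other` (no Neu5Ac). This is
#' the grouping used for the per-site glycome class summaries.
#'
#' @inheritParams format_glycan_code
#' @return Character vector with values in
#'   `c("sialylated", "sialylated_fucosylated", "other")`.
#' @examples
#' classify_glycan(parse_glycan_code(c("5-6-0-3", "5-6-1-3", "4-5-0-0")))
#' @export
classify_glycan <- function(comp) {
  comp <- as_composition(comp)
  ifelse(comp$neuac > 0 & comp$fuc > 0, "sialylated_fucosylated",
         ifelse(comp$neuac > 0, "sialylated", "other"))
}
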