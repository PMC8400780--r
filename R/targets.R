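#' The packaged haptoglobin microheterogeneity table
#'
#' Transcription of the assay's site-by-site glycoform inventory: one row
#' per (site, glycan composition) cell, each cell of the form
#' `"code"` or `"code, k Isomers"`. The packaged table covers 41 glycoform
#' cells expanding to 72 isomer entries across Asn184, Asn207 and Asn241.
#'
#' @param path Optional path to an alternative transcription CSV with
#'   columns `site_id`, `entry`; defaults to the packaged file.
#' @return A data.frame with columns `site_id`, `glycan_code`, `n_isomers`.
#' @export
hp_table1 <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "haptoglobin_table1.csv",
                        package = "glycoPRM", mustWork = TRUE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("site_id", "entry") %in% names(raw)))
  parsed <- lapply(seq_len(nrow(raw)), function(i) {
    cell <- trimws(raw$entry[i])
    m <- regmatches(cell, regexec(
      "^([0-9]+-[0-9]+-[0-9]+-[0-9]+)(?:,\\s*([0-9]+)\\s*Isomers?)?$", cell))[[1]]
    if (length(m) == 0L || !nzchar(m[1])) {
      stop("unparseable glycoform cell at row ", i, ": '", raw$entry[i], "'")
    }
    k <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    data.frame(site_id = raw$site_id[i], glycan_code = m[2], n_isomers = k,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parsed)
}

# Precursor charge rule: tri-/tetra-antennary sialylated glycoforms at Asn241
# (>= 3 HexNAc antennae beyond the 2-HexNAc core, >= 1 Neu5Ac) carry 4+,
# everything else 3+.
target_charge <- function(site_id, comp) {
  ifelse(site_id == "Asn241" & (comp$hexnac - 2L) >= 3L & comp$neuac >= 1L,
         4L, 3L)
}

# Fixture convention for expected retention times: within each site's elution
# window, glycoform cluster centers are spread evenly (with a margin wide
# enough for the largest isomer cluster), ordered so small / lightly
# sialylated compositions elute first; isomers of one composition are spaced
# by `isomer_spacing` minutes around the cluster center.
assign_expected_rt <- function(targets, isomer_spacing) {
  out <- vector("list", 0L)
  for (sid in unique(targets$site_id)) {
    sub <- targets[targets$site_id == sid, , drop = FALSE]
    si <- site_info(sid)
    forms <- sub[!duplicated(sub$glycan_code), , drop = FALSE]
    ord <- order(forms$neuac, forms$hexnac + forms$hex + forms$fuc,
                 forms$hexnac, forms$fuc, forms$glycan_code)
    forms <- forms[ord, , drop = FALSE]
    max_half <- max((forms$n_isomers - 1) / 2 * isomer_spacing)
    margin <- max_half + 1
    centers <- if (nrow(forms) == 1L) {
      (si$window_start + si$window_end) / 2
    } else {
      seq(si$window_start + margin, si$window_end - margin,
          length.out = nrow(forms))
    }
    for (f in seq_len(nrow(forms))) {
      k <- forms$n_isomers[f]
      rts <- centers[f] + (seq_len(k) - (k + 1) / 2) * isomer_spacing
      rows <- sub[sub$glycan_code == forms$glycan_code[f], , drop = FALSE]
      rows$expected_rt <- rts[rows$isomer_index]
      out[[length(out) + 1L]] <- rows
    }
  }
  res <- do.call(rbind, out)
  res[order(res$site_id, res$expected_rt), , drop = FALSE]
}

#' Build the PRM target list
#'
#' Expands the glycoform inventory into one row per isomer entry, computing
#' per-target precursor m/z (charge 3+, or 4+ for tri-/tetra-antennary
#' sialylated Asn241 glycoforms), the six quantifier fragment m/z values
#' (Y1 plus the five-step core Y-ion ladder), and an expected retention
#' time inside the site's elution window (isomers of one composition spaced
#' by `isomer_spacing` minutes, in retention-time order).
#'
#' @param table1 Glycoform inventory as returned by [hp_table1()].
#' @param isomer_spacing Minutes between isomer apexes of one composition.
#' @return A data.frame with one row per isomer entry (72 for the packaged
#'   table) and columns `target_key`, `form_key`, `site_id`, `peptide`,
#'   `glycan_code`, `hexnac`, `hex`, `fuc`, `neuac`, `glycan_class`,
#'   `n_isomers`, `isomer_index`, `charge`, `precursor_mz`, `expected_rt`,
#'   plus a list column `fragment_mzs` of the six quantifier m/z values.
#' @examples
#' targets <- build_target_list()
#' nrow(targets) # 72
#' @export
build_target_list <- function(table1 = hp_table1(), isomer_spacing = 2) {
  stopifnot(nrow(table1) >= 1L, all(table1$n_isomers >= 1L))
  comp <- parse_glycan_code(table1$glycan_code)
  base <- cbind(table1, comp[c("hexnac", "hex", "fuc", "neuac")])
  base$glycan_class <- classify_glycan(comp)
  base$charge <- target_charge(base$site_id, comp)
  si <- site_info(base$site_id)
  base$peptide <- si$peptide
  base$precursor_mz <- (si$peptide_mass + glycan_mass(comp) +
                          base$charge * .glyco_masses$proton) / base$charge

  # one row per isomer entry
  idx <- rep(seq_len(nrow(base)), base$n_isomers)
  targets <- base[idx, , drop = FALSE]
  targets$isomer_index <- unlist(lapply(base$n_isomers, seq_len))
  targets <- assign_expected_rt(targets, isomer_spacing)

  frag <- lapply(seq_len(nrow(targets)), function(i) {
    ser <- y_ion_series(targets$site_id[i],
                        targets[i, c("hexnac", "hex", "fuc", "neuac")])
    mz <- ser$mz[ser$quantifier]
    stats::setNames(mz, ser$label[ser$quantifier])
  })
  targets$fragment_mzs <- frag
  targets$form_key <- paste(targets$site_id, targets$glycan_code, sep = "|")
  targets$target_key <- paste(targets$form_key, targets$isomer_index, sep = "|")
  rownames(targets) <- NULL
  cols <- c("target_key", "form_key", "site_id", "peptide", "glycan_code",
            "hexnac", "hex", "fuc", "neuac", "glycan_class", "n_isomers",
            "isomer_index", "charge", "precursor_mz", "expected_rt",
            "fragment_mzs")
  targets[cols]
}

#' Cross-site glycan composition overlaps
#'
#' Set intersections of the distinct glycan compositions observed at each
#' glycosylation site: every unordered site pair plus the triple
#' intersection.
#'
#' @param targets Target list from [build_target_list()] (any data.frame
#'   with `site_id` and `glycan_code` columns).
#' @return A list with `pairwise` (data.frame `site_a`, `site_b`,
#'   `n_common`) and `triple` (integer count common to all three sites;
#'   `NA` if fewer than three sites are present).
#' @export
site_overlap_counts <- function(targets) {
  sets <- lapply(split(targets$glycan_code, targets$site_id), unique)
  sites <- names(sets)
  if (length(sites) < 1L) stop("no sites in target list")
  pairs <- if (length(sites) >= 2L) t(utils::combn(sites, 2L)) else
    matrix(character(0), ncol = 2L)
  pairwise <- data.frame(
    site_a = pairs[, 1], site_b = pairs[, 2],
    n_common = apply(pairs, 1L, function(p)
      length(intersect(sets[[p[1]]], sets[[p[2]]]))),
    stringsAsFactors = FALSE
  )
  if (nrow(pairwise) == 0L && length(sites) == 1L) {
    # single-site convention: no pairwise overlaps
    pairwise <- data.frame(site_a = character(0), site_b = character(0),
                           n_common = integer(0))
  }
  triple <- if (length(sites) >= 3L) {
    length(Reduce(intersect, sets))
  } else {
    NA_integer_
  }
  list(pairwise = pairwise, triple = triple)
}
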