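#' Normalize peak areas to per-site relative abundances
#'
#' For each patient and glycosylation site, divides every isomer entry's
#' area by the total area of all entries assigned to that site, so each
#' patient-site profile sums to one. A patient-site with zero total area
#' cannot be normalized: its entries become `NA` and are flagged
#' `zero_site_total`. The operation is scale-invariant per patient and
#' idempotent.
#'
#' @param qt A `quant_table` from [build_quant_table()] (or an already
#'   normalized `rel_abundance_table`).
#' @return A list of class `rel_abundance_table` with the same structure:
#'   `values` (matrix patients x entries), `columns`, `flags`.
#' @examples
#' # areas (2, 3, 5) at one site become (0.2, 0.3, 0.5)
#' @export
normalize_by_site <- function(qt) {
  x <- if (inherits(qt, "rel_abundance_table")) qt$values else qt$areas
  stopifnot(is.matrix(x), !is.null(qt$columns))
  if (any(x < 0, na.rm = TRUE)) stop("negative areas cannot be normalized")
  values <- x
  flags <- matrix("ok", nrow(x), ncol(x), dimnames = dimnames(x))
  for (sid in unique(qt$columns$site_id)) {
    sel <- qt$columns$site_id == sid
    tot <- rowSums(x[, sel, drop = FALSE], na.rm = TRUE)
    zero <- tot <= 0 | is.na(tot)
    values[, sel] <- sweep(x[, sel, drop = FALSE], 1, tot, "/")
    if (any(zero)) {
      values[zero, sel] <- NA_real_
      flags[zero, sel] <- "zero_site_total"
    }
  }
  structure(list(values = values, columns = qt$columns, flags = flags),
            class = "rel_abundance_table")
}

#' @exportS3Method base::print
print.rel_abundance_table <- function(x, ...) {
  cat("Relative abundance table:", nrow(x$values), "patients x",
      ncol(x$values), "isomer entries\n")
  invisible(x)
}

#' Per-group glycome class summary for one site
#'
#' For each patient, sums the relative abundances of a site's entries
#' within each glycan class (sialylated, sialylated-fucosylated, other),
#' then averages over the patients of each group. Per-group fractions sum
#' to one; these are the numbers behind the class pie summaries.
#'
#' @param rel A `rel_abundance_table`.
#' @param patients Patient data.frame with `patient_id` and `group`.
#' @param site Site id, e.g. `"Asn207"`.
#' @param pooled If `TRUE`, use pooled-area ratios (class sum of group
#'   totals) instead of the default mean of per-patient fractions.
#' @return A data.frame `site`, `group`, `class`, `fraction`.
#' @export
glycome_class_summary <- function(rel, patients, site, pooled = FALSE) {
  stopifnot(inherits(rel, "rel_abundance_table"))
  if (!nrow(patients)) stop("empty patient table: no groups to summarize")
  sel <- rel$columns$site_id == site
  if (!any(sel)) stop("no entries for site ", site)
  cls <- rel$columns$glycan_class[sel]
  x <- rel$values[, sel, drop = FALSE]
  per_patient <- sapply(sort(unique(cls)), function(cl)
    rowSums(x[, cls == cl, drop = FALSE]))
  groups <- unique(patients$group)
  out <- do.call(rbind, lapply(groups, function(grp) {
    pid <- patients$patient_id[patients$group == grp]
    pid <- intersect(pid, rownames(x))
    if (!length(pid)) stop("empty group: ", grp)
    fr <- if (pooled) {
      tot <- colSums(per_patient[pid, , drop = FALSE], na.rm = TRUE)
      tot / sum(tot)
    } else {
      colMeans(per_patient[pid, , drop = FALSE], na.rm = TRUE)
    }
    data.frame(site = site, group = grp, class = colnames(per_patient),
               fraction = as.numeric(fr), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Z-scored feature matrix for a site heat map
#'
#' Centers and scales every isomer entry across patients (feature mean 0,
#' sd 1), orders patient columns cirrhosis-then-HCC, and orders feature
#' rows by hierarchical clustering (average linkage on Euclidean distance
#' of the z-scored profiles). Zero-variance features get all-zero rows and
#' are flagged.
#'
#' @param rel A `rel_abundance_table`.
#' @param patients Patient data.frame with `patient_id` and `group`.
#' @param site Site id.
#' @return A list: `z` (features x patients, clustered row order applied),
#'   `row_order`, `col_order`, `flagged_features`.
#' @export
heatmap_matrix <- function(rel, patients, site) {
  stopifnot(inherits(rel, "rel_abundance_table"), nrow(patients) >= 2L)
  sel <- rel$columns$site_id == site
  if (!any(sel)) stop("no entries for site ", site)
  x <- t(rel$values[, sel, drop = FALSE]) # features x patients
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  flagged <- rownames(x)[sd == 0 | is.na(sd)]
  z <- (x - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0 | is.na(sd), ] <- 0
  col_order <- order(match(patients$group[match(colnames(z),
                                                patients$patient_id)],
                           c("cirrhosis", "HCC")),
                     colnames(z))
  row_order <- if (nrow(z) > 2L) {
    stats::hclust(stats::dist(z), method = "average")$order
  } else {
    seq_len(nrow(z))
  }
  list(z = z[row_order, col_order, drop = FALSE],
       row_order = rownames(z)[row_order],
       col_order = colnames(z)[col_order],
       flagged_features = flagged)
}
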