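# Glycolysis / TCA enzyme acetylation presence matrices and per-enzyme
# acetylation levels across species.

#' Canonical enzyme labels for the two core pathways
#' @export
GLYCOLYSIS_ENZYMES <- c("HK", "PGI", "PFK", "ALD", "GAPDH", "TIM",
                        "PGK", "PGM", "ENO", "PK")

#' @rdname GLYCOLYSIS_ENZYMES
#' @export
TCA_ENZYMES <- c("CS", "ACO", "IDH", "ODH", "SCS", "SDH", "FH", "MDH")

#' Build a cross-species enzyme acetylation matrix
#'
#' For every (enzyme, species) pair of the catalog, pools the catalog
#' entries (isoforms/paralogs merged by union) and reports whether the
#' enzyme is acetylated (at least one distinct Kac site on any entry), the
#' distinct-site count, and the acetylation percentage (100 x distinct Kac
#' lysines / total lysines over the pooled entries). Species lacking a
#' catalog entry for an enzyme are marked `not_assessed`, which is
#' distinct from assessed-but-unmodified (`not_acetylated`).
#'
#' @param catalog Data frame with columns `enzyme`, `species_id`,
#'   `protein_id` (curated ortholog catalog; one row per entry).
#' @param datasets Named list of [acetylome_dataset()] objects keyed by
#'   species_id (typically per-species unions).
#' @param proteomes Named list of [proteome_index()] objects keyed by
#'   species_id.
#' @param enzymes Row order of the matrix; defaults to the enzymes present
#'   in the catalog.
#' @return Object of class `acetylation_matrix`: data frame with `enzyme`,
#'   `species_id`, `group_label`, `status`
#'   (`acetylated`/`not_acetylated`/`not_assessed`), `n_kac_sites`,
#'   `n_lysines`, `kac_percent`.
#' @export
build_acetylation_matrix <- function(catalog, datasets, proteomes,
                                     enzymes = NULL) {
  stopifnot(all(c("enzyme", "species_id", "protein_id") %in%
                names(catalog)))
  species <- unique(catalog$species_id)
  miss <- setdiff(species, names(datasets))
  if (length(miss) > 0L) {
    stop("no dataset for species: ", paste(miss, collapse = ", "))
  }
  enzymes <- enzymes %||% unique(catalog$enzyme)
  rows <- list()
  for (sp in species) {
    ds <- datasets[[sp]]
    prot <- proteomes[[sp]]
    if (is.null(prot)) stop("no proteome for species: ", sp)
    for (enz in enzymes) {
      entries <- catalog$protein_id[catalog$enzyme == enz &
                                    catalog$species_id == sp]
      if (length(entries) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          enzyme = enz, species_id = sp, group_label = ds$group_label,
          status = "not_assessed", n_kac_sites = NA_integer_,
          n_lysines = NA_integer_, kac_percent = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      unknown <- setdiff(entries, names(prot$proteins))
      if (length(unknown) > 0L) {
        stop("catalog protein(s) not in ", sp, " proteome: ",
             paste(unknown, collapse = ", "))
      }
      sites <- ds$sites[ds$sites$protein_id %in% entries, , drop = FALSE]
      nsites <- nrow(sites)  # sites are already distinct per dataset
      nlys <- sum(prot$per_protein_lysines[entries])
      rows[[length(rows) + 1L]] <- data.frame(
        enzyme = enz, species_id = sp, group_label = ds$group_label,
        status = if (nsites >= 1L) "acetylated" else "not_acetylated",
        n_kac_sites = nsites, n_lysines = nlys,
        kac_percent = if (nlys > 0L) 100 * nsites / nlys else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("acetylation_matrix", "data.frame")
  out
}

#' Rank species or groups by enzyme acetylation level
#'
#' Orders, per enzyme, the assessed species (or groups, averaging cell
#' percentages within a group) by descending acetylation percentage. Ties
#' are broken lexicographically and flagged.
#'
#' @param matrix An `acetylation_matrix`.
#' @param by `"species"` (default) or `"group"`.
#' @return Data frame with `enzyme`, `unit` (species or group), `kac_percent`,
#'   `rank`, `tied`.
#' @export
rank_enzyme_levels <- function(matrix, by = c("species", "group")) {
  by <- match.arg(by)
  stopifnot(inherits(matrix, "acetylation_matrix"))
  m <- matrix[matrix$status != "not_assessed", , drop = FALSE]
  unit <- if (by == "species") m$species_id else m$group_label
  agg <- stats::aggregate(list(kac_percent = m$kac_percent),
                          by = list(enzyme = m$enzyme, unit = unit),
                          FUN = mean)
  parts <- lapply(split(agg, agg$enzyme), function(g) {
    g <- g[order(-g$kac_percent, g$unit), , drop = FALSE]
    g$rank <- seq_len(nrow(g))
    g$tied <- duplicated(g$kac_percent) |
      duplicated(g$kac_percent, fromLast = TRUE)
    g
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
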