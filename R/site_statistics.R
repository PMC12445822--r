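# Proteome-normalized acetylation metrics, site-count distributions,
# highly-acetylated protein selection, and protein-domain summaries.

SITE_BINS <- c("1", "2", "3-5", "6-10", ">10")

bin_of_count <- function(n) {
  stopifnot(all(n >= 1L))
  cut(n, breaks = c(0.5, 1.5, 2.5, 5.5, 10.5, Inf),
      labels = SITE_BINS)
}

#' Proteome-normalized acetylation summary of one acetylome
#'
#' Computes the two normalized metrics used to compare acetylomes across
#' species of very different proteome sizes: the percentage of all proteome
#' lysines found acetylated, and the percentage of all proteome proteins
#' with at least one Kac site. Both are reported on the 0-100 scale.
#'
#' @param dataset An [acetylome_dataset()].
#' @param proteome The matching [proteome_index()].
#' @return Data frame with `acetylome_id`, `species_id`, `n_kac_sites`,
#'   `n_kac_proteins`, `pct_kac_sites`, `pct_kac_proteins`.
#' @export
kac_summary <- function(dataset, proteome) {
  stopifnot(inherits(dataset, "acetylome_dataset"),
            inherits(proteome, "proteome_index"))
  if (proteome$n_lysines_total == 0L) {
    stop("proteome has zero lysines; pct_kac_sites undefined")
  }
  if (proteome$n_proteins == 0L) {
    stop("proteome has zero proteins; pct_kac_proteins undefined")
  }
  n_sites <- nrow(dataset$sites)
  n_prot <- length(dataset$kac_proteins)
  data.frame(
    acetylome_id = dataset$acetylome_id,
    species_id = dataset$species_id,
    group_label = dataset$group_label,
    n_kac_sites = n_sites,
    n_kac_proteins = n_prot,
    pct_kac_sites = 100 * n_sites / proteome$n_lysines_total,
    pct_kac_proteins = 100 * n_prot / proteome$n_proteins,
    stringsAsFactors = FALSE)
}

#' Distribution of Kac-site counts per protein
#'
#' Bins every Kac protein of a dataset by its number of distinct acetylated
#' positions into the five classes 1, 2, 3-5, 6-10 (the ">5-10" class) and
#' >10.
#'
#' @param dataset An [acetylome_dataset()].
#' @return Object of class `site_distribution`: data frame with `bin`,
#'   `count`, `percent`; attribute `n_kac_proteins`.
#' @export
site_count_distribution <- function(dataset) {
  stopifnot(inherits(dataset, "acetylome_dataset"))
  per <- table(dataset$sites$protein_id)
  counts <- as.integer(table(bin_of_count(as.integer(per))))
  n <- sum(counts)
  pct <- if (n > 0L) 100 * counts / n else rep(NA_real_, length(SITE_BINS))
  structure(
    data.frame(bin = SITE_BINS, count = counts, percent = pct,
               stringsAsFactors = FALSE),
    n_kac_proteins = n,
    class = c("site_distribution", "data.frame"))
}

#' Pool site-count distributions across acetylomes
#'
#' Pooled counts are sums over the inputs and pooled percentages are
#' recomputed from the pooled counts (count-weighted), not averaged over
#' per-acetylome percentages. The unweighted mean of per-acetylome
#' percentages is also attached (attribute `mean_percent`) since both views
#' are of interest.
#'
#' @param distributions List of `site_distribution` objects.
#' @return A pooled `site_distribution`.
#' @export
aggregate_distributions <- function(distributions) {
  if (length(distributions) == 0L) {
    stop("no distributions to aggregate")
  }
  stopifnot(all(vapply(distributions, inherits, logical(1),
                       "site_distribution")))
  counts <- Reduce(`+`, lapply(distributions, `[[`, "count"))
  n <- sum(counts)
  pct <- if (n > 0L) 100 * counts / n else rep(NA_real_, length(SITE_BINS))
  mean_pct <- rowMeans(do.call(cbind,
                               lapply(distributions, `[[`, "percent")))
  structure(
    data.frame(bin = SITE_BINS, count = counts, percent = pct,
               stringsAsFactors = FALSE),
    n_kac_proteins = n,
    mean_percent = mean_pct,
    class = c("site_distribution", "data.frame"))
}

#' Select highly acetylated proteins
#'
#' Returns the proteins carrying at least five distinct Kac sites, split
#' into the three disjoint classes used for domain analysis: exactly 5,
#' 6-10, and more than 10 sites.
#'
#' @param dataset An [acetylome_dataset()].
#' @return Data frame with `protein_id`, `species_id`, `n_sites`,
#'   `class_label` (one of `"exactly_5"`, `"6-10"`, `">10"`).
#' @export
select_high_acetyl <- function(dataset) {
  stopifnot(inherits(dataset, "acetylome_dataset"))
  per <- table(dataset$sites$protein_id)
  n <- as.integer(per)
  keep <- n >= 5L
  cls <- ifelse(n == 5L, "exactly_5", ifelse(n <= 10L, "6-10", ">10"))
  out <- data.frame(protein_id = names(per)[keep],
                    species_id = dataset$species_id,
                    n_sites = n[keep],
                    class_label = cls[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize protein domains over a high-acetylation selection
#'
#' Counts, per acetylation class and protein domain, the number of proteins
#' carrying the domain and the number of distinct species contributing them.
#' Proteins absent from the domain map are tallied under `"unannotated"`.
#'
#' @param selection Data frame as returned by [select_high_acetyl()]
#'   (rows from several datasets may be concatenated).
#' @param domain_map Data frame with columns `protein_id`, `domain_id`
#'   (e.g. InterPro accessions); one row per assignment.
#' @return Data frame with `class_label`, `domain_id`, `n_proteins`,
#'   `n_species`, sorted within class by descending protein count.
#' @export
summarize_domains <- function(selection, domain_map) {
  stopifnot(is.data.frame(selection),
            all(c("protein_id", "species_id", "class_label") %in%
                names(selection)))
  if (nrow(selection) == 0L) {
    return(data.frame(class_label = character(), domain_id = character(),
                      n_proteins = integer(), n_species = integer(),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(c("protein_id", "domain_id") %in% names(domain_map)))
  m <- merge(selection, domain_map, by = "protein_id", all.x = TRUE)
  m$domain_id[is.na(m$domain_id)] <- "unannotated"
  agg <- do.call(rbind, lapply(
    split(m, list(m$class_label, m$domain_id), drop = TRUE),
    function(g) data.frame(class_label = g$class_label[1L],
                           domain_id = g$domain_id[1L],
                           n_proteins = length(unique(g$protein_id)),
                           n_species = length(unique(g$species_id)),
                           stringsAsFactors = FALSE)))
  agg <- agg[order(agg$class_label, -agg$n_proteins, agg$domain_id), ]
  rownames(agg) <- NULL
  agg
}

#' Percentage of a protein's lysines found acetylated
#'
#' @param protein_id Protein identifier, present in the proteome.
#' @param dataset An [acetylome_dataset()].
#' @param proteome The matching [proteome_index()].
#' @return Percentage (0-100) of the protein's lysines with a Kac site.
#' @export
protein_kac_percent <- function(protein_id, dataset, proteome) {
  stopifnot(inherits(dataset, "acetylome_dataset"),
            inherits(proteome, "proteome_index"))
  if (!protein_id %in% names(proteome$proteins)) {
    stop("protein not in proteome: ", protein_id)
  }
  nk <- proteome$per_protein_lysines[[protein_id]]
  if (nk == 0L) {
    stop("protein has zero lysines: ", protein_id)
  }
  nsites <- sum(dataset$sites$protein_id == protein_id)
  100 * nsites / nk
}
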