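#!/usr/bin/env Rscript
# Ingest the simulated panel and compute the normalized acetylation
# metrics, the pooled site-count distribution, and the domain summary of
# highly acetylated proteins.

suppressMessages(library(kacmeta))
simdir <- "results/simdata"
out <- "results/site_stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
manifest <- read.delim(file.path(simdir, "manifest.tsv"))

dialect <- list(protein_col = "protein_id", position_col = "position")
proteomes <- list()
datasets <- list()
for (i in seq_len(nrow(manifest))) {
  m <- manifest[i, ]
  if (is.null(proteomes[[m$species_id]])) {
    proteomes[[m$species_id]] <- read_proteome_fasta(
      file.path(simdir, m$proteome_fasta), m$species_id)
  }
  datasets[[m$acetylome_id]] <- read_acetylome_table(
    file.path(simdir, m$site_table), dialect,
    acetylome_id = m$acetylome_id, species_id = m$species_id,
    group_label = m$group_label, proteome = proteomes[[m$species_id]],
    mode = "strict")
}

# per-acetylome normalized metrics (the cross-species comparison table)
summaries <- do.call(rbind, lapply(datasets, function(ds) {
  kac_summary(ds, proteomes[[ds$species_id]])
}))
write.table(summaries, file.path(out, "kac_summaries.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
top <- summaries[which.max(summaries$pct_kac_proteins), ]
cat(sprintf(
  "%d acetylomes; pct_kac_sites %.2f-%.2f%%; highest pct_kac_proteins %s (%.1f%%)\n",
  nrow(summaries), min(summaries$pct_kac_sites),
  max(summaries$pct_kac_sites), top$acetylome_id,
  top$pct_kac_proteins))

# pooled site-count distribution and per-group versions
dists <- lapply(datasets, site_count_distribution)
pooled <- aggregate_distributions(dists)
write.table(pooled, file.path(out, "site_count_distribution_pooled.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat(sprintf("pooled single-site bin: %.2f%% of %d Kac proteins\n",
            pooled$percent[1], attr(pooled, "n_kac_proteins")))
bygroup <- do.call(rbind, lapply(split(names(datasets), vapply(
  datasets, `[[`, character(1), "group_label")), function(ids) {
    d <- aggregate_distributions(dists[ids])
    data.frame(group_label = datasets[[ids[1]]]$group_label,
               bin = d$bin, count = d$count, percent = d$percent)
  }))
write.table(bygroup, file.path(out, "site_count_distribution_groups.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

# highly acetylated proteins and a synthetic domain map over them
selection <- do.call(rbind, lapply(datasets, select_high_acetyl))
set.seed(1)
domain_pool <- c("IPR013126", "IPR000719", "IPR036291", "IPR020828",
                 "IPR001609")
domain_map <- data.frame(
  protein_id = unique(selection$protein_id),
  domain_id = sample(domain_pool, length(unique(selection$protein_id)),
                     replace = TRUE))
domains <- summarize_domains(selection, domain_map)
write.table(domains, file.path(out, "domain_summary.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("high-acetylation selection: %d proteins (%d exactly-5)\n",
            nrow(selection), sum(selection$class_label == "exactly_5")))
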