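#!/usr/bin/env Rscript
# Build the synthetic study panel: 48 acetylomes over 37 species across 8
# phylogenetic groups, with planted site-count distributions. Stands in
# for the curated compilation of published acetylomes and writes the
# exact file formats the ingestion stage reads.

suppressMessages(library(kacmeta))
out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

groups <- c("bacteria", "fungi", "protozoa", "worms", "plants",
            "insects", "fish", "mammals")
# 37 species spread over the groups; 11 species contribute two acetylomes
n_per_group <- c(9, 6, 5, 3, 5, 3, 2, 4)
stopifnot(sum(n_per_group) == 37)

manifest <- NULL
acetylome_no <- 0L
for (g in seq_along(groups)) {
  for (s in seq_len(n_per_group[g])) {
    sp <- sprintf("%s_sp%02d", groups[g], s)
    sp_seed <- g * 100L + s
    fasta <- file.path(out, paste0(sp, ".fasta"))
    gen <- generate_proteome(n_proteins = 150L, min_lysines = 16L,
                             species_id = sp, seed = sp_seed,
                             path = fasta)
    # the first species of every group and the second species of the
    # three largest groups contribute two acetylomes: 37 + 8 + 3 = 48
    n_ac <- if (s == 1L || (s == 2L && g <= 3L)) 2L else 1L
    for (k in seq_len(n_ac)) {
      acetylome_no <- acetylome_no + 1L
      ac_id <- sprintf("AC%03d", acetylome_no)
      tsv <- file.path(out, paste0(ac_id, "_sites.tsv"))
      generate_acetylome(gen,
                         prop_kac_proteins = 0.10 + 0.02 * g,
                         mode = "multinomial",
                         acetylome_id = ac_id, group_label = groups[g],
                         seed = sp_seed * 10L + k, path = tsv)
      manifest <- rbind(manifest, data.frame(
        acetylome_id = ac_id, species_id = sp, group_label = groups[g],
        proteome_fasta = basename(fasta), site_table = basename(tsv)))
    }
  }
}
write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("simulated", nrow(manifest), "acetylomes over",
    length(unique(manifest$species_id)), "species into", out, "\n")
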