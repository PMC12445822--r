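#!/usr/bin/env Rscript
# Regulatory-lysine conservation: Hsp70 K77 and aldolase K147 projected
# across the packaged synthetic ortholog panels.

suppressMessages(library(kacmeta))
out <- "results/conservation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
fixture <- function(f) system.file("extdata", f, package = "kacmeta")
read_named <- function(f) {
  s <- Biostrings::readAAStringSet(fixture(f))
  setNames(as.character(s), names(s))
}

hsp <- read_named("hsp70_orthologs_synthetic.fasta")
proj <- project_site(hsp, "Hs", 77L)
ids <- sapply(setdiff(names(hsp), "Hs"), function(tg) {
  percent_identity(global_align(hsp[["Hs"]], hsp[[tg]]))
})
proj$pct_identity_vs_Hs <- ids[proj$target]
write.table(proj, file.path(out, "hsp70_k77_projection.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("Hsp70 K77: %d/%d orthologs conserved K, %d conservative R\n",
            sum(proj$class == "conserved_K"), nrow(proj),
            sum(proj$class == "conservative_R")))
motif <- motif_scan(hsp[["Hs"]], "KRLIGERKFGDP")
cat(sprintf("regulatory motif at %d-%d in the reference\n",
            motif$start, motif$end))

ald <- read_named("aldolase_orthologs_synthetic.fasta")
pa <- project_site(ald, "Hs", 147L)
write.table(pa, file.path(out, "aldolase_k147_projection.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("aldolase K147 maps to:",
    paste(sprintf("%s:K%d", pa$target, pa$target_position),
          collapse = " "), "\n")
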