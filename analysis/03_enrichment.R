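#!/usr/bin/env Rscript
# GO and KEGG enrichment of a study set with a planted signal, using the
# packaged ontology and BRITE fixtures.

suppressMessages(library(kacmeta))
out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

dag <- parse_obo(system.file("extdata", "go_synthetic.obo",
                             package = "kacmeta"))
genes <- sprintf("g%04d", 1:1000)
study <- genes[1:100]

# GO-style annotations: spike the study set into "glycolytic process"
# and assign the remaining leaf terms at random.
set.seed(10)
leaves <- c("GO:0000004", "GO:0000005", "GO:0000007", "GO:0000010",
            "GO:0000012", "GO:0000013", "GO:0000014")
ann <- do.call(rbind, lapply(leaves, function(t) {
  base <- genes[runif(1000) < 0.03]
  if (t == "GO:0000004") base <- unique(c(base, study[1:15]))
  if (length(base) == 0) return(NULL)
  data.frame(gene = base, term = t)
}))
res <- run_enrichment(study, ann, background_genes = genes, dag = dag,
                      alpha = 0.01)
res$name <- dag$terms$name[match(res$term, dag$terms$id)]
write.table(res, file.path(out, "go_enrichment.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
sig <- res[res$significant, ]
cat("GO: ", nrow(sig), "significant term(s):",
    paste(sig$name, collapse = "; "), "\n")

# propagation off reproduces the flat 2x2 counting of the original
# enrichment scripts; both views are exported
flat <- run_enrichment(study, ann, background_genes = genes, dag = dag,
                       propagate = FALSE, alpha = 0.01)
write.table(flat, file.path(out, "go_enrichment_unpropagated.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

# KEGG: map genes to KOs, KOs to pathways, enrich at the pathway level
ph <- parse_kegg_htext(system.file("extdata", "ko00001_synthetic.keg",
                                   package = "kacmeta"))
set.seed(11)
kos <- unique(ph$ko2pathway$ko)
gene2ko <- data.frame(gene = genes,
                      ko = sample(kos, 1000, replace = TRUE))
glyco <- ph$ko2pathway$ko[ph$ko2pathway$pathway_id == "ko00010"]
gene2ko$ko[1:60] <- sample(glyco, 60, replace = TRUE)  # planted signal
kann <- merge(gene2ko, ph$ko2pathway, by = "ko")
kres <- run_enrichment(study, data.frame(gene = kann$gene,
                                         term = kann$pathway_id),
                       background_genes = genes, alpha = 0.01)
kres$name <- ph$pathways$name[match(kres$term, ph$pathways$pathway_id)]
write.table(kres, file.path(out, "kegg_enrichment.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("KEGG:", sum(kres$significant), "significant pathway(s):",
    paste(kres$name[kres$significant], collapse = "; "), "\n")
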