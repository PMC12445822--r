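# One-off construction of the packaged synthetic fixtures under
# inst/extdata/. Each fixture is verified with the package's own
# functions before being written.
suppressMessages(library(kacmeta))
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

## ---- aldolase ortholog family ------------------------------------------
# Key catalytic lysine at 147 in the reference; target coordinates follow
# published cross-species numbering via N-terminal extensions:
# At K185 (+38), Dr K147 (+0), Ts K162 (+15), Dm K147 (+0), Tc K157 (+10).
ald_targets <- data.frame(
  name = c("At", "Dr", "Ts", "Dm", "Tc"),
  n_ext = c(38L, 0L, 15L, 0L, 10L),
  mutation_rate = c(0.10, 0.08, 0.12, 0.10, 0.15),
  key_class = "K", stringsAsFactors = FALSE)
ald <- generate_ortholog_family(
  ald_targets, ref_length = 360L, key_position = 147L,
  reference_id = "Hs", protect = 227:233, seed = 101L,
  path = "inst/extdata/aldolase_orthologs_synthetic.fasta")
proj <- project_site(ald$sequences, "Hs", 147L)
stopifnot(identical(proj$target_position[match(c("At","Dr","Ts","Dm","Tc"),
                                              proj$target)],
                    c(185L, 147L, 162L, 147L, 157L)),
          all(proj$class == "conserved_K"))
cat("aldolase projections:", paste(proj$target, proj$target_position), "\n")

## ---- Hsp70 ortholog family ---------------------------------------------
# Regulatory motif KRLIGERKFGDP at 70-81 carries K77 (8th motif residue).
# Ec/Pa/At/Os carry the charge-preserving arginine substitution at the
# K77 column; Dr stays close to the reference (>80% identity).
hsp_targets <- data.frame(
  name = c("Dr", "Tb", "Sc", "Dm", "Ec", "Pa", "At", "Os"),
  n_ext = 0L,
  mutation_rate = c(0.07, 0.15, 0.15, 0.12, 0.22, 0.22, 0.18, 0.18),
  key_class = c("K", "K", "K", "K", "R", "R", "R", "R"),
  stringsAsFactors = FALSE)
hsp <- generate_ortholog_family(
  hsp_targets, ref_length = 240L, key_position = 77L,
  reference_id = "Hs", motif = "KRLIGERKFGDP", motif_start = 70L,
  seed = 202L, path = "inst/extdata/hsp70_orthologs_synthetic.fasta")
projh <- project_site(hsp$sequences, "Hs", 77L)
stopifnot(all(projh$class[projh$target %in% c("Ec","Pa","At","Os")] ==
              "conservative_R"),
          all(projh$class[projh$target %in% c("Dr","Tb","Sc","Dm")] ==
              "conserved_K"))
idd <- percent_identity(global_align(hsp$sequences[["Hs"]],
                                     hsp$sequences[["Dr"]]))
cat("Hs-Dr hsp70 identity:", idd, "\n")
stopifnot(idd >= 85)  # headroom over the 80% check
stopifnot(nrow(motif_scan(hsp$sequences[["Hs"]], "KRLIGERKFGDP")) == 1L)

## ---- SODA family + funnel regions + planted Kac sites -------------------
# Reference built around fixed funnel lysines so planted acetylation
# counts are controllable; human carries the most funnel Kac sites,
# followed by Tb and Dm (the published ordering).
set.seed(303)
funnel_k <- c(26L, 30L, 34L, 38L, 42L, 121L, 125L, 129L, 133L, 137L)
other_k  <- c(60L, 75L, 90L, 155L, 170L, 185L)
aa_no_k <- setdiff(c("A","C","D","E","F","G","H","I","L","M","N","P","Q",
                     "R","S","T","V","W","Y"), character(0))
ref <- sample(aa_no_k, 200L, replace = TRUE)
ref[c(funnel_k, other_k)] <- "K"
soda_targets <- data.frame(
  name = c("Tb", "Ts", "Dm", "Af", "Ec", "At", "Dr"),
  n_ext = 0L, mutation_rate = 0.10, key_class = "K",
  stringsAsFactors = FALSE)
soda <- generate_ortholog_family(
  soda_targets, reference = paste(ref, collapse = ""),
  key_position = 129L, reference_id = "Hs",
  protect = c(funnel_k, other_k), seed = 304L,
  path = "inst/extdata/soda_orthologs_synthetic.fasta")
# planted acetylated positions per species (funnel + out-of-funnel)
plant <- list(
  Hs = c(funnel_k[c(1, 3, 5, 7, 9)], other_k[c(1, 2, 3, 4)]),
  Tb = c(funnel_k[c(2, 6, 8)],       other_k[1]),
  Dm = c(funnel_k[c(4, 10)],         other_k[c(1, 2, 5)]),
  Ec = c(funnel_k[1],                other_k[c(2, 3, 4, 6)]),
  Af = c(funnel_k[5],                other_k[c(1, 5, 6)]),
  At = c(funnel_k[9],                other_k[2]),
  Dr = c(funnel_k[3],                other_k[4]),
  Ts = c(integer(0),                 other_k[c(1, 3)]))
regions <- data.frame(start = c(25L, 120L), end = c(45L, 140L))
for (sp in names(plant)) {
  seqsp <- soda$sequences[[sp]]
  res <- substring(seqsp, plant[[sp]], plant[[sp]])
  stopifnot(all(res == "K"))
}
fk <- sapply(names(plant), function(sp)
  funnel_lysine_counts(soda$sequences[[sp]], regions, plant[[sp]])[["FKac"]])
cat("FKac:", paste(names(plant), fk), "\n")
stopifnot(fk[["Hs"]] == max(fk), fk[["Hs"]] > fk[["Tb"]],
          fk[["Tb"]] >= fk[["Dm"]], fk[["Dm"]] > fk[["Ec"]])
write.table(
  data.frame(species = rep(names(plant), lengths(plant)),
             position = unlist(plant, use.names = FALSE)),
  "inst/extdata/soda_kac_sites_synthetic.tsv",
  sep = "\t", row.names = FALSE, quote = FALSE)
write.table(
  data.frame(species = rep(names(plant), each = 2L),
             start = rep(regions$start, length(plant)),
             end = rep(regions$end, length(plant))),
  "inst/extdata/soda_funnel_regions_synthetic.tsv",
  sep = "\t", row.names = FALSE, quote = FALSE)

cat("fixtures written\n")
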