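# Proteome/acetylome ingestion, validation, merging and round trips.

write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(seqs), function(id) {
    c(paste0(">", id), seqs[[id]])
  })), path)
  path
}

test_that("proteome reading counts lysines and rejects bad input", {
  p <- read_proteome_fasta(write_fasta(c(P1 = "MKK")), "sp")
  expect_equal(p$n_proteins, 1L)
  expect_equal(p$n_lysines_total, 2L)

  p <- read_proteome_fasta(write_fasta(c(P1 = strrep("A", 50))), "sp")
  expect_equal(unname(p$per_protein_lysines["P1"]), 0L)

  # lowercase and ambiguity codes: k counted, X/B/Z/U never
  p <- read_proteome_fasta(write_fasta(c(P1 = "mkXBZUk")), "sp")
  expect_equal(p$n_lysines_total, 2L)

  expect_error(read_proteome_fasta(
    write_fasta(c(P1 = "MK", P1 = "MA")), "sp"), "duplicate")
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_proteome_fasta(empty, "sp"))
  expect_error(proteome_index(c(P1 = "MO9K"), "sp"), "illegal")
})

test_that("UniProt-style headers resolve through id_pattern", {
  path <- write_fasta(c("sp|Q12345|NAME_HUMAN some description" = "MKKA"))
  p <- read_proteome_fasta(path, "hs", id_pattern = "^sp\\|([^|]+)\\|")
  expect_identical(names(p$proteins), "Q12345")
})

test_that("generated proteome lysine totals match a naive file scan", {
  path <- tempfile(fileext = ".fasta")
  gen <- generate_proteome(n_proteins = 100L, seed = 1L, path = path)
  lines <- readLines(path)
  naive <- sum(vapply(lines[!startsWith(lines, ">")], function(ln) {
    sum(strsplit(ln, "")[[1]] == "K")
  }, numeric(1)))
  expect_equal(gen$proteome$n_lysines_total, naive)
  expect_equal(gen$proteome$n_lysines_total,
               sum(gen$proteome$per_protein_lysines))
})

test_that("acetylome tables validate positions against the proteome", {
  prot <- proteome_index(c(P1 = "MAKL"), "sp")
  tab <- tempfile(fileext = ".tsv")
  dialect <- list(protein_col = "protein", position_col = "pos")

  writeLines(c("protein\tpos", "P1\t3"), tab)
  ds <- read_acetylome_table(tab, dialect, "ac1", "sp", proteome = prot,
                             mode = "strict")
  expect_equal(nrow(ds$sites), 1L)
  expect_identical(ds$sites$residue_observed, "K")

  writeLines(c("protein\tpos", "P1\t2"), tab)
  expect_error(read_acetylome_table(tab, dialect, "ac1", "sp",
                                    proteome = prot, mode = "strict"),
               "mismatch")
  ds <- read_acetylome_table(tab, dialect, "ac1", "sp", proteome = prot,
                             mode = "lenient")
  expect_equal(unname(ds$validation["n_mismatch"]), 1L)

  # duplicated rows collapse to one site
  writeLines(c("protein\tpos", "P1\t3", "P1\t3"), tab)
  ds <- read_acetylome_table(tab, dialect, "ac1", "sp", proteome = prot)
  expect_equal(nrow(ds$sites), 1L)

  # K123-style site strings
  writeLines(c("protein\tsite", "P1\tK3"), tab)
  ds <- read_acetylome_table(tab, list(protein_col = "protein",
                                       site_col = "site"),
                             "ac1", "sp", proteome = prot, mode = "strict")
  expect_equal(ds$sites$position, 3L)
})

test_that("validation report partitions the deduplicated rows", {
  prot <- proteome_index(c(P1 = "MAKLK"), "sp")
  ds <- toy_dataset(c("P1", "P1", "P1", "P2", "P1"),
                    c(3, 5, 2, 1, 3), proteome = prot)
  v <- ds$validation
  expect_equal(unname(v["n_after_dedup"]), 4L)
  expect_equal(unname(v["n_valid"] + v["n_mismatch"] + v["n_unmapped"]),
               unname(v["n_after_dedup"]))
  expect_equal(unname(v["n_mismatch"]), 1L)  # P1:2 is A
  expect_equal(unname(v["n_unmapped"]), 1L)  # P2 unknown
})

test_that("dataset invariants hold on random synthetic data", {
  for (seed in 1:5) {
    gen <- generate_proteome(n_proteins = 60L, min_lysines = 16L,
                             seed = seed)
    ac <- generate_acetylome(gen, seed = seed + 100L)
    ds <- ac$dataset
    expect_lte(length(ds$kac_proteins), nrow(ds$sites))
    expect_lte(length(ds$kac_proteins), gen$proteome$n_proteins)
    expect_false(any(duplicated(
      paste(ds$sites$protein_id, ds$sites$position))))
  }
})

test_that("merging unions sites per species", {
  d1 <- toy_dataset(rep("P1", 5), 1:5, id = "a1", species = "sp1")
  d2 <- toy_dataset(rep("P2", 5), 1:5, id = "a2", species = "sp1")
  u <- merge_datasets(list(d1, d2), "per_species_union")
  expect_length(u, 1L)
  expect_equal(nrow(u[[1]]$sites), 10L)

  # idempotence on identical datasets
  u2 <- merge_datasets(list(d1, d1), "per_species_union")
  expect_equal(nrow(u2[[1]]$sites), nrow(d1$sites))

  # brute-force set union on overlapping random datasets
  set.seed(9)
  for (rep in 1:4) {
    s1 <- data.frame(protein_id = sample(sprintf("P%d", 1:6), 25, TRUE),
                     position = sample(1:10, 25, TRUE))
    s2 <- data.frame(protein_id = sample(sprintf("P%d", 1:6), 25, TRUE),
                     position = sample(1:10, 25, TRUE))
    da <- toy_dataset(s1$protein_id, s1$position, id = "x", species = "s")
    db <- toy_dataset(s2$protein_id, s2$position, id = "y", species = "s")
    u <- merge_datasets(list(da, db), "per_species_union")[[1]]
    brute <- unique(rbind(da$sites[, 1:2], db$sites[, 1:2]))
    expect_equal(nrow(u$sites), nrow(brute))
  }

  # per_acetylome is the identity
  expect_identical(merge_datasets(list(d1, d2), "per_acetylome"),
                   list(d1, d2))

  d3 <- toy_dataset("P1", 1, id = "a3", species = "sp1", group = "fungi")
  expect_error(merge_datasets(list(d1, d3), "per_species_union"),
               "conflicting group_label")
})

test_that("JSON serialization round-trips the site set", {
  gen <- generate_proteome(n_proteins = 40L, min_lysines = 16L, seed = 2L)
  ds <- generate_acetylome(gen, seed = 5L)$dataset
  path <- tempfile(fileext = ".json")
  write_acetylome_json(ds, path)
  back <- read_acetylome_json(path)
  key <- function(d) sort(paste(d$sites$protein_id, d$sites$position))
  expect_identical(key(back), key(ds))
  expect_identical(back$species_id, ds$species_id)
  expect_identical(back$group_label, ds$group_label)
})
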