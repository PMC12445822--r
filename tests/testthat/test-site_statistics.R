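# Normalized Kac metrics, site-count bins, high-acetylation selection,
# and domain summaries.

test_that("kac_summary computes proteome-normalized percentages", {
  # 100 proteins x 20 lysines = 2000 lysines; 50 sites -> 2.5%
  prot <- flat_proteome(100, strrep("KA", 20))
  ds <- toy_dataset(sprintf("P%03d", 1:50), rep(1L, 50), proteome = prot)
  s <- kac_summary(ds, prot)
  expect_equal(s$pct_kac_sites, 2.5)
  expect_equal(s$pct_kac_proteins, 50)

  # every protein carrying a site saturates pct_kac_proteins
  ds <- toy_dataset(sprintf("P%03d", 1:100), rep(1L, 100),
                    proteome = prot)
  expect_equal(kac_summary(ds, prot)$pct_kac_proteins, 100)

  nok <- flat_proteome(3, "AAAA")
  expect_error(kac_summary(toy_dataset("P001", 1), nok), "zero lysines")
})

test_that("site-count bins place proteins by distinct-position count", {
  ds <- toy_dataset(sprintf("P%02d", 1:10), rep(1L, 10))
  d <- site_count_distribution(ds)
  expect_equal(d$percent[d$bin == "1"], 100)

  # 7 distinct positions -> the >5-10 class
  ds <- toy_dataset(rep("P1", 7), 1:7)
  d <- site_count_distribution(ds)
  expect_equal(d$count[d$bin == "6-10"], 1L)

  # boundary placements: 5 -> 3-5, 10 -> 6-10, 11 -> >10
  ds <- toy_dataset(c(rep("A", 5), rep("B", 10), rep("C", 11)),
                    c(1:5, 1:10, 1:11))
  d <- site_count_distribution(ds)
  expect_equal(d$count, c(0L, 0L, 1L, 1L, 1L))
})

test_that("bin counts conserve the Kac-protein count and percents sum to 100", {
  for (seed in 1:6) {
    gen <- generate_proteome(n_proteins = 80L, min_lysines = 16L,
                             seed = seed)
    ds <- generate_acetylome(gen, mode = "multinomial",
                             seed = seed + 50L)$dataset
    d <- site_count_distribution(ds)
    expect_equal(sum(d$count), length(ds$kac_proteins))
    expect_equal(sum(d$percent), 100, tolerance = 1e-9)
  }
})

test_that("metrics are invariant to row order and protein relabeling", {
  gen <- generate_proteome(n_proteins = 50L, min_lysines = 16L, seed = 3L)
  ds <- generate_acetylome(gen, seed = 4L)$dataset
  shuf <- ds$sites[sample(nrow(ds$sites)), ]
  ds2 <- toy_dataset(shuf$protein_id, shuf$position,
                     proteome = gen$proteome)
  expect_equal(site_count_distribution(ds2)$count,
               site_count_distribution(ds)$count)
  expect_equal(kac_summary(ds2, gen$proteome)$pct_kac_sites,
               kac_summary(ds, gen$proteome)$pct_kac_sites)

  # relabel proteins bijectively: counts unchanged
  relab <- setNames(sprintf("Q%03d", seq_along(gen$proteome$proteins)),
                    names(gen$proteome$proteins))
  prot2 <- proteome_index(setNames(gen$proteome$proteins,
                                   relab[names(gen$proteome$proteins)]),
                          "toy2")
  ds3 <- toy_dataset(unname(relab[ds$sites$protein_id]),
                     ds$sites$position, proteome = prot2)
  expect_equal(site_count_distribution(ds3)$count,
               site_count_distribution(ds)$count)
})

test_that("pooling distributions is count-weighted, associative, commutative", {
  d1 <- site_count_distribution(toy_dataset(sprintf("P%02d", 1:10),
                                            rep(1L, 10)))
  # self-aggregation leaves percentages unchanged
  expect_equal(aggregate_distributions(list(d1, d1))$percent, d1$percent)

  d2 <- site_count_distribution(
    toy_dataset(rep(sprintf("Q%02d", 1:30), each = 2),
                rep(c(1L, 2L), 30)))
  agg <- aggregate_distributions(list(d1, d2))
  expect_equal(agg$percent[1:2], c(25, 75))

  gen <- generate_proteome(n_proteins = 60L, min_lysines = 16L, seed = 8L)
  d3 <- site_count_distribution(
    generate_acetylome(gen, mode = "multinomial", seed = 9L)$dataset)
  left <- aggregate_distributions(
    list(aggregate_distributions(list(d1, d2)), d3))
  right <- aggregate_distributions(
    list(d1, aggregate_distributions(list(d2, d3))))
  expect_equal(left$count, right$count)
  expect_equal(aggregate_distributions(list(d3, d1, d2))$count,
               left$count)

  expect_error(aggregate_distributions(list()), "no distributions")
})

test_that("quota-planted proportions are recovered exactly after pooling", {
  props <- c(0.50, 0.20, 0.20, 0.07, 0.03)
  dists <- lapply(1:4, function(seed) {
    gen <- generate_proteome(n_proteins = 100L, min_lysines = 16L,
                             seed = seed)
    site_count_distribution(
      generate_acetylome(gen, prop_kac_proteins = 1, bin_props = props,
                         mode = "deterministic_quota",
                         seed = seed)$dataset)
  })
  pooled <- aggregate_distributions(dists)
  expect_identical(pooled$percent, c(50, 20, 20, 7, 3))
})

test_that("high-acetylation classes are disjoint and match a naive recount", {
  ds <- toy_dataset(c(rep("A", 5), rep("B", 11)), c(1:5, 1:11))
  sel <- select_high_acetyl(ds)
  expect_identical(sel$class_label[sel$protein_id == "A"], "exactly_5")
  expect_identical(sel$class_label[sel$protein_id == "B"], ">10")

  for (seed in 1:4) {
    gen <- generate_proteome(n_proteins = 70L, min_lysines = 16L,
                             seed = seed)
    ds <- generate_acetylome(gen, mode = "multinomial",
                             seed = seed + 7L)$dataset
    sel <- select_high_acetyl(ds)
    counts <- table(ds$sites$protein_id)
    expect_setequal(sel$protein_id, names(counts)[counts >= 5])
    naive <- ifelse(counts == 5, "exactly_5",
                    ifelse(counts <= 10, "6-10", ">10"))[counts >= 5]
    expect_identical(sel$class_label[match(names(naive)[1],
                                           sel$protein_id)],
                     unname(naive[1]))
    expect_false(any(duplicated(sel$protein_id)))
  }
})

test_that("domain summaries count proteins and distinct species", {
  sel <- data.frame(protein_id = c("A", "B", "C"),
                    species_id = c("s1", "s1", "s2"),
                    class_label = "exactly_5")
  dm <- data.frame(protein_id = c("A", "B", "C"),
                   domain_id = "IPR013126")
  out <- summarize_domains(sel, dm)
  expect_equal(out$n_proteins, 3L)
  expect_equal(out$n_species, 2L)
  expect_lte(out$n_species, out$n_proteins)

  expect_equal(nrow(summarize_domains(sel[0, ], dm)), 0L)

  # unannotated proteins are reported, not dropped
  out <- summarize_domains(sel, dm[1:2, , drop = FALSE])
  expect_true("unannotated" %in% out$domain_id)

  # planted domain labels recovered from a generator-style ledger
  set.seed(11)
  n <- 40
  led <- data.frame(protein_id = sprintf("P%02d", 1:n),
                    species_id = sample(c("s1", "s2", "s3"), n, TRUE),
                    class_label = sample(c("exactly_5", "6-10", ">10"),
                                         n, TRUE))
  dm <- data.frame(protein_id = led$protein_id,
                   domain_id = sample(c("D1", "D2"), n, TRUE))
  out <- summarize_domains(led, dm)
  for (k in seq_len(nrow(out))) {
    sub <- merge(led, dm)[merge(led, dm)$class_label == out$class_label[k] &
                          merge(led, dm)$domain_id == out$domain_id[k], ]
    expect_equal(out$n_proteins[k], length(unique(sub$protein_id)))
    expect_equal(out$n_species[k], length(unique(sub$species_id)))
  }
})

test_that("per-protein Kac percentage uses that protein's lysine count", {
  prot <- proteome_index(c(P1 = "KKKK", P2 = "AAAA"), "sp")
  ds <- toy_dataset(c("P1", "P1"), c(1, 3), proteome = prot)
  expect_equal(protein_kac_percent("P1", ds, prot), 50)
  ds0 <- toy_dataset("P1", 1, proteome = prot)
  expect_equal(protein_kac_percent("P1", ds0, prot), 25)
  none <- toy_dataset(character(0), integer(0), proteome = prot)
  expect_equal(protein_kac_percent("P1", none, prot), 0)
  expect_error(protein_kac_percent("P2", ds, prot), "zero lysines")
  expect_error(protein_kac_percent("PX", ds, prot), "not in proteome")

  # generator plant: 3 of 12 lysines acetylated -> 25%
  prot <- proteome_index(c(P1 = strrep("KA", 12)), "sp")
  ds <- toy_dataset(rep("P1", 3), c(1, 3, 5), proteome = prot,
                    mode = "strict")
  expect_equal(protein_kac_percent("P1", ds, prot), 25)
})
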