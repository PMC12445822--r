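# Independent oracles and small builders used across the test files.
# Oracles are deliberately naive re-implementations, kept separate from
# the package code paths they check.

# Random amino-acid sequence from the 20 standard residues.
random_aa <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               n, replace = TRUE), collapse = "")
}

# Naive affine-gap global alignment score: plain scalar three-state DP,
# gap(L) = go + (L - 1) * ge.
naive_align_score <- function(seqA, seqB, sub, go = -10, ge = -0.5) {
  A <- strsplit(seqA, "")[[1]]
  B <- strsplit(seqB, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- go + (i - 1) * ge
  for (j in seq_len(m)) Y[1, j + 1] <- go + (j - 1) * ge
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub[A[i], B[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + go, X[i, j + 1] + ge)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + go, Y[i + 1, j] + ge)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Monte-Carlo rejection oracle for the free volume inside a sphere.
mc_cavity_volume <- function(atoms, center, radius = 8, probe_radius = 0,
                             n_samples = 1e6) {
  radii_tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
  pts <- matrix(runif(3 * n_samples, -radius, radius), ncol = 3)
  pts <- pts[rowSums(pts^2) <= radius^2, , drop = FALSE]
  free <- rep(TRUE, nrow(pts))
  if (nrow(atoms) > 0) {
    for (i in seq_len(nrow(atoms))) {
      r <- radii_tab[[atoms$element[i]]] + probe_radius
      d2 <- (pts[, 1] + center[1] - atoms$x[i])^2 +
        (pts[, 2] + center[2] - atoms$y[i])^2 +
        (pts[, 3] + center[3] - atoms$z[i])^2
      free <- free & d2 > r^2
    }
  }
  cube <- (2 * radius)^3
  cube * sum(free) / n_samples
}

# Transitive closure of a parent map (named list id -> parents) by
# iterated expansion; the ancestor-set oracle for the OBO DAG.
closure_oracle <- function(parents, id) {
  anc <- character(0)
  frontier <- parents[[id]]
  while (length(frontier) > 0) {
    new <- setdiff(frontier, anc)
    anc <- union(anc, new)
    frontier <- unique(unlist(parents[new], use.names = FALSE))
  }
  sort(anc)
}

# Quick builders -----------------------------------------------------------

# Proteome of n identical proteins, each the given sequence.
flat_proteome <- function(n, seq, species_id = "toy") {
  s <- setNames(rep(seq, n), sprintf("P%03d", seq_len(n)))
  proteome_index(s, species_id = species_id)
}

# Dataset from a bare (protein, position) table, unvalidated.
toy_dataset <- function(protein_id, position, id = "toy_ac",
                        species = "toy", group = "bacteria",
                        proteome = NULL, mode = "lenient") {
  acetylome_dataset(data.frame(protein_id = protein_id,
                               position = position,
                               stringsAsFactors = FALSE),
                    acetylome_id = id, species_id = species,
                    group_label = group, proteome = proteome, mode = mode)
}

extdata <- function(...) system.file("extdata", ..., package = "kacmeta")
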