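# Synthetic-data generators: every input format the pipeline consumes,
# emitted with a ledger of planted ground truth so each stage can be
# tested hermetically. All generators are pure functions of their
# arguments plus the seed.

#' Largest-remainder allocation of an integer total over proportions
#'
#' Allocates `total` integer units to bins so the realized proportions
#' match the requested ones as closely as arithmetic allows; when
#' `total * props` are integers the match is exact, which gives the test
#' suite a deterministic recovery surface.
#'
#' @param total Non-negative integer.
#' @param props Numeric proportions summing to 1.
#' @return Integer vector summing to `total`.
#' @export
largest_remainder <- function(total, props) {
  stopifnot(total >= 0, all(props >= 0),
            abs(sum(props) - 1) < 1e-9)
  raw <- total * props
  base <- floor(raw + 1e-9)
  rem <- raw - base
  k <- total - sum(base)
  if (k > 0L) {
    idx <- order(rem, seq_along(rem), decreasing = c(TRUE, FALSE),
                 method = "radix")[seq_len(k)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Generate a synthetic proteome
#'
#' Residues are drawn i.i.d. with the stated lysine frequency (default
#' 0.07, a typical proteome-wide composition) and the remaining mass
#' spread evenly over the other 19 standard residues. When `min_lysines`
#' is positive, random non-K positions are converted to K as needed so
#' every protein can carry the largest planted site count.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Inclusive bounds for uniform protein lengths.
#' @param lysine_freq Per-residue probability of K.
#' @param min_lysines Guaranteed minimum K count per protein.
#' @param species_id Species label for the index.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @param path Optional FASTA output path.
#' @return List with `proteome` (a [proteome_index()]) and `ledger`
#'   (data frame `protein_id`, `length`, `n_lysines`).
#' @export
generate_proteome <- function(n_proteins = 100L,
                              length_range = c(150L, 500L),
                              lysine_freq = 0.07, min_lysines = 0L,
                              species_id = "synthetic", seed = 1L,
                              path = NULL) {
  stopifnot(n_proteins >= 1L, lysine_freq >= 0, lysine_freq <= 1)
  if (lysine_freq == 0 && min_lysines > 0L) {
    stop("lysine_freq 0 is incompatible with min_lysines > 0")
  }
  others <- setdiff(AA_STANDARD, "K")
  probs <- c(lysine_freq, rep((1 - lysine_freq) / length(others),
                              length(others)))
  alphabet <- c("K", others)
  seqs <- with_seed(seed, {
    lens <- sample(length_range[1L]:length_range[2L], n_proteins,
                   replace = TRUE)
    vapply(lens, function(L) {
      res <- sample(alphabet, L, replace = TRUE, prob = probs)
      nk <- sum(res == "K")
      if (nk < min_lysines) {
        conv <- sample(which(res != "K"), min_lysines - nk)
        res[conv] <- "K"
      }
      paste(res, collapse = "")
    }, character(1))
  })
  names(seqs) <- sprintf("SYNP%05d", seq_len(n_proteins))
  prot <- proteome_index(seqs, species_id = species_id)
  if (!is.null(path)) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  }
  list(proteome = prot,
       ledger = data.frame(protein_id = names(seqs),
                           length = nchar(seqs),
                           n_lysines = as.integer(
                             prot$per_protein_lysines),
                           stringsAsFactors = FALSE))
}

# Draw a concrete per-protein site count for each bin label.
site_count_for_bin <- function(bin) {
  switch(bin,
         "1" = 1L, "2" = 2L,
         "3-5" = sample(3:5, 1L),
         "6-10" = sample(6:10, 1L),
         ">10" = sample(11:15, 1L),
         stop("unknown bin: ", bin))
}

#' Generate a synthetic acetylome with a planted site-count distribution
#'
#' Plants a chosen proportion of Kac proteins and a site-count-per-protein
#' distribution over the five classes 1 / 2 / 3-5 / 6-10 / >10. In
#' `deterministic_quota` mode the bin counts are fixed by largest-remainder
#' rounding, so [site_count_distribution()] recovers the planted
#' proportions exactly; in `multinomial` mode the bin membership is
#' sampled. Acetylated positions are drawn without replacement from each
#' protein's actual lysine positions, so every planted site falls on a K.
#'
#' @param proteome_gen Result of [generate_proteome()] (or a bare
#'   [proteome_index()]).
#' @param prop_kac_proteins Fraction of proteins that receive sites.
#' @param bin_props Proportions over the five site-count bins.
#' @param mode `"deterministic_quota"` or `"multinomial"`.
#' @param acetylome_id,group_label Metadata for the emitted dataset.
#' @param seed RNG seed.
#' @param path Optional TSV output path (columns protein, position).
#' @return List with `dataset` (an [acetylome_dataset()]), `ledger`
#'   (data frame `protein_id`, `n_sites`, `bin`) and `bin_counts`.
#' @export
generate_acetylome <- function(proteome_gen, prop_kac_proteins = 0.3,
                               bin_props = c(0.50, 0.20, 0.20, 0.07, 0.03),
                               mode = c("deterministic_quota",
                                        "multinomial"),
                               acetylome_id = "synthetic_acetylome",
                               group_label = "bacteria", seed = 1L,
                               path = NULL) {
  mode <- match.arg(mode)
  prot <- if (inherits(proteome_gen, "proteome_index")) proteome_gen
          else proteome_gen$proteome
  stopifnot(length(bin_props) == 5L)
  n_kac <- round(prop_kac_proteins * prot$n_proteins)
  res <- with_seed(seed, {
    bin_counts <- if (mode == "deterministic_quota") {
      largest_remainder(n_kac, bin_props)
    } else {
      as.integer(stats::rmultinom(1L, n_kac, bin_props))
    }
    wanted <- rep(SITE_BINS, bin_counts)
    nsites <- vapply(wanted, site_count_for_bin, integer(1))
    ord <- order(-nsites)
    wanted <- wanted[ord]; nsites <- nsites[ord]
    avail <- prot$per_protein_lysines
    pool <- sample(names(avail))          # random protein order
    chosen <- character(length(nsites))
    for (i in seq_along(nsites)) {
      ok <- which(avail[pool] >= nsites[i])
      if (length(ok) == 0L) {
        stop("infeasible plant: no remaining protein with >= ",
             nsites[i], " lysines")
      }
      chosen[i] <- pool[ok[1L]]
      pool <- pool[pool != chosen[i]]
    }
    sites <- do.call(rbind, lapply(seq_along(chosen), function(i) {
      kpos <- char_positions(prot$proteins[[chosen[i]]], "K")
      data.frame(protein_id = chosen[i],
                 position = sort(sample(kpos, nsites[i])),
                 stringsAsFactors = FALSE)
    }))
    list(sites = sites,
         ledger = data.frame(protein_id = chosen, n_sites = nsites,
                             bin = wanted, stringsAsFactors = FALSE),
         bin_counts = bin_counts)
  })
  if (is.null(res$sites)) {
    res$sites <- data.frame(protein_id = character(),
                            position = integer())
  }
  ds <- acetylome_dataset(res$sites, acetylome_id = acetylome_id,
                          species_id = prot$species_id,
                          group_label = group_label, proteome = prot,
                          mode = "strict")
  if (!is.null(path)) {
    utils::write.table(res$sites, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  list(dataset = ds, ledger = res$ledger,
       bin_counts = stats::setNames(res$bin_counts, SITE_BINS))
}

#' Generate gene-term annotations with one planted enriched term
#'
#' Assigns every non-planted term to genes independently of study
#' membership (pure null). When `odds_ratio > 1`, the planted term's
#' per-gene membership probability differs between study and non-study
#' genes so that the odds ratio equals the plant while the expected
#' overall term size stays at `planted_term_size`.
#'
#' @param genes Character vector, the annotation universe.
#' @param study_genes Subset of `genes` forming the study set.
#' @param n_terms Total number of terms (planted term included).
#' @param term_prob Per-gene membership probability of null terms.
#' @param planted_term_size Expected overall size of the planted term.
#' @param odds_ratio Planted study-vs-background odds ratio; 1 plants
#'   nothing (all terms null); values below 1 are rejected.
#' @param seed RNG seed.
#' @return List with `annotations` (data frame `gene`, `term`) and
#'   `ledger` (planted term id or NA, p_study, p_background, term sizes).
#' @export
generate_annotations <- function(genes, study_genes, n_terms = 20L,
                                 term_prob = 0.03,
                                 planted_term_size = 30L,
                                 odds_ratio = 1, seed = 1L) {
  stopifnot(all(study_genes %in% genes), n_terms >= 1L)
  if (odds_ratio < 1) {
    stop("odds_ratio < 1 not supported; use the two-sided test flag ",
         "for depletion designs")
  }
  N <- length(genes); nst <- length(study_genes)
  terms <- sprintf("T%04d", seq_len(n_terms))
  in_study <- genes %in% study_genes
  planted <- NA_character_
  p0 <- p1 <- planted_term_size / N
  if (odds_ratio > 1) {
    planted <- terms[1L]
    f <- function(q0) {
      o1 <- odds_ratio * q0 / (1 - q0)
      nst * o1 / (1 + o1) + (N - nst) * q0 - planted_term_size
    }
    p0 <- stats::uniroot(f, c(1e-9, planted_term_size / N))$root
    o1 <- odds_ratio * p0 / (1 - p0)
    p1 <- o1 / (1 + o1)
  }
  ann <- with_seed(seed, {
    rows <- lapply(seq_len(n_terms), function(ti) {
      pr <- if (!is.na(planted) && terms[ti] == planted) {
        ifelse(in_study, p1, p0)
      } else {
        rep(term_prob, N)
      }
      member <- stats::runif(N) < pr
      if (!any(member)) return(NULL)
      data.frame(gene = genes[member], term = terms[ti],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  sizes <- table(factor(ann$term, levels = terms))
  list(annotations = ann,
       ledger = list(planted_term = planted, p_study = p1,
                     p_background = p0,
                     term_sizes = stats::setNames(as.integer(sizes),
                                                  terms)))
}

#' Generate an ortholog family with a planted key-residue fate
#'
#' Emulates cross-species conservation panels: each target is the
#' reference with an optional N-terminal extension (shifting all
#' coordinates by its length) and random point substitutions, while the
#' key column is forced to lysine, arginine, or another residue according
#' to the plant. Protected positions (by default the key residue's
#' flanks and any supplied motif range) are never mutated, mirroring the
#' local conservation real regulatory regions show.
#'
#' @param targets Data frame with columns `name`, `n_ext` (N-terminal
#'   extension length), `mutation_rate`, `key_class`
#'   (`"K"`, `"R"` or `"other"`).
#' @param ref_length Length of the generated reference.
#' @param key_position 1-based key-lysine position in the reference.
#' @param reference Optional explicit reference sequence (named scalar);
#'   generated when NULL.
#' @param reference_id Name of the reference (default `"REF"`).
#' @param motif Optional motif string written into the reference.
#' @param motif_start Start position of `motif` in the reference.
#' @param protect Additional reference positions never mutated.
#' @param lysine_freq K frequency of the generated reference.
#' @param seed RNG seed.
#' @param path Optional FASTA output path.
#' @return List with `sequences` (named character vector, reference
#'   first) and `ledger` (data frame `name`, `key_target_position`,
#'   `key_class`).
#' @export
generate_ortholog_family <- function(targets, ref_length = 300L,
                                     key_position = 100L,
                                     reference = NULL,
                                     reference_id = "REF",
                                     motif = NULL, motif_start = NULL,
                                     protect = integer(0),
                                     lysine_freq = 0.07, seed = 1L,
                                     path = NULL) {
  stopifnot(all(c("name", "n_ext", "mutation_rate", "key_class") %in%
                names(targets)),
            all(targets$key_class %in% c("K", "R", "other")))
  others <- setdiff(AA_STANDARD, "K")
  out <- with_seed(seed, {
    if (is.null(reference)) {
      probs <- c(lysine_freq, rep((1 - lysine_freq) / length(others),
                                  length(others)))
      ref <- sample(c("K", others), ref_length, replace = TRUE,
                    prob = probs)
    } else {
      ref <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
      ref_length <- length(ref)
    }
    if (!is.null(motif)) {
      stopifnot(!is.null(motif_start),
                motif_start + nchar(motif) - 1L <= ref_length)
      ref[motif_start:(motif_start + nchar(motif) - 1L)] <-
        strsplit(toupper(motif), "", fixed = TRUE)[[1]]
    }
    stopifnot(key_position >= 1L, key_position <= ref_length)
    ref[key_position] <- "K"
    protected <- unique(c(protect,
                          max(1L, key_position - 3L):
                            min(ref_length, key_position + 3L),
                          if (!is.null(motif))
                            motif_start:(motif_start + nchar(motif) - 1L)))
    seqs <- stats::setNames(paste(ref, collapse = ""), reference_id)
    led <- list()
    for (r in seq_len(nrow(targets))) {
      tg <- targets[r, ]
      body <- ref
      mut <- which(stats::runif(ref_length) < tg$mutation_rate)
      mut <- setdiff(mut, protected)
      body[mut] <- vapply(body[mut], function(res) {
        sample(setdiff(AA_STANDARD, res), 1L)
      }, character(1))
      body[key_position] <- switch(tg$key_class, K = "K", R = "R",
                                   other = "A")
      ext <- if (tg$n_ext > 0L) {
        sample(AA_STANDARD, tg$n_ext, replace = TRUE)
      } else character(0)
      seqs[tg$name] <- paste(c(ext, body), collapse = "")
      led[[r]] <- data.frame(
        name = tg$name,
        key_target_position = key_position + tg$n_ext,
        key_class = tg$key_class, stringsAsFactors = FALSE)
    }
    list(sequences = seqs, ledger = do.call(rbind, led))
  })
  if (!is.null(path)) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(out$sequences),
                                path)
  }
  out
}

#' Generate a synthetic multi-model structure fixture
#'
#' Places atoms at recorded coordinates in a spherical shell around a
#' center and, across models, scales them radially by
#' `1 + oscillation * sin(2 * pi * (m - 1) / n_models)` — a "breathing"
#' toy that exercises per-frame cavity-volume and distance measurements.
#'
#' @param n_atoms Number of atoms (0 allowed: emits an empty-model file).
#' @param n_models Number of MODEL frames.
#' @param center Center of the shell.
#' @param shell Radial bounds (Angstrom) for atom placement.
#' @param oscillation Relative radial oscillation amplitude.
#' @param elements Elements to sample atoms from.
#' @param seed RNG seed.
#' @param path Optional multi-model PDB output path.
#' @return List with `frames` (list of `structure_frame`), `ledger`
#'   (base coordinates matrix plus per-model scale factors).
#' @export
generate_structure_fixture <- function(n_atoms = 20L, n_models = 1L,
                                       center = c(0, 0, 0),
                                       shell = c(3, 7), oscillation = 0,
                                       elements = c("C", "N", "O", "S"),
                                       seed = 1L, path = NULL) {
  stopifnot(n_atoms >= 0L, n_models >= 1L)
  gen <- with_seed(seed, {
    if (n_atoms > 0L) {
      dirs <- matrix(stats::rnorm(3L * n_atoms), ncol = 3L)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      rad <- stats::runif(n_atoms, shell[1L], shell[2L])
      base <- dirs * rad
      el <- sample(elements, n_atoms, replace = TRUE)
    } else {
      base <- matrix(numeric(0), ncol = 3L)
      el <- character(0)
    }
    list(base = base, el = el)
  })
  scales <- 1 + oscillation * sin(2 * pi * (seq_len(n_models) - 1L) /
                                  n_models)
  frames <- lapply(seq_len(n_models), function(m) {
    co <- gen$base * scales[m]
    structure_frame(
      data.frame(resno = seq_len(n_atoms),
                 resid = rep("GLY", n_atoms),
                 atom_name = rep("CA", n_atoms),
                 element = gen$el,
                 x = co[, 1L] + center[1L],
                 y = co[, 2L] + center[2L],
                 z = co[, 3L] + center[3L],
                 stringsAsFactors = FALSE),
      frame_index = m)
  })
  if (!is.null(path)) {
    lines <- character(0)
    for (m in seq_len(n_models)) {
      lines <- c(lines, sprintf("MODEL     %4d", m))
      at <- frames[[m]]$atoms
      for (i in seq_len(nrow(at))) {
        lines <- c(lines, sprintf(
          "ATOM  %5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i, " CA ", " ", at$resid[i], "A", at$resno[i], " ",
          at$x[i], at$y[i], at$z[i], 1.00, 0.00, at$element[i]))
      }
      lines <- c(lines, "ENDMDL")
    }
    writeLines(c(lines, "END"), path)
  }
  list(frames = frames,
       ledger = list(base_coords = gen$base, elements = gen$el,
                     scale_factors = scales, center = center))
}
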