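# Reading, validation and indexing of proteomes and acetylome site tables.

GROUP_LABELS <- c("archaea", "bacteria", "fungi", "protozoa", "worms",
                  "plants", "insects", "fish", "mammals")

#' Build a proteome index from named sequences
#'
#' A proteome index holds one amino-acid sequence per protein together with
#' per-protein and total lysine counts. Lysines are counted
#' case-insensitively; ambiguity codes (X/B/Z/U) are never counted as K.
#' These counts are the denominators of all proteome-normalized acetylation
#' metrics.
#'
#' @param sequences Named character vector of amino-acid sequences
#'   (1-based residue numbering). Names are protein identifiers and must be
#'   unique.
#' @param species_id Short species label.
#' @return An object of class `proteome_index` with elements `species_id`,
#'   `proteins` (named character vector, upper-cased), `n_proteins`,
#'   `n_lysines_total` and `per_protein_lysines`.
#' @export
proteome_index <- function(sequences, species_id) {
  if (length(sequences) == 0L) {
    stop("proteome is empty")
  }
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("all sequences must be named with a protein_id")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate protein_id(s): ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(sequences)
  bad <- grepl(sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")), seqs)
  if (any(bad)) {
    stop("sequence(s) with illegal residue characters: ",
         paste(utils::head(ids[bad], 5L), collapse = ", "))
  }
  perk <- count_char(seqs, "K")
  names(perk) <- ids
  structure(
    list(species_id = species_id,
         proteins = stats::setNames(as.character(seqs), ids),
         n_proteins = length(seqs),
         n_lysines_total = sum(perk),
         per_protein_lysines = perk),
    class = "proteome_index")
}

#' Read a proteome FASTA file into a proteome index
#'
#' @param path Path to a FASTA file.
#' @param species_id Short species label.
#' @param id_pattern Optional regular expression with one capture group
#'   applied to the full FASTA header to extract the protein identifier
#'   (e.g. `"^sp\\|([^|]+)\\|"` for UniProt `sp|ACC|NAME` headers). By
#'   default the identifier is the first whitespace-delimited header token.
#' @return A [proteome_index()].
#' @export
read_proteome_fasta <- function(path, species_id, id_pattern = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    stop("empty FASTA file: ", path)
  }
  headers <- names(aa)
  if (is.null(id_pattern)) {
    ids <- sub("\\s.*$", "", headers)
  } else {
    m <- regexec(id_pattern, headers)
    ids <- vapply(regmatches(headers, m), function(g) {
      if (length(g) >= 2L) g[2L] else NA_character_
    }, character(1))
    if (anyNA(ids)) {
      stop("id_pattern failed to match header(s): ",
           paste(utils::head(headers[is.na(ids)], 3L), collapse = "; "))
    }
  }
  seqs <- stats::setNames(as.character(aa), ids)
  proteome_index(seqs, species_id = species_id)
}

#' Construct an acetylome dataset from a site table
#'
#' Sites are deduplicated on (protein_id, position) and validated against a
#' proteome when one is supplied. In `strict` mode any position that does
#' not fall on a lysine of a known protein is an error; in `lenient` mode
#' (the default, appropriate for published tables built on proteome releases
#' one may not hold) mismatches are retained but flagged in the attached
#' validation report.
#'
#' @param sites Data frame with columns `protein_id` and `position`
#'   (1-based residue index).
#' @param acetylome_id Identifier of the acetylome (study).
#' @param species_id Species label.
#' @param group_label One of archaea, bacteria, fungi, protozoa, worms,
#'   plants, insects, fish, mammals.
#' @param proteome Optional [proteome_index()] used for validation.
#' @param mode `"lenient"` (flag mismatches) or `"strict"` (error).
#' @return Object of class `acetylome_dataset`: `acetylome_id`,
#'   `species_id`, `group_label`, `sites` (deduplicated data frame with
#'   `protein_id`, `position`, `residue_observed`, `source_acetylome_id`,
#'   `status`), `kac_proteins` and a `validation` count summary.
#' @export
acetylome_dataset <- function(sites, acetylome_id, species_id,
                              group_label = "bacteria",
                              proteome = NULL,
                              mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  group_label <- match.arg(group_label, GROUP_LABELS)
  stopifnot(is.data.frame(sites),
            all(c("protein_id", "position") %in% names(sites)))
  n_input <- nrow(sites)
  sites$protein_id <- as.character(sites$protein_id)
  sites$position <- as.integer(sites$position)
  if (n_input > 0L && any(sites$position < 1L, na.rm = TRUE)) {
    stop("site positions must be >= 1")
  }
  # collapse duplicate (protein_id, position) pairs
  key <- paste(sites$protein_id, sites$position, sep = "\r")
  sites <- sites[!duplicated(key), , drop = FALSE]
  n_dedup <- nrow(sites)

  status <- rep("valid", n_dedup)
  residue <- rep(NA_character_, n_dedup)
  if (!is.null(proteome) && n_dedup > 0L) {
    known <- sites$protein_id %in% names(proteome$proteins)
    status[!known] <- "unmapped"
    idx <- which(known)
    if (length(idx) > 0L) {
      residue[idx] <- substring(proteome$proteins[sites$protein_id[idx]],
                                sites$position[idx], sites$position[idx])
      residue[idx][residue[idx] == ""] <- NA_character_
      off <- idx[is.na(residue[idx])]
      status[off] <- "unmapped"          # position beyond sequence end
      mk <- idx[!is.na(residue[idx]) & residue[idx] != "K"]
      status[mk] <- "mismatch"
    }
    if (mode == "strict" && any(status != "valid")) {
      bad <- which(status != "valid")
      stop("strict validation failed for ", length(bad), " site(s): ",
           paste(utils::head(sprintf("%s:%d [%s]", sites$protein_id[bad],
                                     sites$position[bad], status[bad]), 10L),
                 collapse = ", "))
    }
  } else if (n_dedup > 0L) {
    residue <- rep("K", n_dedup)  # unvalidated: taken at face value
  }
  sites$residue_observed <- ifelse(status == "valid" & is.na(residue),
                                   "K", residue)
  sites$source_acetylome_id <- rep(acetylome_id, nrow(sites))
  sites$status <- status
  rownames(sites) <- NULL

  validation <- c(n_input_rows = n_input,
                  n_after_dedup = n_dedup,
                  n_valid = sum(status == "valid"),
                  n_mismatch = sum(status == "mismatch"),
                  n_unmapped = sum(status == "unmapped"))
  structure(
    list(acetylome_id = acetylome_id,
         species_id = species_id,
         group_label = group_label,
         sites = sites,
         kac_proteins = unique(sites$protein_id),
         validation = validation),
    class = "acetylome_dataset")
}

#' Read a delimited acetylome table
#'
#' Published acetylome supplementary tables differ in layout; a dialect
#' configuration names the columns to use. Either a numeric position column
#' or a "K123"-style site-string column must be named.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect List with elements `protein_col` (required), and either
#'   `position_col` or `site_col`; optional `sep` (default tab),
#'   `site_pattern` (default `"K(\\d+)"`, first capture group = position)
#'   and `positions_base` (default 1; set 0 for 0-based tables).
#' @param proteome Optional [proteome_index()] for validation.
#' @inheritParams acetylome_dataset
#' @return An [acetylome_dataset()].
#' @export
read_acetylome_table <- function(path, dialect, acetylome_id, species_id,
                                 group_label = "bacteria", proteome = NULL,
                                 mode = c("lenient", "strict")) {
  sep <- dialect$sep %||% "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (is.null(dialect$protein_col) ||
      !dialect$protein_col %in% names(tab)) {
    stop("dialect$protein_col missing or not a column of ", path)
  }
  protein <- as.character(tab[[dialect$protein_col]])
  if (!is.null(dialect$position_col)) {
    if (!dialect$position_col %in% names(tab)) {
      stop("position column '", dialect$position_col, "' not found")
    }
    pos <- as.integer(tab[[dialect$position_col]])
  } else if (!is.null(dialect$site_col)) {
    if (!dialect$site_col %in% names(tab)) {
      stop("site column '", dialect$site_col, "' not found")
    }
    pat <- dialect$site_pattern %||% "K(\\d+)"
    m <- regexec(pat, as.character(tab[[dialect$site_col]]))
    pos <- vapply(regmatches(as.character(tab[[dialect$site_col]]), m),
                  function(g) if (length(g) >= 2L) as.integer(g[2L])
                              else NA_integer_, integer(1))
    if (anyNA(pos)) {
      stop("site_pattern failed on ", sum(is.na(pos)), " row(s)")
    }
  } else {
    stop("dialect must name position_col or site_col")
  }
  base <- dialect$positions_base %||% 1L
  if (base == 0L) pos <- pos + 1L
  acetylome_dataset(data.frame(protein_id = protein, position = pos,
                               stringsAsFactors = FALSE),
                    acetylome_id = acetylome_id, species_id = species_id,
                    group_label = group_label, proteome = proteome,
                    mode = mode)
}

#' Merge acetylome datasets
#'
#' @param datasets List of [acetylome_dataset()] objects.
#' @param level `"per_acetylome"` returns the input unchanged;
#'   `"per_species_union"` takes, per species, the set union of
#'   (protein, position) sites over that species' acetylomes.
#' @return List of `acetylome_dataset` objects (one per species for
#'   `per_species_union`).
#' @export
merge_datasets <- function(datasets,
                           level = c("per_acetylome", "per_species_union")) {
  level <- match.arg(level)
  stopifnot(length(datasets) > 0L,
            all(vapply(datasets, inherits, logical(1), "acetylome_dataset")))
  if (level == "per_acetylome") {
    return(datasets)
  }
  species <- vapply(datasets, `[[`, character(1), "species_id")
  out <- lapply(split(datasets, species), function(dss) {
    groups <- unique(vapply(dss, `[[`, character(1), "group_label"))
    if (length(groups) > 1L) {
      stop("conflicting group_label for species ", dss[[1L]]$species_id,
           ": ", paste(groups, collapse = ", "))
    }
    sites <- do.call(rbind, lapply(dss, `[[`, "sites"))
    ds <- acetylome_dataset(
      sites[, c("protein_id", "position")],
      acetylome_id = paste0(dss[[1L]]$species_id, "_union"),
      species_id = dss[[1L]]$species_id,
      group_label = groups)
    ds
  })
  unname(out)
}

#' Serialize an acetylome dataset to JSON
#' @param dataset An [acetylome_dataset()].
#' @param path Output file path.
#' @export
write_acetylome_json <- function(dataset, path) {
  stopifnot(inherits(dataset, "acetylome_dataset"))
  obj <- list(acetylome_id = dataset$acetylome_id,
              species_id = dataset$species_id,
              group_label = dataset$group_label,
              sites = dataset$sites[, c("protein_id", "position")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an acetylome dataset from JSON written by [write_acetylome_json()]
#' @param path Input file path.
#' @param proteome Optional proteome for re-validation.
#' @param mode Validation mode, see [acetylome_dataset()].
#' @export
read_acetylome_json <- function(path, proteome = NULL,
                                mode = c("lenient", "strict")) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sites <- as.data.frame(obj$sites)
  if (nrow(sites) == 0L) {
    sites <- data.frame(protein_id = character(), position = integer())
  }
  acetylome_dataset(sites, acetylome_id = obj$acetylome_id,
                    species_id = obj$species_id,
                    group_label = obj$group_label,
                    proteome = proteome, mode = mode)
}

#' @export
print.proteome_index <- function(x, ...) {
  cat(sprintf("<proteome_index> %s: %d proteins, %d lysines\n",
              x$species_id, x$n_proteins, x$n_lysines_total))
  invisible(x)
}

#' @export
print.acetylome_dataset <- function(x, ...) {
  cat(sprintf("<acetylome_dataset> %s (%s, %s): %d sites on %d proteins\n",
              x$acetylome_id, x$species_id, x$group_label,
              nrow(x$sites), length(x$kac_proteins)))
  invisible(x)
}
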