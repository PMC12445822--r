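# Cross-species projection of regulatory lysines: global pairwise
# alignment, percent identity, site projection/classification, motif scan.

# Load the standard BLOSUM62 substitution matrix shipped with Biostrings.
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Global pairwise alignment (Needleman-Wunsch with affine gaps)
#'
#' Aligns two amino-acid sequences end-to-end with the Gotoh three-state
#' dynamic program. A gap of length L scores
#' `gap_open + (L - 1) * gap_extend` (i.e. the first gapped position pays
#' the opening penalty, each further position the extension penalty).
#' Traceback ties are broken deterministically: diagonal over up (gap in
#' B) over left (gap in A).
#'
#' @param seqA,seqB Non-empty amino-acid sequences (character scalars).
#' @param substitution_matrix Square scored matrix with residue dimnames;
#'   default BLOSUM62.
#' @param gap_open Score for opening a gap (default -10).
#' @param gap_extend Score for each additional gapped position
#'   (default -0.5).
#' @return Object of class `pairwise_alignment`: list with `alignedA`,
#'   `alignedB` (gapped strings of equal length), `score`, and `map`
#'   (data frame `column`, `posA`, `posB`; NA where gapped).
#' @export
global_align <- function(seqA, seqB, substitution_matrix = NULL,
                         gap_open = -10, gap_extend = -0.5) {
  sub <- substitution_matrix %||% blosum62()
  A <- strsplit(toupper(seqA), "", fixed = TRUE)[[1]]
  B <- strsplit(toupper(seqB), "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  if (n == 0L || m == 0L) stop("sequences must be non-empty")
  bad <- setdiff(unique(c(A, B)), rownames(sub))
  if (length(bad) > 0L) {
    stop("character(s) not in substitution matrix: ",
         paste(bad, collapse = ", "))
  }
  NEG <- -1e18
  # state matrices over (0..n) x (0..m); M ends in a match/mismatch,
  # X with A-residue over gap ("up"), Y with gap over B-residue ("left")
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  if (n >= 1L) X[2L:(n + 1L), 1L] <- gap_open + (0:(n - 1L)) * gap_extend
  if (m >= 1L) Y[1L, 2L:(m + 1L)] <- gap_open + (0:(m - 1L)) * gap_extend
  Bidx <- match(B, colnames(sub))
  for (i in 2L:(n + 1L)) {
    srow <- sub[A[i - 1L], Bidx]                    # scores vs all of B
    prevbest <- pmax(M[i - 1L, ], X[i - 1L, ], Y[i - 1L, ])
    M[i, 2L:(m + 1L)] <- prevbest[1L:m] + srow
    X[i, ] <- pmax(M[i - 1L, ] + gap_open, X[i - 1L, ] + gap_extend)
    # Y within the row is a running max: unroll the recurrence
    # Y[i,j] = max_{k<j}( M[i,k] + gap_open + (j-1-k) * gap_extend )
    z <- M[i, 1L:m] + gap_open - (0:(m - 1L)) * gap_extend
    Y[i, 2L:(m + 1L)] <- cummax(z) + (0:(m - 1L)) * gap_extend
  }
  score <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])

  # traceback; tie priority M (diagonal) > X (up) > Y (left)
  st <- c("M", "X", "Y")[which.max(c(M[n + 1L, m + 1L],
                                     X[n + 1L, m + 1L],
                                     Y[n + 1L, m + 1L]))]
  i <- n + 1L; j <- m + 1L
  outA <- character(0); outB <- character(0)
  tol <- 1e-9
  while (i > 1L || j > 1L) {
    if (st == "M") {
      outA <- c(A[i - 1L], outA); outB <- c(B[j - 1L], outB)
      s <- sub[A[i - 1L], B[j - 1L]]
      prev <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      st <- c("M", "X", "Y")[which(abs(prev + s - M[i, j]) < tol)[1L]]
      i <- i - 1L; j <- j - 1L
    } else if (st == "X") {
      outA <- c(A[i - 1L], outA); outB <- c("-", outB)
      st <- if (abs(M[i - 1L, j] + gap_open - X[i, j]) < tol) "M" else "X"
      i <- i - 1L
    } else {
      outA <- c("-", outA); outB <- c(B[j - 1L], outB)
      st <- if (abs(M[i, j - 1L] + gap_open - Y[i, j]) < tol) "M" else "Y"
      j <- j - 1L
    }
  }
  gA <- paste(outA, collapse = ""); gB <- paste(outB, collapse = "")
  posA <- cumsum(outA != "-"); posA[outA == "-"] <- NA_integer_
  posB <- cumsum(outB != "-"); posB[outB == "-"] <- NA_integer_
  structure(
    list(alignedA = gA, alignedB = gB, score = score,
         map = data.frame(column = seq_along(outA), posA = posA,
                          posB = posB)),
    class = "pairwise_alignment")
}

#' Percent identity of a pairwise alignment
#'
#' 100 x (columns with identical residues) / (columns where at least one
#' sequence has a residue). Columns gapped in both sequences (possible in
#' slices of multiple alignments) are excluded from the denominator.
#'
#' @param alignment A `pairwise_alignment`, or a list/character vector of
#'   two equal-length gapped strings.
#' @return Percent identity on the 0-100 scale.
#' @export
percent_identity <- function(alignment) {
  if (inherits(alignment, "pairwise_alignment")) {
    ga <- alignment$alignedA; gb <- alignment$alignedB
  } else {
    ga <- alignment[[1L]]; gb <- alignment[[2L]]
  }
  a <- strsplit(toupper(ga), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(gb), "", fixed = TRUE)[[1]]
  stopifnot(length(a) == length(b))
  qual <- a != "-" | b != "-"
  if (!any(qual)) stop("no qualifying columns")
  100 * sum(a == b & a != "-" & qual) / sum(qual)
}

#' Project a reference site across ortholog sequences
#'
#' Locates the alignment column holding a reference residue (e.g. human
#' aldolase K147) in each target sequence and classifies the aligned
#' residue: `conserved_K` (lysine retained), `conservative_R` (arginine,
#' the charge-preserving substitution), `gap`, or `other`. When acetylome
#' site lists are supplied the projected target position is additionally
#' flagged as acetylated or not.
#'
#' @param sequences Named character vector of ungapped sequences including
#'   the reference, or a named list of equal-length gapped strings (a
#'   pre-computed multiple alignment, which then takes precedence over
#'   pairwise alignment).
#' @param reference_id Name of the reference sequence.
#' @param position 1-based residue position in the (ungapped) reference.
#' @param kac_sites Optional named list: target name -> integer vector of
#'   acetylated positions in that target.
#' @param ... Passed to [global_align()] (substitution matrix, gap scores).
#' @return Data frame with `target`, `aligned_residue`, `target_position`,
#'   `class`, and `acetylated` (NA when no site list given).
#' @export
project_site <- function(sequences, reference_id, position,
                         kac_sites = NULL, ...) {
  stopifnot(!is.null(names(sequences)),
            reference_id %in% names(sequences))
  seqs <- vapply(sequences, function(s) toupper(as.character(s)),
                 character(1))
  is_msa <- any(grepl("-", seqs, fixed = TRUE)) &&
    length(unique(nchar(seqs))) == 1L
  ref_ungapped <- gsub("-", "", seqs[[reference_id]], fixed = TRUE)
  if (position < 1L || position > nchar(ref_ungapped)) {
    stop("reference position ", position, " outside sequence (length ",
         nchar(ref_ungapped), ")")
  }
  ref_res <- substring(ref_ungapped, position, position)
  if (ref_res != "K") {
    warning("reference residue at position ", position, " is '", ref_res,
            "', not K")
  }
  targets <- setdiff(names(seqs), reference_id)
  classify <- function(res) {
    if (res == "-") "gap"
    else if (res == "K") "conserved_K"
    else if (res == "R") "conservative_R"
    else "other"
  }
  rows <- lapply(targets, function(tg) {
    if (is_msa) {
      refchars <- strsplit(seqs[[reference_id]], "", fixed = TRUE)[[1]]
      col <- which(cumsum(refchars != "-") == position &
                   refchars != "-")[1L]
      tchars <- strsplit(seqs[[tg]], "", fixed = TRUE)[[1]]
      res <- tchars[col]
      tpos <- if (res == "-") NA_integer_ else sum(tchars[1:col] != "-")
    } else {
      al <- global_align(ref_ungapped,
                         gsub("-", "", seqs[[tg]], fixed = TRUE), ...)
      row <- al$map[which(al$map$posA == position), , drop = FALSE]
      tpos <- row$posB[1L]
      res <- if (is.na(tpos)) "-" else
        substring(al$alignedB, row$column[1L], row$column[1L])
    }
    ac <- if (is.null(kac_sites) || is.null(kac_sites[[tg]])) NA else
      !is.na(tpos) && tpos %in% kac_sites[[tg]]
    data.frame(target = tg, aligned_residue = res,
               target_position = if (is.na(tpos)) NA_integer_
                                 else as.integer(tpos),
               class = classify(res), acetylated = ac,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan a sequence for a motif with bounded mismatches
#'
#' @param sequence Amino-acid sequence.
#' @param motif Plain amino-acid motif (no wildcards).
#' @param max_mismatches Maximum Hamming mismatches allowed (default 0).
#' @return Data frame with `start`, `end` (1-based inclusive) and
#'   `n_mismatch`; zero rows when the motif is longer than the sequence or
#'   absent.
#' @export
motif_scan <- function(sequence, motif, max_mismatches = 0L) {
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  mo <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  L <- length(mo); n <- length(s)
  empty <- data.frame(start = integer(), end = integer(),
                      n_mismatch = integer())
  if (L == 0L || L > n) return(empty)
  starts <- 1:(n - L + 1L)
  mism <- vapply(starts, function(st) {
    sum(s[st:(st + L - 1L)] != mo)
  }, integer(1))
  hit <- mism <= max_mismatches
  data.frame(start = starts[hit], end = starts[hit] + L - 1L,
             n_mismatch = mism[hit])
}
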