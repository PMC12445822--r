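# Structure-based measurements: PDB frame reading, funnel-region lysine
# counts, sphere-grid cavity volume, and minimum residue distances.

# Fixed van der Waals radii (Angstrom) used for grid occlusion.
ATOMIC_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
DEFAULT_ATOM_RADIUS <- 1.70

#' Construct a structure frame from an atom table
#'
#' @param atoms Data frame with columns `resno` (1-based residue number),
#'   `resid` (residue name), `atom_name`, `element`, `x`, `y`, `z`
#'   (Angstrom). Zero rows are allowed (empty frame).
#' @param frame_index Frame number within a trajectory (default 1).
#' @param chain_id Chain identifier (default "A").
#' @return Object of class `structure_frame`.
#' @export
structure_frame <- function(atoms, frame_index = 1L, chain_id = "A") {
  need <- c("resno", "resid", "atom_name", "element", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  if (nrow(atoms) > 0L &&
      !all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  structure(list(atoms = atoms, frame_index = frame_index,
                 chain_id = chain_id),
            class = "structure_frame")
}

#' Read a (multi-model) PDB file into structure frames
#'
#' Single-model files yield one frame; each MODEL record of a multi-model
#' file (e.g. a trajectory exported as PDB) yields its own frame. Only
#' ATOM records are kept; a file without any is an error.
#'
#' @param path Path to a PDB file.
#' @return List of `structure_frame` objects.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  keep <- pdb$atom$type == "ATOM"
  if (!any(keep)) stop("no ATOM records in ", path)
  atom <- pdb$atom[keep, , drop = FALSE]
  element <- atom$elesy
  blank <- is.na(element) | !nzchar(trimws(element))
  # fall back on the first alphabetic character of the atom name
  element[blank] <- substring(gsub("[^A-Za-z].*$", "",
                                   trimws(atom$elety[blank])), 1L, 1L)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nframes <- nrow(xyz)
  cols <- as.vector(rbind(3 * which(keep) - 2L, 3 * which(keep) - 1L,
                          3 * which(keep)))
  lapply(seq_len(nframes), function(f) {
    co <- matrix(xyz[f, cols], ncol = 3L, byrow = TRUE)
    structure_frame(
      data.frame(resno = atom$resno, resid = atom$resid,
                 atom_name = trimws(atom$elety),
                 element = toupper(trimws(element)),
                 x = co[, 1L], y = co[, 2L], z = co[, 3L],
                 stringsAsFactors = FALSE),
      frame_index = f,
      chain_id = atom$chain[1L] %||% "A")
  })
}

#' Count funnel-region lysines and their acetylated subset
#'
#' For superoxide dismutase-style analyses: FK is the number of lysines
#' whose positions fall inside the named region (a set of inclusive
#' residue ranges), FKac the subset of those also present in the supplied
#' acetylated-position list.
#'
#' @param sequence Amino-acid sequence of the protein.
#' @param region Data frame with columns `start`, `end` (1-based,
#'   inclusive) or a single `c(start, end)` pair.
#' @param kac_positions Integer vector of acetylated lysine positions.
#' @return Named integer vector `c(FK = ..., FKac = ...)`.
#' @export
funnel_lysine_counts <- function(sequence, region,
                                 kac_positions = integer(0)) {
  if (!is.data.frame(region)) {
    region <- data.frame(start = region[1L], end = region[2L])
  }
  stopifnot(all(c("start", "end") %in% names(region)),
            nrow(region) > 0L, all(region$start <= region$end),
            all(region$start >= 1L))
  L <- nchar(sequence)
  if (any(region$end > L)) stop("region extends beyond sequence length ", L)
  kac_positions <- as.integer(kac_positions)
  if (length(kac_positions) > 0L &&
      (any(kac_positions < 1L) || any(kac_positions > L))) {
    stop("kac position(s) outside sequence")
  }
  kpos <- char_positions(sequence, "K")
  in_region <- rep(FALSE, L)
  for (r in seq_len(nrow(region))) {
    in_region[region$start[r]:region$end[r]] <- TRUE
  }
  fk <- kpos[in_region[kpos]]
  c(FK = length(fk), FKac = length(intersect(fk, kac_positions)))
}

resolve_probe_center <- function(frame, center) {
  if (is.numeric(center) && length(center) == 3L) {
    return(as.numeric(center))
  }
  sel <- frame$atoms$resno %in% as.integer(center)
  if (!any(sel)) {
    stop("no atoms for center residue(s): ",
         paste(center, collapse = ", "))
  }
  colMeans(frame$atoms[sel, c("x", "y", "z")])
}

#' Free cavity volume inside a probe sphere (grid counting)
#'
#' Emulates the Epock-style measurement: an axis-aligned cubic grid
#' centered on the probe center is laid over a sphere of the given radius;
#' grid points inside the sphere and farther than (atomic radius +
#' `probe_radius`) from every atom are counted as free, and the volume is
#' the free-point count times the grid-cell volume.
#'
#' @param frame A `structure_frame` (zero atoms allowed).
#' @param center Numeric xyz (Angstrom) or residue number(s) whose atom
#'   centroid defines the probe center.
#' @param radius Sphere radius in Angstrom (default 8, covering a
#'   catalytic-site cavity).
#' @param spacing Grid spacing in Angstrom (default 0.5).
#' @param probe_radius Added to each atomic radius (default 0,
#'   free-volume counting).
#' @return Volume in cubic Angstrom.
#' @export
cavity_volume <- function(frame, center, radius = 8, spacing = 0.5,
                          probe_radius = 0) {
  stopifnot(inherits(frame, "structure_frame"), radius > 0,
            spacing > 0, spacing <= radius)
  ctr <- resolve_probe_center(frame, center)
  k <- floor(radius / spacing)
  ax <- (-k:k) * spacing
  grid <- as.matrix(expand.grid(x = ctr[1L] + ax, y = ctr[2L] + ax,
                                z = ctr[3L] + ax))
  d2 <- (grid[, 1L] - ctr[1L])^2 + (grid[, 2L] - ctr[2L])^2 +
    (grid[, 3L] - ctr[3L])^2
  inside <- d2 <= radius^2
  grid <- grid[inside, , drop = FALSE]
  free <- rep(TRUE, nrow(grid))
  at <- frame$atoms
  if (nrow(at) > 0L) {
    radii <- ATOMIC_RADII[at$element]
    radii[is.na(radii)] <- DEFAULT_ATOM_RADIUS
    rocc <- (radii + probe_radius)^2
    for (ia in seq_len(nrow(at))) {
      if (!any(free)) break
      da <- (grid[, 1L] - at$x[ia])^2 + (grid[, 2L] - at$y[ia])^2 +
        (grid[, 3L] - at$z[ia])^2
      free <- free & da > rocc[ia]
    }
  }
  sum(free) * spacing^3
}

#' Minimum distance between two residue sets
#'
#' Minimum Euclidean distance over all atom pairs drawn one from each
#' residue set.
#'
#' @param frame A `structure_frame`.
#' @param residues_a,residues_b Integer vectors of residue numbers; each
#'   must resolve to at least one atom.
#' @return Distance in Angstrom.
#' @export
min_residue_distance <- function(frame, residues_a, residues_b) {
  stopifnot(inherits(frame, "structure_frame"))
  pick <- function(res) {
    miss <- setdiff(as.integer(res), frame$atoms$resno)
    if (length(miss) > 0L) {
      stop("unresolvable residue(s): ", paste(miss, collapse = ", "))
    }
    as.matrix(frame$atoms[frame$atoms$resno %in% as.integer(res),
                          c("x", "y", "z")])
  }
  A <- pick(residues_a); B <- pick(residues_b)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Cavity volume along a trajectory
#'
#' Applies [cavity_volume()] to every frame and reports the series with
#' its mean and population standard deviation (the parenthetical-SD style
#' used for reporting MD cavity volumes).
#'
#' @param frames List of `structure_frame` objects (at least one).
#' @inheritParams cavity_volume
#' @return List with `volumes` (numeric per-frame series), `mean`, `sd`
#'   (population SD).
#' @export
volume_trajectory <- function(frames, center, radius = 8, spacing = 0.5,
                              probe_radius = 0) {
  stopifnot(length(frames) >= 1L)
  v <- vapply(frames, cavity_volume, numeric(1), center = center,
              radius = radius, spacing = spacing,
              probe_radius = probe_radius)
  list(volumes = v, mean = mean(v),
       sd = sqrt(mean((v - mean(v))^2)))
}
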