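#' Construct a conformational ensemble
#'
#' A `conformational_ensemble` stores one bead per residue (typically the
#' C-alpha position) for every frame of a trajectory or multi-model structure,
#' together with per-bead scattering weights and per-frame prior weights
#' \eqn{w^0_j}.  Coordinates are in Angstrom throughout.
#'
#' @param coords numeric array `[n_frames, n_beads, 3]`, or a list of
#'   `n_beads x 3` matrices (one per frame).
#' @param bead_labels optional data frame with columns `resno` (1-based
#'   residue number) and `resname` (three-letter residue name).  Defaults to
#'   residues `1..n_beads` named `"GLY"`.
#' @param bead_weights per-bead scattering weight \eqn{f_0} (dimensionless,
#'   e.g. residue electron counts); default 1 for every bead.
#' @param prior_weights per-frame prior probability \eqn{w^0_j}; default
#'   uniform `1/n_frames`.  Renormalized to sum to 1 (with a message if the
#'   input deviated by more than 1e-6).
#'
#' @return An object of class `conformational_ensemble`: a list with elements
#'   `coords`, `bead_labels`, `bead_weights`, `prior_weights`, `n_residues`.
#' @seealso [load_ensemble()], [generate_chain_ensemble()]
#' @export
conformational_ensemble <- function(coords, bead_labels = NULL,
                                    bead_weights = NULL, prior_weights = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    nb <- vapply(coords, nrow, integer(1))
    .assert(length(unique(nb)) == 1, "frames differ in bead count")
    arr <- array(NA_real_, c(length(coords), nb[1], 3))
    for (j in seq_along(coords)) arr[j, , ] <- as.matrix(coords[[j]])
    coords <- arr
  }
  .assert(is.array(coords) && length(dim(coords)) == 3 && dim(coords)[3] == 3,
          "coords must be an [n_frames, n_beads, 3] array")
  .assert(dim(coords)[1] >= 1, "ensemble must contain at least one frame")
  .assert(all(is.finite(coords)), "coordinates contain non-finite values")
  nf <- dim(coords)[1]
  nb <- dim(coords)[2]
  if (is.null(bead_labels)) {
    bead_labels <- data.frame(resno = seq_len(nb), resname = "GLY")
  }
  .assert(nrow(bead_labels) == nb, "bead_labels must have one row per bead")
  if (is.null(bead_weights)) bead_weights <- rep(1, nb)
  .assert(length(bead_weights) == nb && all(bead_weights > 0),
          "bead_weights must be positive, one per bead")
  if (is.null(prior_weights)) prior_weights <- rep(1 / nf, nf)
  .assert(length(prior_weights) == nf, "prior_weights must have one value per frame")
  prior_weights <- .normalize_weights(prior_weights, "prior weights")
  structure(list(coords = coords, bead_labels = bead_labels,
                 bead_weights = as.numeric(bead_weights),
                 prior_weights = prior_weights, n_residues = nb),
            class = "conformational_ensemble")
}

#' @export
print.conformational_ensemble <- function(x, ...) {
  cat(sprintf("conformational_ensemble: %d frames x %d beads (Angstrom)\n",
              n_frames(x), x$n_residues))
  pw <- x$prior_weights
  cat(sprintf("  prior weights: uniform = %s\n",
              if (max(abs(pw - 1 / length(pw))) < 1e-12) "yes" else "no"))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a [conformational_ensemble()]
#' @return integer frame count
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[1]

#' Extract the coordinate matrix of one frame
#' @param ensemble a [conformational_ensemble()]
#' @param j frame index (1-based)
#' @return `n_beads x 3` numeric matrix (Angstrom)
#' @export
frame_coords <- function(ensemble, j) {
  .assert(j >= 1 && j <= n_frames(ensemble), "frame index out of range")
  matrix(ensemble$coords[j, , ], ncol = 3)
}

#' Load a conformational ensemble from file
#'
#' Reads multi-model PDB files, DCD trajectories (with a PDB topology) or the
#' package's plain-text coordinate table, and maps structures to one bead per
#' residue: either the C-alpha atom (default) or the residue centroid.
#'
#' The coordinate-table dialect is whitespace-separated with columns
#' `frame resno resname x y z` (coordinates in Angstrom); lines starting with
#' `#` are ignored.  All frames must share the same bead count and ordering.
#'
#' @param path file to read (PDB, DCD or coordinate table).
#' @param format one of `"auto"` (by extension), `"pdb"`, `"dcd"`, `"table"`.
#' @param topology PDB file defining atoms/residues; required for `"dcd"`.
#' @param mapping `"calpha"` (one bead at each C-alpha) or `"centroid"`
#'   (unweighted mean of each residue's atoms).  Ignored for tables.
#' @param weights_file optional per-frame prior weights file
#'   (see [load_weights()]); default uniform.
#'
#' @return A [conformational_ensemble()].
#' @export
load_ensemble <- function(path, format = c("auto", "pdb", "dcd", "table"),
                          topology = NULL, mapping = c("calpha", "centroid"),
                          weights_file = NULL) {
  format <- match.arg(format)
  mapping <- match.arg(mapping)
  .assert(file.exists(path), "file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", dcd = "dcd", "table")
  }
  ens <- switch(format,
    pdb = .read_pdb_ensemble(path, mapping),
    dcd = .read_dcd_ensemble(path, topology, mapping),
    table = .read_table_ensemble(path))
  if (!is.null(weights_file)) {
    w <- load_weights(weights_file)
    .assert(length(w) == n_frames(ens),
            "weights file has %d entries for %d frames", length(w), n_frames(ens))
    ens$prior_weights <- w
  }
  ens
}

.bead_map <- function(xyz_frame, resno, mapping) {
  # xyz_frame: n_atoms x 3; returns one row per residue in order of appearance
  if (mapping == "centroid") {
    g <- factor(resno, levels = unique(resno))
    counts <- as.vector(table(g))
    rowsum(xyz_frame, g, reorder = FALSE) / counts
  } else {
    xyz_frame
  }
}

.read_pdb_ensemble <- function(path, mapping) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  if (mapping == "calpha") {
    sel <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
  } else {
    sel <- bio3d::atom.select(pdb, "protein", verbose = FALSE)
  }
  .assert(length(sel$atom) > 0, "no protein atoms found in %s", path)
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  nf <- nrow(xyz)
  .assert(nf >= 1, "zero frames (models) in %s", path)
  resno <- pdb$atom$resno[sel$atom]
  resname <- pdb$atom$resid[sel$atom]
  frames <- vector("list", nf)
  for (j in seq_len(nf)) {
    m <- matrix(xyz[j, ], ncol = 3, byrow = TRUE)
    frames[[j]] <- .bead_map(m, resno, mapping)
  }
  keep <- !duplicated(resno)
  labels <- data.frame(resno = resno[keep], resname = resname[keep])
  ew <- residue_electron_counts(labels$resname, normalize = "glycine")
  conformational_ensemble(frames, bead_labels = labels, bead_weights = ew)
}

.read_dcd_ensemble <- function(path, topology, mapping) {
  .assert(!is.null(topology), "a PDB topology is required to read a DCD trajectory")
  pdb <- bio3d::read.pdb(topology, verbose = FALSE)
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  if (mapping == "calpha") {
    sel <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
  } else {
    sel <- bio3d::atom.select(pdb, "protein", verbose = FALSE)
  }
  .assert(ncol(xyz) == 3 * nrow(pdb$atom),
          "trajectory atom count does not match topology")
  xyz <- xyz[, sel$xyz, drop = FALSE]
  resno <- pdb$atom$resno[sel$atom]
  resname <- pdb$atom$resid[sel$atom]
  frames <- lapply(seq_len(nrow(xyz)), function(j) {
    .bead_map(matrix(xyz[j, ], ncol = 3, byrow = TRUE), resno, mapping)
  })
  keep <- !duplicated(resno)
  labels <- data.frame(resno = resno[keep], resname = resname[keep])
  ew <- residue_electron_counts(labels$resname, normalize = "glycine")
  conformational_ensemble(frames, bead_labels = labels, bead_weights = ew)
}

.read_table_ensemble <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("frame", "resno", "resname", "x", "y", "z"),
                           colClasses = c("integer", "integer", "character",
                                          "numeric", "numeric", "numeric"))
  .assert(nrow(tab) > 0, "zero frames in %s", path)
  fids <- unique(tab$frame)
  counts <- table(factor(tab$frame, levels = fids))
  if (length(unique(as.vector(counts))) != 1) {
    bad <- names(counts)[as.vector(counts) != as.vector(counts)[1]][1]
    stop(sprintf("inconsistent bead count in frame %s of %s", bad, path),
         call. = FALSE)
  }
  first <- tab[tab$frame == fids[1], ]
  frames <- lapply(fids, function(f) {
    sub <- tab[tab$frame == f, ]
    .assert(identical(sub$resno, first$resno),
            "frame %s bead ordering differs from frame %s", f, fids[1])
    as.matrix(sub[, c("x", "y", "z")])
  })
  labels <- data.frame(resno = first$resno, resname = first$resname)
  ew <- residue_electron_counts(labels$resname, normalize = "glycine")
  conformational_ensemble(frames, bead_labels = labels, bead_weights = ew)
}

#' Write an ensemble as a plain-text coordinate table
#'
#' Inverse of [load_ensemble()] with `format = "table"`.  Values are written
#' with 14 significant digits so a write/read round trip is lossless to at
#' least 12 significant digits.
#'
#' @param ensemble a [conformational_ensemble()]
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_ensemble_table <- function(ensemble, path) {
  nf <- n_frames(ensemble)
  nb <- ensemble$n_residues
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# frame resno resname x y z (Angstrom)", con)
  for (j in seq_len(nf)) {
    m <- frame_coords(ensemble, j)
    writeLines(sprintf("%d %d %s %.14g %.14g %.14g", j,
                       ensemble$bead_labels$resno,
                       ensemble$bead_labels$resname,
                       m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Read or write per-frame weights
#'
#' Weights files hold one non-negative float per line; blank lines and
#' `#`-comments are ignored.  Loaded weights are renormalized to sum to 1
#' (with a message if the stored values deviated by more than 1e-6).
#'
#' @param path file to read or write
#' @return `load_weights()` returns a normalized numeric vector;
#'   `save_weights()` returns `path` invisibly.
#' @export
load_weights <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  .assert(length(lines) >= 1, "no weights found in %s", path)
  w <- suppressWarnings(as.numeric(lines))
  .assert(!anyNA(w), "non-numeric weight line in %s", path)
  .normalize_weights(w, sprintf("weights from %s", path))
}

#' @param weights numeric vector of per-frame weights
#' @rdname load_weights
#' @export
save_weights <- function(weights, path) {
  weights <- .normalize_weights(weights)
  writeLines(c("# per-frame weights, normalized", sprintf("%.14g", weights)), path)
  invisible(path)
}
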