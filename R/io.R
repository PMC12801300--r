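# Input/output: xyzr and pqr atom readers, the keyword=value configuration
# dialect, and ASCII OFF/PLY triangle-mesh writers (with readers for
# round-trip checking).  All coordinates and radii are Angstrom throughout;
# no unit conversion happens anywhere in the package.

#' Atom set
#'
#' Centres and radii of the solute atoms.
#'
#' @param centers Numeric n x 3 matrix of atom centres (Angstrom).
#' @param radii Positive numeric vector of length n (Angstrom).
#' @return An object of class `atom_set` with fields `centers`, `radii`,
#'   `count`.
#' @export
atom_set <- function(centers, radii) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  radii <- as.numeric(radii)
  if (nrow(centers) < 1L) stop("atom_set needs at least one atom")
  if (length(radii) != nrow(centers)) stop("centers/radii length mismatch")
  if (!all(is.finite(centers))) stop("atom coordinates must be finite")
  if (!all(is.finite(radii)) || any(radii <= 0)) stop("all radii must be > 0")
  structure(list(centers = centers, radii = radii, count = nrow(centers)),
            class = "atom_set")
}

#' @export
print.atom_set <- function(x, ...) {
  cat(sprintf("<atom_set> %d atoms, radii [%.3g, %.3g] A\n",
              x$count, min(x$radii), max(x$radii)))
  invisible(x)
}

#' Read an xyzr file
#'
#' One atom per line, four whitespace-separated fields `x y z r` (Angstrom).
#'
#' @param path Path to the file.
#' @return An [atom_set()]; input order preserved.
#' @export
read_xyzr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("xyzr file has no records: ", path)
  vals <- matrix(NA_real_, nrow = length(keep), ncol = 4)
  for (n in seq_along(keep)) {
    ln <- keep[n]
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    if (length(tok) != 4L)
      stop(sprintf("xyzr parse error at line %d: expected 4 fields, got %d",
                   ln, length(tok)))
    v <- suppressWarnings(as.numeric(tok))
    if (any(is.na(v)))
      stop(sprintf("xyzr parse error at line %d: non-numeric field", ln))
    if (v[4] <= 0)
      stop(sprintf("xyzr parse error at line %d: radius must be > 0", ln))
    vals[n, ] <- v
  }
  atom_set(vals[, 1:3, drop = FALSE], vals[, 4])
}

#' Write an xyzr file
#'
#' @param atoms An [atom_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyzr <- function(atoms, path) {
  stopifnot(inherits(atoms, "atom_set"))
  lines <- sprintf("%.17g %.17g %.17g %.17g",
                   atoms$centers[, 1], atoms$centers[, 2], atoms$centers[, 3],
                   atoms$radii)
  writeLines(lines, path)
  invisible(path)
}

#' Read a pqr file
#'
#' Whitespace-tokenised PQR dialect (as produced by PDB2PQR): only
#' `ATOM`/`HETATM` records are used, with `x y z charge radius` taken as the
#' last five fields; the charge is discarded.  Other record types are skipped
#' silently.
#'
#' @param path Path to the file.
#' @return An [atom_set()].
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM|HETATM)\\b", lines)
  if (length(rec) == 0L) stop("pqr file has no ATOM/HETATM records: ", path)
  vals <- matrix(NA_real_, nrow = length(rec), ncol = 4)
  for (n in seq_along(rec)) {
    ln <- rec[n]
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    if (length(tok) < 6L)
      stop(sprintf("pqr parse error at line %d: too few fields", ln))
    tail5 <- suppressWarnings(as.numeric(tok[(length(tok) - 4):length(tok)]))
    if (any(is.na(tail5)))
      stop(sprintf("pqr parse error at line %d: non-numeric coordinate/radius",
                   ln))
    if (tail5[5] <= 0)
      stop(sprintf("pqr parse error at line %d: radius must be > 0", ln))
    vals[n, ] <- tail5[c(1, 2, 3, 5)]
  }
  atom_set(vals[, 1:3, drop = FALSE], vals[, 4])
}

#' Surface computation configuration
#'
#' Tunable parameters of the SES pipeline.  `grid_scale` is the inverse grid
#' spacing (grid spacing `h = 1/grid_scale` Angstrom).
#'
#' @param probe_radius Rolling-probe radius, Angstrom (water: 1.4).
#' @param grid_scale Grid scale `s` in 1/Angstrom.
#' @param halo_thickness Slab halo-layer thickness, Angstrom.
#' @param slab_count Requested number of slabs for the parallel-decomposition
#'   semantics of the SES build.
#' @param skip_strategy `"one_point"` or `"two_point"` near-pair skipping.
#' @param skip_eps Entry/exit pair-gap threshold, Angstrom.
#' @param big_probe_radius Large probe used by pocket detection, Angstrom.
#' @param smoothing_iterations Laplacian smoothing iterations.
#' @return An object of class `surface_config`.
#' @export
surface_config <- function(probe_radius = 1.4, grid_scale = 2.0,
                           halo_thickness = 12, slab_count = 1L,
                           skip_strategy = c("two_point", "one_point"),
                           skip_eps = 1e-7, big_probe_radius = 3.0,
                           smoothing_iterations = 1L) {
  skip_strategy <- match.arg(skip_strategy)
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (grid_scale <= 0) stop("grid_scale must be > 0")
  if (halo_thickness < 2 * probe_radius)
    stop("halo_thickness must be >= 2 * probe_radius")
  if (skip_eps <= 0) stop("skip_eps must be > 0")
  if (slab_count < 1) stop("slab_count must be >= 1")
  if (smoothing_iterations < 0) stop("smoothing_iterations must be >= 0")
  structure(list(probe_radius = probe_radius, grid_scale = grid_scale,
                 halo_thickness = halo_thickness,
                 slab_count = as.integer(slab_count),
                 skip_strategy = skip_strategy, skip_eps = skip_eps,
                 big_probe_radius = big_probe_radius,
                 smoothing_iterations = as.integer(smoothing_iterations)),
            class = "surface_config")
}

.config_keywords <- list(
  probe_radius = "numeric", grid_scale = "numeric",
  halo_thickness = "numeric", slab_count = "integer",
  skip_strategy = "enum", skip_eps = "numeric",
  big_probe_radius = "numeric", smoothing_iterations = "integer")

#' Read a keyword configuration file
#'
#' Lines of `keyword = value`; `#` starts a comment.  Unknown keywords are
#' logged with a warning but do not fail; missing keywords take the
#' [surface_config()] defaults.  Parsing is order-independent.
#'
#' @param path Path to the configuration file.
#' @return A [surface_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("config parse error: expected 'keyword = value' in: ", ln)
    key <- trimws(parts[1]); val <- trimws(parts[2])
    if (!key %in% names(.config_keywords)) {
      warning("unknown configuration keyword ignored: ", key)
      next
    }
    kind <- .config_keywords[[key]]
    if (kind == "enum") {
      if (!val %in% c("one_point", "two_point"))
        stop("config error: invalid value for keyword '", key, "': ", val)
      args[[key]] <- val
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num))
        stop("config error: non-numeric value for keyword '", key, "': ", val)
      args[[key]] <- if (kind == "integer") as.integer(num) else num
    }
  }
  do.call(surface_config, args)
}

#' Write a triangle mesh to OFF or PLY
#'
#' ASCII formats with 0-based vertex indices; reading the file back with
#' [read_mesh()] reproduces the vertex and triangle arrays to text precision.
#'
#' @param mesh A [tri_mesh()].
#' @param path Output path.
#' @param format `"OFF"` or `"PLY"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("OFF", "PLY")) {
  format <- match.arg(format)
  stopifnot(inherits(mesh, "tri_mesh"))
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  if (nv == 0L || nt == 0L) stop("refusing to write an empty mesh")
  vtx <- sprintf("%.10g %.10g %.10g",
                 mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  tri0 <- mesh$triangles - 1L
  fac <- sprintf("3 %d %d %d", tri0[, 1], tri0[, 2], tri0[, 3])
  out <- if (format == "OFF") {
    c("OFF", sprintf("%d %d 0", nv, nt), vtx, fac)
  } else {
    c("ply", "format ascii 1.0",
      sprintf("element vertex %d", nv),
      "property float x", "property float y", "property float z",
      sprintf("element face %d", nt),
      "property list uchar int vertex_indices", "end_header", vtx, fac)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read a triangle mesh written by [write_mesh()]
#'
#' @param path Path to an ASCII OFF or PLY file.
#' @return A [tri_mesh()] (normals are recomputed as vertex-averaged face
#'   normals since neither format stores them here).
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (identical(lines[1], "OFF")) {
    hdr <- as.integer(strsplit(trimws(lines[2]), "[[:space:]]+")[[1]])
    nv <- hdr[1]; nt <- hdr[2]
    body <- lines[-(1:2)]
  } else if (identical(lines[1], "ply")) {
    endh <- which(lines == "end_header")[1]
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
    nt <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
    body <- lines[-(1:endh)]
  } else stop("unrecognised mesh format: ", path)
  vtx <- do.call(rbind, lapply(body[seq_len(nv)], function(l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])))
  fac <- do.call(rbind, lapply(body[nv + seq_len(nt)], function(l)
    as.integer(strsplit(trimws(l), "[[:space:]]+")[[1]])[-1]))
  tri_mesh(vtx[, 1:3, drop = FALSE], fac + 1L)
}
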