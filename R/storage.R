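# Memory-lean containers used by the ray-tracing and meshing stages: a bilevel
# in/out/cavity status map (coarse cells lazily holding 4^3 fine blocks, 2 bits
# per voxel), a 32-booleans-per-word bit buffer, and three bilevel grids that
# jointly index mesh vertices and normals by grid edge.  All are mutable
# environment-backed objects, behaviourally equivalent to dense arrays.

#' Status codes of the in/out grid
#'
#' Named integer codes of the four voxel states: `outside = 0L`,
#' `inside = 1L`, `boundary = 2L`, `cavity = 3L`.  Unwritten voxels read as
#' `outside`.
#'
#' @format Named integer vector of length 4.
#' @export
ses_status <- c(outside = 0L, inside = 1L, boundary = 2L, cavity = 3L)

#' Create a bilevel status map
#'
#' A two-level in/out grid: a uniform coarse grid at one quarter of the fine
#' resolution whose cells are empty by default and lazily allocate a 4x4x4
#' fine block (2 bits per voxel) on first write.  Fine dimensions need not be
#' multiples of 4; edge blocks are full blocks with unused lanes.
#'
#' @param dims Integer length-3 fine-resolution voxel counts.
#' @return An object of class `status_map`.
#' @export
status_map <- function(dims) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1))
  cdims <- (dims + 3L) %/% 4L       # == ceiling(dims/4), power-of-two arithmetic
  e <- new.env(parent = emptyenv())
  e$dims <- dims
  e$cdims <- cdims
  e$blocks <- vector("list", prod(cdims))
  class(e) <- "status_map"
  e
}

.sm_check_idx <- function(map, i, j, k) {
  if (any(c(i, j, k) < 0L) || i >= map$dims[1] || j >= map$dims[2] || k >= map$dims[3])
    stop("status_map index out of range")
}

# coarse linear index (1-based) and fine offset (0..63) for 0-based i,j,k
.sm_locate <- function(map, i, j, k) {
  cb <- c(i %/% 4L, j %/% 4L, k %/% 4L)
  off <- c(i %% 4L, j %% 4L, k %% 4L)
  list(block = 1L + cb[1] + map$cdims[1] * (cb[2] + map$cdims[2] * cb[3]),
       voxel = off[1] + 4L * (off[2] + 4L * off[3]))
}

#' Read a voxel status
#'
#' @param map A [status_map()].
#' @param i,j,k 0-based voxel indices.
#' @return Integer status code (see [ses_status]); `outside` for voxels never
#'   written.
#' @export
status_get <- function(map, i, j, k) {
  .sm_check_idx(map, i, j, k)
  loc <- .sm_locate(map, i, j, k)
  blk <- map$blocks[[loc$block]]
  if (is.null(blk)) return(ses_status[["outside"]])
  byte <- as.integer(blk[1L + loc$voxel %/% 4L])
  (byte %/% .crumb_shift[1L + loc$voxel %% 4L]) %% 4L
}

# 2-bit lane shifts within a byte (integer powers of four)
.crumb_shift <- c(1L, 4L, 16L, 64L)

#' Write a voxel status
#'
#' Lazily allocates the containing 4^3 block.
#'
#' @inheritParams status_get
#' @param v Integer status code (see [ses_status]).
#' @return The map, invisibly (modified in place).
#' @export
status_set <- function(map, i, j, k, v) {
  .sm_check_idx(map, i, j, k)
  v <- as.integer(v)
  stopifnot(v >= 0L, v <= 3L)
  loc <- .sm_locate(map, i, j, k)
  blk <- map$blocks[[loc$block]]
  if (is.null(blk)) blk <- raw(16L)   # 64 voxels x 2 bits
  bi <- 1L + loc$voxel %/% 4L
  sh <- .crumb_shift[1L + loc$voxel %% 4L]
  byte <- as.integer(blk[bi])
  byte <- byte - ((byte %/% sh) %% 4L) * sh + v * sh
  blk[bi] <- as.raw(byte)
  map$blocks[[loc$block]] <- blk
  invisible(map)
}

#' Number of allocated fine blocks
#' @param map A [status_map()].
#' @return Integer count of 4^3 blocks currently allocated.
#' @export
status_blocks_allocated <- function(map) {
  sum(!vapply(map$blocks, is.null, logical(1)))
}

#' Expand a bilevel status map to a dense array
#'
#' @param map A [status_map()].
#' @return A 3-D integer array of status codes, elementwise equal to
#'   [status_get()].
#' @export
to_dense <- function(map) {
  stopifnot(inherits(map, "status_map"))
  arr <- array(ses_status[["outside"]], dim = map$dims)
  shifts <- .crumb_shift
  alloc <- which(!vapply(map$blocks, is.null, logical(1)))
  if (length(alloc) == 0L) return(arr)
  cd <- map$cdims
  for (bl in alloc) {
    b0 <- bl - 1L
    cx <- b0 %% cd[1]; rest <- b0 %/% cd[1]
    cy <- rest %% cd[2]; cz <- rest %/% cd[2]
    bytes <- as.integer(map$blocks[[bl]])
    vals <- as.vector(vapply(shifts, function(s) (bytes %/% s) %% 4L,
                             integer(16L)))
    # vals is ordered byte-major; reorder to voxel index 0..63
    vox <- order(rep(0:15, 4) * 4L + rep(0:3, each = 16L))
    vals <- vals[vox]
    xs <- cx * 4L + 0:3; ys <- cy * 4L + 0:3; zs <- cz * 4L + 0:3
    keep_x <- xs < map$dims[1]; keep_y <- ys < map$dims[2]; keep_z <- zs < map$dims[3]
    cube <- array(vals, dim = c(4, 4, 4))
    arr[xs[keep_x] + 1L, ys[keep_y] + 1L, zs[keep_z] + 1L] <-
      cube[keep_x, keep_y, keep_z, drop = FALSE]
  }
  arr
}

#' Fill a status map from a dense array
#'
#' Convenience constructor: voxels whose value differs from `outside` are
#' written (so the bilevel map stays sparse).
#'
#' @param arr 3-D integer array of status codes.
#' @return A [status_map()].
#' @export
status_map_from_dense <- function(arr) {
  map <- status_map(dim(arr))
  idx <- which(arr != ses_status[["outside"]], arr.ind = TRUE)
  if (nrow(idx)) {
    for (r in seq_len(nrow(idx)))
      status_set(map, idx[r, 1] - 1L, idx[r, 2] - 1L, idx[r, 3] - 1L,
                 arr[idx[r, 1], idx[r, 2], idx[r, 3]])
  }
  map
}

#' Create a packed bit buffer
#'
#' Boolean buffer storing 32 values per word (`word = i %/% 32`,
#' `bit = i %% 32`); all bits start clear.
#'
#' @param length Number of booleans.
#' @return An object of class `bit_buffer` with fields `length` and `words`.
#' @export
bit_buffer <- function(length) {
  length <- as.integer(length)
  stopifnot(length >= 0L)
  e <- new.env(parent = emptyenv())
  e$length <- length
  e$words <- numeric(max(1L, (length + 31L) %/% 32L))
  class(e) <- "bit_buffer"
  e
}

.bb_check <- function(buf, i) {
  if (any(i < 0L | i >= buf$length)) stop("bit_buffer index out of range")
}

#' Read bits
#' @param buf A [bit_buffer()].
#' @param i 0-based index (vectorised).
#' @return Logical vector.
#' @export
bit_get <- function(buf, i) {
  .bb_check(buf, i)
  w <- i %/% 32L
  p <- 2^(i %% 32L)
  (buf$words[w + 1L] %/% p) %% 2 == 1
}

#' Write bits
#' @inheritParams bit_get
#' @param v Logical value(s), recycled against `i`.
#' @return The buffer, invisibly (modified in place).
#' @export
bit_set <- function(buf, i, v) {
  .bb_check(buf, i)
  v <- rep_len(as.logical(v), length(i))
  w <- i %/% 32L + 1L
  p <- 2^(i %% 32L)
  for (n in seq_along(i)) {
    cur <- (buf$words[w[n]] %/% p[n]) %% 2 == 1
    if (cur != v[n])
      buf$words[w[n]] <- buf$words[w[n]] + if (v[n]) p[n] else -p[n]
  }
  invisible(buf)
}

#' Count of set bits
#' @param buf A [bit_buffer()].
#' @return Integer number of `TRUE` bits.
#' @export
bit_count <- function(buf) {
  if (buf$length == 0L) return(0L)
  sum(vapply(0:(buf$length - 1L), function(i) bit_get(buf, i), logical(1)))
}

#' Create a joint vertex/normal index map
#'
#' Three direction-indexed bilevel grids mapping a grid edge (direction 1, 2
#' or 3 plus the 0-based node index of its lower end) to the index of the mesh
#' vertex created on that edge; vertex positions, normals and source patch ids
#' live in growing side arrays.  One structure indexes vertices and normals
#' jointly; an edge may be written at most once per build.
#'
#' @param dims Integer length-3 node counts of the fine grid.
#' @return An object of class `vertex_index_map`.
#' @export
vertex_index_map <- function(dims) {
  dims <- as.integer(dims)
  e <- new.env(parent = emptyenv())
  e$dims <- dims
  e$cdims <- (dims + 3L) %/% 4L
  e$grids <- lapply(1:3, function(d) vector("list", prod(e$cdims)))
  e$n_vertices <- 0L
  # grown as lists to keep insertion O(1); see vim_vertex_data()
  e$positions <- list()
  e$normals <- list()
  e$patch_ids <- list()
  e$dangling <- list()
  class(e) <- "vertex_index_map"
  e
}

.vim_locate <- function(map, i, j, k) {
  cb1 <- i %/% 4L; cb2 <- j %/% 4L; cb3 <- k %/% 4L
  list(block = 1L + cb1 + map$cdims[1] * (cb2 + map$cdims[2] * cb3),
       voxel = 1L + (i %% 4L) + 4L * ((j %% 4L) + 4L * (k %% 4L)))
}

#' Look up the vertex on a grid edge
#'
#' @param map A [vertex_index_map()].
#' @param dir Edge direction, 1 (X), 2 (Y) or 3 (Z).
#' @param i,j,k 0-based node index of the edge's lower endpoint.
#' @return 1-based vertex index, or `0L` if no vertex is stored there.
#' @export
vim_get <- function(map, dir, i, j, k) {
  loc <- .vim_locate(map, i, j, k)
  blk <- map$grids[[dir]][[loc$block]]
  if (is.null(blk)) return(0L)
  blk[loc$voxel]
}

#' Store a new vertex on a grid edge
#'
#' Errors if the edge already holds a vertex (write-once contract).
#'
#' @inheritParams vim_get
#' @param position,normal Numeric length-3.
#' @param patch_id Integer id of the source patch (`NA` for dangling
#'   midpoint vertices).
#' @param dangling Logical; `TRUE` when the vertex was created at the edge
#'   midpoint for lack of an analytic intersection.
#' @return The new 1-based vertex index.
#' @export
vim_put <- function(map, dir, i, j, k, position, normal, patch_id = NA_integer_,
                    dangling = FALSE) {
  loc <- .vim_locate(map, i, j, k)
  blk <- map$grids[[dir]][[loc$block]]
  if (is.null(blk)) blk <- integer(64L)
  if (blk[loc$voxel] != 0L) stop("vertex_index_map: edge written twice")
  id <- map$n_vertices + 1L
  blk[loc$voxel] <- id
  map$grids[[dir]][[loc$block]] <- blk
  map$n_vertices <- id
  map$positions[[id]] <- as.numeric(position)
  map$normals[[id]] <- as.numeric(normal)
  map$patch_ids[[id]] <- as.integer(patch_id)
  map$dangling[[id]] <- isTRUE(dangling)
  id
}

#' Collect the vertex side arrays of a [vertex_index_map()]
#'
#' @param map A [vertex_index_map()].
#' @return List with `positions` and `normals` (n x 3 matrices), integer
#'   `patch_ids` and logical `dangling`, in vertex-index order.
#' @export
vim_vertex_data <- function(map) {
  n <- map$n_vertices
  list(positions = if (n) do.call(rbind, map$positions) else matrix(numeric(0), ncol = 3),
       normals = if (n) do.call(rbind, map$normals) else matrix(numeric(0), ncol = 3),
       patch_ids = if (n) unlist(map$patch_ids) else integer(0),
       dangling = if (n) unlist(map$dangling) else logical(0))
}
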