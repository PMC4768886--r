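#' Define a regular grid of cells with an optional buffer
#'
#' Builds the lattice on which the latent fields live. The core `nx` by
#' `ny` cells carry observations; `buffer_width` extra cells are added on
#' every side so that edge artifacts of the spatial priors are pushed away
#' from the region of interest. Buffer cells are ordinary cells with zero
#' observations; they are modeled but excluded from output products via
#' `core_mask`.
#'
#' Cells are indexed linearly in row-major order over the *buffered*
#' lattice, with the x index varying fastest. All matrices in the package
#' use this single ordering.
#'
#' @param nx,ny Number of core cells in the x and y directions.
#' @param buffer_width Number of buffer cells added on each side.
#' @param origin_x,origin_y Projected coordinates (meters) of the centroid
#'   of the first (south-west) core cell. Metadata only; the model never
#'   uses coordinates except to label output.
#' @param cell_size Cell side length in meters. Metadata only.
#' @return An object of class `grid_spec` with elements `nx`, `ny`,
#'   `buffer`, `nxb`, `nyb` (buffered dimensions), `m` (total cells) and
#'   `core_mask` (logical of length `m`).
#' @examples
#' g <- build_grid(3, 3, buffer_width = 1)
#' g$m          # 25
#' sum(g$core_mask)  # 9
#' @export
build_grid <- function(nx, ny, buffer_width = 0L,
                       origin_x = 0, origin_y = 0, cell_size = 8000) {
  if (length(nx) != 1L || length(ny) != 1L || nx < 1 || ny < 1 ||
      nx != round(nx) || ny != round(ny)) {
    stop("'nx' and 'ny' must be positive integers")
  }
  if (buffer_width < 0 || buffer_width != round(buffer_width)) {
    stop("'buffer_width' must be a nonnegative integer")
  }
  nx <- as.integer(nx); ny <- as.integer(ny)
  b <- as.integer(buffer_width)
  nxb <- nx + 2L * b
  nyb <- ny + 2L * b
  m <- nxb * nyb
  ix <- rep(seq_len(nxb), times = nyb)
  iy <- rep(seq_len(nyb), each = nxb)
  core_mask <- ix > b & ix <= b + nx & iy > b & iy <= b + ny
  structure(
    list(nx = nx, ny = ny, buffer = b, nxb = nxb, nyb = nyb, m = m,
         origin_x = origin_x, origin_y = origin_y, cell_size = cell_size,
         core_mask = core_mask),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d core cells, buffer %d (%d x %d = %d total)\n",
              x$nx, x$ny, x$buffer, x$nxb, x$nyb, x$m))
  invisible(x)
}

#' Linear cell index from buffered lattice coordinates
#'
#' @param grid A `grid_spec`.
#' @param ix,iy Coordinates on the buffered lattice, `1..nxb` / `1..nyb`.
#' @return Integer linear indices (row-major, x fastest).
#' @export
cell_index <- function(grid, ix, iy) {
  if (any(ix < 1 | ix > grid$nxb | iy < 1 | iy > grid$nyb)) {
    stop("cell coordinates outside the buffered lattice")
  }
  (as.integer(iy) - 1L) * grid$nxb + as.integer(ix)
}

#' Buffered lattice coordinates from a linear index
#' @param grid A `grid_spec`.
#' @param idx Linear cell indices.
#' @return A two-column integer matrix with columns `ix`, `iy`.
#' @export
cell_coords <- function(grid, idx) {
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > grid$m)) stop("cell index out of range")
  ix <- (idx - 1L) %% grid$nxb + 1L
  iy <- (idx - 1L) %/% grid$nxb + 1L
  cbind(ix = ix, iy = iy)
}

#' Linear cell index from core-grid coordinates
#'
#' External tables address cells in core coordinates `1..nx`, `1..ny`;
#' this maps them onto the buffered lattice used internally.
#' @param grid A `grid_spec`.
#' @param cx,cy Core coordinates.
#' @return Integer linear indices on the buffered lattice.
#' @export
core_index <- function(grid, cx, cy) {
  if (any(cx < 1 | cx > grid$nx | cy < 1 | cy > grid$ny)) {
    stop("cell coordinates outside the core grid")
  }
  cell_index(grid, as.integer(cx) + grid$buffer, as.integer(cy) + grid$buffer)
}

#' Projected centroid coordinates of cells
#' @param grid A `grid_spec`.
#' @param idx Linear indices; defaults to all cells.
#' @return Two-column matrix of x/y centroid coordinates in meters.
#' @export
cell_centers <- function(grid, idx = seq_len(grid$m)) {
  co <- cell_coords(grid, idx)
  cbind(x = grid$origin_x + (co[, "ix"] - grid$buffer - 1) * grid$cell_size,
        y = grid$origin_y + (co[, "iy"] - grid$buffer - 1) * grid$cell_size)
}

#' Cardinal-neighbor adjacency of a grid
#'
#' Two cells are neighbors iff they differ by exactly one step along
#' exactly one axis (the four cardinal neighbors). Interior cells have
#' degree 4, edge cells 3, corner cells 2.
#'
#' @param grid A `grid_spec`.
#' @return An object of class `cell_adjacency`: list with `C` (sparse
#'   symmetric 0/1 matrix, zero diagonal), `degree` (row sums) and `grid`.
#' @export
cardinal_adjacency <- function(grid) {
  nxb <- grid$nxb; nyb <- grid$nyb; m <- grid$m
  # horizontal edges: (ix, iy) -- (ix + 1, iy)
  if (nxb > 1L) {
    ixh <- rep(seq_len(nxb - 1L), times = nyb)
    iyh <- rep(seq_len(nyb), each = nxb - 1L)
    hi <- (iyh - 1L) * nxb + ixh
    hk <- hi + 1L
  } else hi <- hk <- integer(0)
  # vertical edges: (ix, iy) -- (ix, iy + 1)
  if (nyb > 1L) {
    vi <- seq_len(nxb * (nyb - 1L))
    vk <- vi + nxb
  } else vi <- vk <- integer(0)
  C <- Matrix::sparseMatrix(i = c(hi, vi), j = c(hk, vk), x = 1,
                            dims = c(m, m), symmetric = TRUE)
  structure(list(C = C, degree = Matrix::rowSums(C), grid = grid),
            class = "cell_adjacency")
}

#' @export
print.cell_adjacency <- function(x, ...) {
  cat(sprintf("cell_adjacency: %d cells, %d undirected edges\n",
              length(x$degree), sum(x$degree) / 2))
  invisible(x)
}

#' Normalize areal-overlap weights between townships and grid cells
#'
#' Townships are irregular areal units whose trees have unknown within-unit
#' locations; each township places prior mass on the grid cells it overlaps,
#' proportional to the overlap area. This normalizes raw overlap areas to
#' weights summing to one per township and drops zero-area entries.
#'
#' @param raw A data frame with columns `township_id`, `cell` (linear cell
#'   index on the buffered lattice) and `area` (nonnegative raw overlap
#'   area). Alternatively columns `cell_x`, `cell_y` in core coordinates
#'   may be given together with `grid`.
#' @param grid Optional `grid_spec`, required when cells are addressed by
#'   core coordinates, and used to validate indices when supplied.
#' @return An object of class `township_overlap`: list with `table` (data
#'   frame `township_id`, `cell`, `psi`) and `townships` (unique ids, in
#'   order of first appearance).
#' @export
normalize_overlap <- function(raw, grid = NULL) {
  raw <- as.data.frame(raw)
  if (!"cell" %in% names(raw)) {
    if (is.null(grid) || !all(c("cell_x", "cell_y") %in% names(raw))) {
      stop("'raw' must have a 'cell' column, or 'cell_x'/'cell_y' plus 'grid'")
    }
    raw$cell <- core_index(grid, raw$cell_x, raw$cell_y)
  }
  if (!all(c("township_id", "area") %in% names(raw))) {
    stop("'raw' must have columns 'township_id' and 'area'")
  }
  if (any(!is.finite(raw$area)) || any(raw$area < 0)) {
    bad <- which(!is.finite(raw$area) | raw$area < 0)
    stop("negative or non-finite overlap area at row(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  if (!is.null(grid) && any(raw$cell < 1 | raw$cell > grid$m)) {
    stop("overlap table references cells outside the grid")
  }
  ids <- unique(raw$township_id)
  tot <- tapply(raw$area, factor(raw$township_id, levels = ids), sum)
  if (any(tot <= 0)) {
    stop("township(s) with zero total overlap area: ",
         paste(head(ids[tot <= 0], 5), collapse = ", "))
  }
  keep <- raw$area > 0
  out <- raw[keep, c("township_id", "cell", "area")]
  out$psi <- out$area / as.numeric(tot[match(out$township_id, ids)])
  out$area <- NULL
  rownames(out) <- NULL
  structure(list(table = out, townships = ids), class = "township_overlap")
}

#' @export
print.township_overlap <- function(x, ...) {
  cat(sprintf("township_overlap: %d townships over %d (township, cell) pairs\n",
              length(x$townships), nrow(x$table)))
  invisible(x)
}

# Number of connected components of the adjacency graph (BFS on the
# sparse pattern); needed for the generalized determinant rank of the
# intrinsic CAR precision.
n_components <- function(adj) {
  m <- length(adj$degree)
  Cp <- as(adj$C, "generalMatrix")
  Cl <- as(Cp, "CsparseMatrix")
  visited <- logical(m)
  ncomp <- 0L
  ptr <- Cl@p
  idx <- Cl@i
  for (start in seq_len(m)) {
    if (visited[start]) next
    ncomp <- ncomp + 1L
    queue <- start
    visited[start] <- TRUE
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- idx[seq.int(ptr[v] + 1L, length.out = ptr[v + 1L] - ptr[v])] + 1L
      nb <- nb[!visited[nb]]
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  ncomp
}
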