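#' Rectangular lattice with serpentine site numbering
#'
#' Constructs an `nr` x `nc` rectangular lattice of sites. Sites are numbered
#' 1..`nr * nc` along a boustrophedon ("serpentine") path: row 1 runs left to
#' right, row 2 right to left, and so on, starting from the upper-left corner.
#' Rows are counted downward from the top, so site (1, 1) sits where the
#' (1, 1) element of a matrix would. This ordering is what makes every
#' surviving term of the link-field trace expansion positive, and gives the
#' antisymmetric activity matrix its block-tridiagonal form.
#'
#' @param nr Number of rows (>= 1).
#' @param nc Number of columns (>= 1).
#' @return An object of class `grid_shape`: a list with elements `nr`, `nc`
#'   and `n_sites = nr * nc`.
#' @examples
#' g <- grid_shape(3, 4)
#' g$n_sites
#' @export
grid_shape <- function(nr, nc) {
  stopifnot(length(nr) == 1, length(nc) == 1, nr >= 1, nc >= 1,
            nr == as.integer(nr), nc == as.integer(nc))
  structure(
    list(nr = as.integer(nr), nc = as.integer(nc),
         n_sites = as.integer(nr) * as.integer(nc)),
    class = "grid_shape"
  )
}

#' @export
print.grid_shape <- function(x, ...) {
  cat(sprintf("<grid_shape> %d x %d lattice (%d sites, %d links)\n",
              x$nr, x$nc, x$n_sites,
              x$nr * (x$nc - 1L) + (x$nr - 1L) * x$nc))
  invisible(x)
}

as_grid_shape <- function(shape) {
  if (inherits(shape, "grid_shape")) return(shape)
  stopifnot(length(shape) == 2)
  grid_shape(shape[[1]], shape[[2]])
}

#' Serpentine site index of a lattice coordinate
#'
#' Maps a (row, column) coordinate to its 1-based serpentine site id:
#' odd rows run left to right, even rows right to left.
#'
#' @param row,col 1-based lattice coordinates (vectorised).
#' @param shape A [grid_shape()].
#' @return Integer site id(s) in 1..`n_sites`.
#' @examples
#' serpentine_index(3, 5, grid_shape(6, 11)) # 27
#' serpentine_index(4, 5, grid_shape(6, 11)) # 40
#' @export
serpentine_index <- function(row, col, shape) {
  shape <- as_grid_shape(shape)
  if (any(row < 1 | row > shape$nr | col < 1 | col > shape$nc)) {
    stop("coordinates outside the ", shape$nr, " x ", shape$nc, " lattice")
  }
  ifelse(row %% 2 == 1L,
         (row - 1L) * shape$nc + col,
         row * shape$nc - col + 1L)
}

#' Lattice coordinates of a serpentine site index
#'
#' Inverse of [serpentine_index()].
#'
#' @param site 1-based serpentine site id(s).
#' @param shape A [grid_shape()].
#' @return A tibble with columns `site`, `row`, `col`.
#' @export
serpentine_coords <- function(site, shape) {
  shape <- as_grid_shape(shape)
  if (any(site < 1 | site > shape$n_sites)) stop("site id out of range")
  row <- (site - 1L) %/% shape$nc + 1L
  offset <- (site - 1L) %% shape$nc + 1L
  col <- ifelse(row %% 2 == 1L, offset, shape$nc - offset + 1L)
  tibble(site = as.integer(site), row = as.integer(row), col = as.integer(col))
}

#' Nearest-neighbor links of a lattice
#'
#' Enumerates all nearest-neighbor links under serpentine numbering. A link is
#' identified by its ordered endpoint pair (j, k) with j < k; horizontal links
#' join sites adjacent along a row, vertical links join vertically adjacent
#' sites in consecutive rows. The count is `nr * (nc - 1) + (nr - 1) * nc`.
#'
#' @param shape A [grid_shape()].
#' @return A tibble with integer columns `from`, `to` (serpentine ids,
#'   `from < to`) and character column `orientation`
#'   (`"horizontal"` / `"vertical"`), sorted by (`from`, `to`).
#' @examples
#' grid_links(grid_shape(2, 2))
#' @export
grid_links <- function(shape) {
  shape <- as_grid_shape(shape)
  nr <- shape$nr; nc <- shape$nc
  horiz <- if (nc > 1) {
    rows <- rep(seq_len(nr), each = nc - 1L)
    cols <- rep(seq_len(nc - 1L), times = nr)
    a <- serpentine_index(rows, cols, shape)
    b <- serpentine_index(rows, cols + 1L, shape)
    tibble(from = pmin(a, b), to = pmax(a, b), orientation = "horizontal")
  } else {
    tibble(from = integer(), to = integer(), orientation = character())
  }
  vert <- if (nr > 1) {
    rows <- rep(seq_len(nr - 1L), each = nc)
    cols <- rep(seq_len(nc), times = nr - 1L)
    a <- serpentine_index(rows, cols, shape)
    b <- serpentine_index(rows + 1L, cols, shape)
    tibble(from = pmin(a, b), to = pmax(a, b), orientation = "vertical")
  } else {
    tibble(from = integer(), to = integer(), orientation = character())
  }
  out <- dplyr::bind_rows(horiz, vert)
  dplyr::arrange(out, .data$from, .data$to)
}

#' Antisymmetric activity matrix of a lattice
#'
#' Builds the `n_sites` x `n_sites` antisymmetric matrix M whose upper
#' triangle carries the dimer activity on each nearest-neighbor link: `x` on
#' horizontal links, `y` on vertical links, zero elsewhere; the lower triangle
#' follows by antisymmetry. Under serpentine numbering M is block-tridiagonal:
#' `nr` diagonal blocks `X` (size `nc`, activity `x` on the superdiagonal)
#' with `+Y` above and `-Y` below the block diagonal, where `Y` has `y` along
#' its antidiagonal. The Pfaffian of M is the complete-filling partition
#' function.
#'
#' @param shape A [grid_shape()].
#' @param x Activity of horizontal dimers (>= 0).
#' @param y Activity of vertical dimers (>= 0).
#' @return A base matrix of class `c("skew_matrix", "matrix", "array")` with
#'   the shape stored in attribute `"shape"`.
#' @examples
#' m <- build_skew_matrix(grid_shape(3, 4), x = 1, y = 2)
#' m[1, 2]   # x
#' m[1, 8]   # y: vertical link between sites 1 and 8
#' @export
build_skew_matrix <- function(shape, x, y) {
  shape <- as_grid_shape(shape)
  stopifnot(x >= 0, y >= 0)
  n <- shape$n_sites
  m <- matrix(0, n, n)
  links <- grid_links(shape)
  w <- ifelse(links$orientation == "horizontal", x, y)
  m[cbind(links$from, links$to)] <- w
  m[cbind(links$to, links$from)] <- -w
  structure(m, shape = shape, class = c("skew_matrix", "matrix", "array"))
}

#' Diagonal and off-diagonal blocks of the activity matrix
#'
#' The `nc` x `nc` building blocks of the block-tridiagonal activity matrix:
#' `skew_block_x()` is the within-row block (activity `x` one step above the
#' diagonal, antisymmetric), `skew_block_y()` the row-coupling block
#' (activity `y` along the antidiagonal).
#'
#' @param nc Block order (number of lattice columns).
#' @param x,y Dimer activities.
#' @return A base `nc` x `nc` matrix.
#' @export
skew_block_x <- function(nc, x) {
  m <- matrix(0, nc, nc)
  if (nc > 1) {
    idx <- seq_len(nc - 1L)
    m[cbind(idx, idx + 1L)] <- x
    m[cbind(idx + 1L, idx)] <- -x
  }
  m
}

#' @rdname skew_block_x
#' @export
skew_block_y <- function(nc, y) {
  m <- matrix(0, nc, nc)
  m[cbind(seq_len(nc), rev(seq_len(nc)))] <- y
  m
}

#' Assemble the activity matrix from its blocks
#'
#' Builds M directly in the block-tridiagonal layout
#' `diag(X)` with `+Y` on the superdiagonal of blocks and `-Y` on the
#' subdiagonal. Entrywise identical to [build_skew_matrix()]; exposed so the
#' two constructions can be compared.
#'
#' @inheritParams build_skew_matrix
#' @return A base matrix (no class attribute).
#' @export
build_skew_matrix_blocks <- function(shape, x, y) {
  shape <- as_grid_shape(shape)
  nr <- shape$nr; nc <- shape$nc
  m <- matrix(0, nr * nc, nr * nc)
  bx <- skew_block_x(nc, x)
  by <- skew_block_y(nc, y)
  for (r in seq_len(nr)) {
    i <- (r - 1L) * nc + seq_len(nc)
    m[i, i] <- bx
    if (r < nr) {
      j <- r * nc + seq_len(nc)
      m[i, j] <- by
      m[j, i] <- -by
    }
  }
  m
}

#' Write an activity matrix to CSV
#'
#' Plain-text export of a [build_skew_matrix()] result for inspection.
#'
#' @param m A matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_skew_matrix_csv <- function(m, path) {
  utils::write.table(unclass(m), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
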