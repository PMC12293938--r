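#' Exhaustive enumeration of complete dimer coverings
#'
#' Lists every perfect matching of the grid graph: a set of links such that
#' every site is covered by exactly one dimer (complete filling). Recursion on
#' the lowest-numbered uncovered site, trying each of its incident links, so
#' the result is deterministic (lexicographic by sorted link list). Ground
#' truth for the trace-algebra, Pfaffian and closed-form routes on small
#' lattices.
#'
#' @param shape A [grid_shape()].
#' @return A list of matchings; each matching is a tibble of links (columns
#'   `from`, `to`, `orientation`) sorted by `from`. A lattice with an odd
#'   number of sites has no complete covering: the empty list is returned.
#' @examples
#' length(enumerate_matchings(grid_shape(2, 4))) # 5
#' @export
enumerate_matchings <- function(shape) {
  shape <- as_grid_shape(shape)
  if (shape$n_sites %% 2 == 1L) return(list())
  links <- grid_links(shape)
  n <- shape$n_sites
  incidence <- lapply(seq_len(n), function(j) {
    which(links$from == j | links$to == j)
  })
  out <- list()
  covered <- logical(n)
  pick <- integer(0)
  recurse <- function() {
    j <- which.min(covered)  # lowest uncovered site
    if (covered[j]) {        # all covered
      out[[length(out) + 1L]] <<- sort(pick)
      return(invisible())
    }
    for (l in incidence[[j]]) {
      k <- if (links$from[l] == j) links$to[l] else links$from[l]
      if (covered[k]) next
      covered[c(j, k)] <<- TRUE
      pick <<- c(pick, l)
      recurse()
      pick <<- pick[-length(pick)]
      covered[c(j, k)] <<- FALSE
    }
    invisible()
  }
  recurse()
  ord <- order(vapply(out, function(m) paste(m, collapse = ","), ""))
  lapply(out[ord], function(m) links[m, ])
}

#' Matching polynomial by exhaustive enumeration
#'
#' Histogram of (horizontal, vertical) dimer counts over
#' [enumerate_matchings()]: the generating polynomial
#' `sum g(Nx, Ny) x^Nx y^Ny` of the complete-filling partition function,
#' computed by brute force.
#'
#' @param shape A [grid_shape()] with an even number of sites.
#' @return A `matching_polynomial` tibble (columns `n_x`, `n_y`, `weight`)
#'   sorted by descending `n_x`; see [symbolic_partition_function()] for the
#'   trace-algebra route to the same object.
#' @examples
#' matching_polynomial(grid_shape(2, 2)) # x^2 + y^2
#' @export
matching_polynomial <- function(shape) {
  shape <- as_grid_shape(shape)
  if (shape$n_sites %% 2 == 1L) {
    stop("complete dimer filling requires an even number of sites")
  }
  matchings <- enumerate_matchings(shape)
  counts <- purrr::map(matchings, function(m) {
    nx <- sum(m$orientation == "horizontal")
    tibble(n_x = nx, n_y = nrow(m) - nx)
  })
  out <- dplyr::bind_rows(counts) |>
    dplyr::count(.data$n_x, .data$n_y, name = "weight") |>
    dplyr::arrange(dplyr::desc(.data$n_x))
  out$n_x <- as.integer(out$n_x); out$n_y <- as.integer(out$n_y)
  out$weight <- as.integer(out$weight)
  structure(out, class = c("matching_polynomial", class(out)))
}

#' Finite monomer-dimer-vacancy chain partition function
#'
#' Exact grand-canonical partition function of an N-site linear chain in
#' which each site is either a monomer (weight `z`), a vacancy (weight `v`),
#' or one end of a dimer occupying an adjacent pair (weight `x` per dimer).
#' Satisfies the recurrence `Z_N = (z + v) Z_{N-1} + x Z_{N-2}` with
#' `Z_0 = 1`, `Z_1 = z + v`; the ratio `Z_{N+1} / Z_N` converges to the
#' dominant transfer-matrix eigenvalue, the per-site partition function of
#' the infinite chain.
#'
#' @param N Number of chain sites (>= 0).
#' @param x Dimer activity (>= 0).
#' @param z Monomer activity (>= 0).
#' @param v Vacancy activity (>= 0).
#' @return The partition function `Z_N` (a double; grows like `Z_site^N`).
#' @examples
#' chain_partition(2, x = 1, z = 0, v = 1) # 2: vacancy pair or one dimer
#' @export
chain_partition <- function(N, x, z, v) {
  stopifnot(N >= 0, x >= 0, z >= 0, v >= 0)
  zm1 <- 1          # Z_0
  if (N == 0) return(zm1)
  zc <- z + v       # Z_1
  if (N == 1) return(zc)
  for (i in 2:N) {
    tmp <- (z + v) * zc + x * zm1
    zm1 <- zc
    zc <- tmp
  }
  zc
}

#' Probability that two adjacent four-state rotors pair up
#'
#' In the half-dimer picture each lattice site carries a rotor whose marked
#' face points north, south, east or west, uniformly at random. Two
#' neighboring rotors form a dimer when their marks point toward one another.
#' This enumerates all orientation pairs of one adjacent site pair and
#' returns the fraction that pair up.
#'
#' @return The pairing probability (1 of the 16 orientation pairs: 1/16).
#' @export
rotor_pairing_probability <- function() {
  # orientations 1..4 = N, S, E, W; neighbor to the east pairs when the left
  # rotor points E and the right rotor points W
  orientations <- expand.grid(left = 1:4, right = 1:4)
  paired <- orientations$left == 3 & orientations$right == 4
  mean(paired)
}
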