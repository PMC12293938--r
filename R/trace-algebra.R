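#' Ordered product of anticommuting link fields
#'
#' A link field A^(j,k) lives on the lattice link joining nearest-neighbor
#' sites j < k; distinct link fields anticommute and each squares to the
#' identity. A link product is an ordered sequence of such factors, the basic
#' object whose normalized trace the model evaluates.
#'
#' @param ... Links, each a length-2 integer vector `c(j, k)`; alternatively a
#'   single two-column matrix with one link per row. The empty product is the
#'   identity.
#' @return An object of class `link_product`: an n x 2 integer matrix.
#' @examples
#' link_product(c(1, 2), c(2, 3), c(1, 2), c(2, 3))
#' @export
link_product <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.matrix(args[[1]])) {
    m <- args[[1]]
  } else if (length(args) == 0) {
    m <- matrix(integer(), 0, 2)
  } else {
    stopifnot(all(vapply(args, length, 1L) == 2))
    m <- do.call(rbind, args)
  }
  storage.mode(m) <- "integer"
  if (nrow(m) > 0 && any(m[, 1] >= m[, 2])) {
    stop("each link must be an ordered pair (j, k) with j < k")
  }
  structure(m, class = c("link_product", class(matrix())))
}

#' @export
print.link_product <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<link_product> identity (empty product)\n")
  } else {
    cat("<link_product>",
        paste0("A(", x[, 1], ",", x[, 2], ")", collapse = " "), "\n")
  }
  invisible(x)
}

# Canonical single-integer key for a link (j, k); distinct links get
# distinct keys for any lattice below ~ 2^15 sites.
link_key <- function(m) m[, 1] * 65536L + m[, 2]

#' Normalized trace of a product of anticommuting link fields
#'
#' Evaluates (1/d) Tr(A^mu1 ... A^mun) for any faithful matrix representation
#' of the link-field algebra. The value is +1 or -1 when every distinct link
#' occurs an even number of times -- the sign being the parity of the
#' transpositions needed to bring identical factors adjacent -- and 0
#' otherwise (any unmatched factor kills the trace).
#'
#' The reduction repeatedly locates the next occurrence of the leading
#' factor, counts the transpositions needed to make the pair adjacent,
#' deletes the pair, and accumulates the parity. Factors occurring more than
#' twice are paired greedily left to right, consistent with each field
#' squaring to the identity.
#'
#' @param p A [link_product()] (or a plain two-column matrix of links).
#' @return `+1`, `-1` or `0`.
#' @examples
#' trace_product(link_product(c(1, 2), c(1, 2)))             # +1
#' trace_product(link_product(c(1, 2), c(2, 3), c(3, 4)))    # 0
#' trace_product(link_product(c(1, 2), c(2, 3), c(1, 2), c(2, 3))) # -1
#' @export
trace_product <- function(p) {
  if (!is.matrix(p)) stop("p must be a link_product or two-column matrix")
  keys <- if (nrow(p)) link_key(p) else integer()
  trace_keys(keys)
}

# Core reduction on integer keys.
trace_keys <- function(keys) {
  n <- length(keys)
  if (n %% 2 == 1L) return(0L)
  parity <- 0L
  while (length(keys) > 0) {
    partner <- match(keys[1], keys[-1])
    if (is.na(partner)) return(0L)
    pos <- partner + 1L          # position of the partner in the sequence
    parity <- (parity + pos - 2L) %% 2L
    keys <- keys[-c(1L, pos)]
  }
  if (parity == 0L) 1L else -1L
}

#' Matching polynomial via the link-field trace expansion
#'
#' First-principles construction of the complete-filling partition function:
#' attach to each site j the sum V_j of sqrt(activity) * A^(jl) over the
#' nearest neighbors l of j, expand the ordered product V_1 V_2 ... V_N, and
#' evaluate the normalized trace of each term. Terms in which every chosen
#' link appears exactly twice survive; under serpentine numbering each
#' survivor has sign +1 and contributes one complete dimer covering. The
#' result is accumulated exactly (activity square roots tracked as integer
#' half-exponents) into the generating polynomial
#' `sum g(Nx, Ny) x^Nx y^Ny` over coverings with `Nx` horizontal and `Ny`
#' vertical dimers.
#'
#' Exponential in lattice size; intended as an oracle for small lattices
#' (up to roughly 24 sites). The expansion is a depth-first product over
#' sites with early pruning: a branch in which a previously chosen link can
#' no longer find its second endpoint is dropped.
#'
#' @param shape A [grid_shape()] with an even number of sites.
#' @return A `matching_polynomial`: a tibble with integer columns `n_x`,
#'   `n_y`, `weight` (`weight` = number of coverings with that dimer split),
#'   sorted by descending `n_x`. An attribute `"all_signs_positive"` records
#'   that every surviving trace evaluated to +1.
#' @examples
#' symbolic_partition_function(grid_shape(2, 3)) # 2 x^2 y + y^3
#' @export
symbolic_partition_function <- function(shape) {
  shape <- as_grid_shape(shape)
  if (shape$n_sites %% 2 == 1L) {
    stop("complete dimer filling requires an even number of sites")
  }
  links <- grid_links(shape)
  n <- shape$n_sites
  # incidence[[j]]: indices (rows of `links`) of links touching site j
  incidence <- lapply(seq_len(n), function(j) {
    which(links$from == j | links$to == j)
  })
  horizontal <- links$orientation == "horizontal"
  other_end <- function(l, j) if (links$from[l] == j) links$to[l] else links$from[l]

  counts <- integer(nrow(links))   # times each link has been chosen
  chosen <- integer(n)             # link chosen by each site, in site order
  terms <- new.env(parent = emptyenv())
  all_positive <- TRUE

  recurse <- function(j) {
    if (j > n) {
      # every link count must be 0 or 2 (guaranteed by pruning); evaluate
      # the trace of the ordered factor sequence and accumulate
      keys <- link_key(as.matrix(links[chosen, c("from", "to")]))
      s <- trace_keys(keys)
      if (s != 0L) {
        if (s < 0L) all_positive <<- FALSE
        nx <- sum(horizontal[chosen]) %/% 2L
        ny <- (length(chosen) %/% 2L) - nx
        key <- paste(nx, ny)
        terms[[key]] <- (if (is.null(terms[[key]])) 0L else terms[[key]]) + s
      }
      return(invisible())
    }
    # any link with one endpoint < j still waiting for a second choice must
    # be incident on j or it can never be completed
    pending <- which(counts == 1L)
    must <- pending[links$to[pending] == j | links$from[pending] == j]
    if (length(pending) - length(must) > 0) {
      # some pending link's second endpoint is not j; if its second endpoint
      # is > j it can still be completed later -- only prune truly dead ones
      dead <- pending[links$from[pending] < j & links$to[pending] < j]
      if (length(dead) > 0) return(invisible())
    }
    if (length(must) > 1L) return(invisible())  # site j cannot close two links
    cands <- if (length(must) == 1L) must else incidence[[j]]
    for (l in cands) {
      if (counts[l] >= 2L) next
      # choosing a fresh link whose other endpoint precedes j is dead
      if (counts[l] == 0L && other_end(l, j) < j) next
      counts[l] <<- counts[l] + 1L
      chosen[j] <<- l
      recurse(j + 1L)
      counts[l] <<- counts[l] - 1L
    }
    invisible()
  }
  recurse(1L)

  keys <- ls(terms)
  if (length(keys) == 0) {
    out <- tibble(n_x = integer(), n_y = integer(), weight = integer())
  } else {
    split_keys <- do.call(rbind, strsplit(keys, " "))
    out <- tibble(
      n_x = as.integer(split_keys[, 1]),
      n_y = as.integer(split_keys[, 2]),
      weight = vapply(keys, function(k) as.integer(terms[[k]]), 1L)
    )
    out <- dplyr::arrange(out, dplyr::desc(.data$n_x))
  }
  structure(out, class = c("matching_polynomial", class(out)),
            all_signs_positive = all_positive)
}

#' Evaluate a matching polynomial at given activities
#'
#' @param poly A matching polynomial tibble with columns `n_x`, `n_y`,
#'   `weight` (from [symbolic_partition_function()] or
#'   [matching_polynomial()]).
#' @param x,y Horizontal and vertical dimer activities.
#' @return The polynomial value `sum weight * x^n_x * y^n_y`.
#' @export
eval_matching_polynomial <- function(poly, x, y) {
  if (nrow(poly) == 0) return(0)
  sum(poly$weight * x^poly$n_x * y^poly$n_y)
}
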