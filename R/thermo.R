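#' Grand-canonical activity of a species
#'
#' The statistical weight `exp(-beta * (eps - mu))` of a species with binding
#' energy `eps` and chemical potential `mu` at inverse thermal energy
#' `beta = 1 / (kB T)`. All thermodynamic inputs enter the model only through
#' such dimensionless products, so `eps` and `mu` may be given directly as
#' `beta * eps`, `beta * mu` with `beta = 1`.
#'
#' @param eps Binding energy (energy units; negative = attractive).
#' @param mu Chemical potential (same units).
#' @param beta Inverse thermal energy (default 1, i.e. energies are already
#'   in units of kB T).
#' @return The activity, a positive double. Vectorised.
#' @examples
#' activity(eps = -0.79, mu = 0) # exp(0.79)
#' @export
activity <- function(eps, mu, beta = 1) {
  stopifnot(all(beta > 0))
  exp(-beta * (eps - mu))
}

# 0 * log(0) = 0 convention for zero-activity species
xlogx <- function(a) ifelse(a == 0, 0, a * log(a))

#' Per-site log partition function of the infinite square lattice
#'
#' The thermodynamic limit of the complete-filling dimer model on the square
#' lattice:
#' `ln Z_site = (1/4) ln 2 + (1/(4 pi^2)) *`
#' `int_0^pi int_0^pi ln[x^2 (1 + cos t) + y^2 (1 + cos s)] dt ds`.
#' The inner integral has the closed form `pi ln[(a + sqrt(a^2 - b^2)) / 2]`
#' with `a = x^2 (1 + cos t) + y^2`, `b = y^2`; the outer integral is done by
#' adaptive quadrature. At `x = y = 1` the value is Catalan's constant over
#' pi (~ 0.29156); at `y = 0` the rows decouple into packed one-dimensional
#' chains and the value is `(1/2) ln x`.
#'
#' @param x,y Dimer activities (>= 0, not both zero).
#' @param rel_tol Quadrature relative tolerance.
#' @return `ln Z_site`, a double; symmetric in `x` and `y`.
#' @examples
#' ln_z_site_2d(1, 1) # Catalan / pi
#' @export
ln_z_site_2d <- function(x, y, rel_tol = 1e-10) {
  stopifnot(x >= 0, y >= 0)
  if (x == 0 && y == 0) stop("at least one activity must be positive")
  # integrate over the direction of the smaller activity for a smooth
  # integrand (the closed-form inner integral absorbs the larger one)
  if (y > x) { tmp <- x; x <- y; y <- tmp }
  inner <- function(t) {
    a <- x^2 * (1 + cos(t)) + y^2
    b <- y^2
    log((a + sqrt(pmax(a^2 - b^2, 0))) / 2)
  }
  q <- stats::integrate(inner, 0, pi, rel.tol = rel_tol, abs.tol = 1e-12,
                        subdivisions = 500L)
  log(2) / 4 + q$value / (4 * pi)
}

#' Log partition function of the finite two-leg ladder
#'
#' For `nr = 2` rows the closed form collapses to a single product over
#' column winding numbers:
#' `ln Z = sum_{omega=1}^{nc/2} ln[2 x^2 (1 + cos(2 pi omega/(nc+1))) + y^2]`
#' (the row factor `1 + cos(2 pi / 3) = 1/2` absorbs the power of two).
#' Viewed edge-on, the ladder is a linear chain in which vertical dimers act
#' as monomers; the per-site limit of this expression, with `x^2` corrected
#' to `x` to remove the double-counted leg dimers, yields the monomer-dimer
#' chain ([ln_z_site_chain()]).
#'
#' @param nc Number of ladder columns (even).
#' @param x,y Dimer activities.
#' @return `ln Z` of the full `2 x nc` ladder (not per site); equals
#'   `z_closed(grid_shape(2, nc), x, y, log = TRUE)`.
#' @examples
#' ln_z_ladder(4, 1, 1) # log(5)
#' @export
ln_z_ladder <- function(nc, x, y) {
  stopifnot(nc %% 2 == 0, nc >= 2)
  omega <- seq_len(nc %/% 2)
  sum(log(2 * x^2 * (1 + cos(2 * pi * omega / (nc + 1))) + y^2))
}

#' Per-site log partition function of the infinite monomer-dimer chain
#'
#' Thermodynamic limit of a linear chain of dimers (activity `x`) and
#' monomers (activity `y`): `ln Z_site = ln[(sqrt(4 x + y^2) + y) / 2]`.
#' At `x = 1, y = 1` this is the log of the golden ratio.
#'
#' @param x Dimer activity (>= 0).
#' @param y Monomer activity (>= 0); not both zero.
#' @return `ln Z_site`.
#' @export
ln_z_site_chain <- function(x, y) {
  stopifnot(x >= 0, y >= 0)
  if (x == 0 && y == 0) stop("at least one activity must be positive")
  log((sqrt(4 * x + y^2) + y) / 2)
}

#' Per-site log partition function of the dimer-monomer-vacancy chain
#'
#' Coloring the chain monomers into two species -- bound perpendicular
#' dimers (activity `z_perp`) and bare vacancies (activity `v`) -- multiplies
#' the monomer degeneracy binomially, so the two-species chain is the
#' monomer-dimer chain at combined monomer activity `z_perp + v`:
#' `ln Z_site = ln{ [z_perp + v + sqrt((z_perp + v)^2 + 4 x_par)] / 2 }`.
#'
#' @param x_par Activity of parallel (lattice-aligned, two-site) dimers.
#' @param z_perp Activity of perpendicular dimers (single-site monomers).
#' @param v Vacancy activity (default 1: a hole has neither energy nor
#'   chemical potential).
#' @return `ln Z_site`.
#' @examples
#' ln_z_site_chain3(0, 1, 1) # log(2): two equal-weight states per site
#' @export
ln_z_site_chain3 <- function(x_par, z_perp, v = 1) {
  stopifnot(x_par >= 0, z_perp >= 0, v >= 0)
  ln_z_site_chain(x_par, z_perp + v)
}

#' Per-site entropy of the dimer-monomer-vacancy chain
#'
#' Analytic entropy (units of kB) from the beta-derivative of the per-site
#' free energy at fixed binding energies and chemical potentials:
#' `S/kB = ln Z_site - 1/(2 Z_site) * { z ln z +`
#' `[(z + v)^2 + 4 x]^(-1/2) [(z + v) z ln z + 2 x ln x] }`
#' with `z = z_perp`, `x = x_par`. The vacancy has zero energy and chemical
#' potential (its activity does not run with beta), and `0 ln 0 = 0` covers
#' zero-activity species.
#'
#' @inheritParams ln_z_site_chain3
#' @return Entropy per site in units of kB.
#' @examples
#' entropy_site_chain(0, 1, 1) # log(2)
#' @export
entropy_site_chain <- function(x_par, z_perp, v = 1) {
  z_site <- exp(ln_z_site_chain3(x_par, z_perp, v))
  root <- sqrt((z_perp + v)^2 + 4 * x_par)
  ln_z_site_chain3(x_par, z_perp, v) -
    (xlogx(z_perp) +
       ((z_perp + v) * xlogx(z_perp) + 2 * xlogx(x_par)) / root) /
      (2 * z_site)
}

#' Per-site species occupancies of the dimer-monomer-vacancy chain
#'
#' Closed-form mean occupancies from chemical-potential derivatives of the
#' per-site free energy, with `R = sqrt((z_perp + v)^2 + 4 x_par)`:
#' perpendicular dimers `n_perp = z_perp / R`, vacancies `n_vac = v / R`,
#' and parallel dimers (two sites each) `n_par = 2 x_par / (Z_site R)`.
#' The three sum to one identically.
#'
#' @inheritParams ln_z_site_chain3
#' @return A one-row tibble with columns `n_perp`, `n_par`, `n_vac`.
#' @examples
#' occupancies_chain(0, 1, 1) # (1/2, 0, 1/2)
#' @export
occupancies_chain <- function(x_par, z_perp, v = 1) {
  z_site <- exp(ln_z_site_chain3(x_par, z_perp, v))
  root <- sqrt((z_perp + v)^2 + 4 * x_par)
  tibble(
    n_perp = z_perp / root,
    n_par = 2 * x_par / (z_site * root),
    n_vac = v / root
  )
}

#' Net per-site charge of the dressed chain
#'
#' Charge bookkeeping for divalent polyions on a negatively charged backbone:
#' a vacant site keeps the backbone's -1, a perpendicular dimer neutralizes
#' its site and carries +1 on its free end, and a parallel dimer neutralizes
#' both sites it covers. The signed net charge per site is therefore
#' `n_perp - n_vac` (the default). `convention = "as_printed"` returns the
#' literal sum `n_perp + n_vac` instead, the form in which the charge
#' comparison figure labels its axis.
#'
#' @inheritParams ln_z_site_chain3
#' @param convention `"signed"` (default) or `"as_printed"`.
#' @return Net charge per site (units of the elementary charge).
#' @export
charge_chain <- function(x_par, z_perp, v = 1,
                         convention = c("signed", "as_printed")) {
  convention <- match.arg(convention)
  occ <- occupancies_chain(x_par, z_perp, v)
  if (convention == "signed") occ$n_perp - occ$n_vac else occ$n_perp + occ$n_vac
}

#' Chain thermodynamics bundle
#'
#' Evaluates the full set of chain observables at one activity triple and
#' returns them as a single object with broom-style [tidy()] and [glance()]
#' methods.
#'
#' @inheritParams charge_chain
#' @return An object of class `chain_thermo`: list with the activities,
#'   `ln_z_site`, `entropy`, `occupancies` (tibble) and `charge`.
#' @examples
#' glance(chain_thermo(x_par = 2, z_perp = 0.7))
#' @export
chain_thermo <- function(x_par, z_perp, v = 1,
                         convention = c("signed", "as_printed")) {
  convention <- match.arg(convention)
  structure(
    list(
      x_par = x_par, z_perp = z_perp, v = v, convention = convention,
      ln_z_site = ln_z_site_chain3(x_par, z_perp, v),
      entropy = entropy_site_chain(x_par, z_perp, v),
      occupancies = occupancies_chain(x_par, z_perp, v),
      charge = charge_chain(x_par, z_perp, v, convention)
    ),
    class = "chain_thermo"
  )
}

#' @export
print.chain_thermo <- function(x, ...) {
  cat(sprintf("<chain_thermo> x_par = %g, z_perp = %g, v = %g\n",
              x$x_par, x$z_perp, x$v))
  cat(sprintf("  ln Z_site = %.6f   S/kB = %.6f   charge (%s) = %.6f\n",
              x$ln_z_site, x$entropy, x$convention, x$charge))
  print(x$occupancies)
  invisible(x)
}

#' @rdname chain_thermo
#' @param x A `chain_thermo` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.chain_thermo <- function(x, ...) {
  tibble(
    species = c("perpendicular", "parallel", "vacancy"),
    activity = c(x$z_perp, x$x_par, x$v),
    occupancy = c(x$occupancies$n_perp, x$occupancies$n_par,
                  x$occupancies$n_vac),
    charge_per_site = c(x$occupancies$n_perp, 0, -x$occupancies$n_vac)
  )
}

#' @rdname chain_thermo
#' @exportS3Method generics::glance
glance.chain_thermo <- function(x, ...) {
  tibble(
    ln_z_site = x$ln_z_site,
    entropy = x$entropy,
    charge = x$charge,
    occupancy_sum = sum(unlist(x$occupancies))
  )
}

#' Non-interacting lattice-gas baseline
#'
#' Independent-site adsorption of point particles: each site holds exactly
#' one species drawn from the given activities, so
#' `ln Z_site = ln(sum a_i)`, the occupancies are `n_i = a_i / sum a_j`, and
#' the entropy per site (kB units) is
#' `S/kB = ln(sum a_i) - (sum a_i ln a_i) / (sum a_i)`, the
#' free-energy-derivative evaluation of the grand-canonical entropy (equal to
#' the Gibbs-Shannon entropy `-sum n_i ln n_i` of the site distribution).
#'
#' @param activities A named numeric vector of species activities (>= 0,
#'   not all zero), or a data frame with columns `species` and `activity`.
#' @return An object of class `lattice_gas`: list with `ln_z_site`,
#'   `entropy` and an `occupancies` tibble (`species`, `activity`,
#'   `occupancy`). Has [tidy()] and [glance()] methods.
#' @examples
#' lattice_gas(c(red = 1, blue = 1))$entropy # log(2)
#' @export
lattice_gas <- function(activities) {
  if (is.data.frame(activities)) {
    stopifnot(all(c("species", "activity") %in% names(activities)))
    labels <- as.character(activities$species)
    a <- activities$activity
  } else {
    a <- as.numeric(activities)
    labels <- names(activities) %||% paste0("species", seq_along(a))
  }
  stopifnot(all(a >= 0), sum(a) > 0)
  total <- sum(a)
  structure(
    list(
      ln_z_site = log(total),
      entropy = log(total) - sum(xlogx(a)) / total,
      occupancies = tibble(species = labels, activity = a,
                           occupancy = a / total)
    ),
    class = "lattice_gas"
  )
}

#' @export
print.lattice_gas <- function(x, ...) {
  cat(sprintf("<lattice_gas> ln Z_site = %.6f   S/kB = %.6f\n",
              x$ln_z_site, x$entropy))
  print(x$occupancies)
  invisible(x)
}

#' @rdname lattice_gas
#' @param x A `lattice_gas` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.lattice_gas <- function(x, ...) x$occupancies

#' @rdname lattice_gas
#' @exportS3Method generics::glance
glance.lattice_gas <- function(x, ...) {
  tibble(ln_z_site = x$ln_z_site, entropy = x$entropy,
         occupancy_sum = sum(x$occupancies$occupancy))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
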