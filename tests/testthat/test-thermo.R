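test_that("activities are grand-canonical Boltzmann weights", {
  expect_equal(activity(1.3, 1.3), 1)
  expect_equal(activity(-0.79, 0, beta = 1), exp(0.79))
  expect_equal(activity(2, 1, beta = 1e4), 0, tolerance = 1e-12)
  expect_equal(activity(1, 2, beta = 2), exp(2))
})

test_that("2D per-site free energy has the right limits and symmetry", {
  # equal activities: Catalan's constant over pi
  expect_equal(ln_z_site_2d(1, 1), catalan_constant / pi, tolerance = 1e-6)
  # one activity zero: rows decouple into packed chains
  for (x in c(0.5, 1, 3)) {
    expect_equal(ln_z_site_2d(x, 0), log(x) / 2, tolerance = 1e-8)
  }
  expect_equal(ln_z_site_2d(2, 3), ln_z_site_2d(3, 2), tolerance = 1e-10)
  # independent raw 2D quadrature, no closed-form inner integral
  for (acts in list(c(1, 1), c(2, 0.5))) {
    expect_equal(ln_z_site_2d(acts[1], acts[2]),
                 ln_z_site_2d_quadrature(acts[1], acts[2]),
                 tolerance = 1e-5)
  }
  expect_error(ln_z_site_2d(0, 0), "positive")
})

test_that("finite-size square lattices converge to the 2D limit", {
  per_site <- vapply(c(8, 16, 24), function(n) {
    z_closed(grid_shape(n, n), 1, 1, log = TRUE) / n^2
  }, 1)
  expect_true(all(diff(per_site) > 0))
  expect_lt(abs(per_site[3] - catalan_constant / pi), 2e-2)
})

test_that("two-leg ladder log partition function matches the closed form", {
  expect_equal(ln_z_ladder(2, 1, 1), log(2))
  expect_equal(ln_z_ladder(4, 1, 1), log(5))
  for (nc in seq(2, 12, by = 2)) {
    expect_equal(ln_z_ladder(nc, 1.3, 0.8),
                 z_closed(grid_shape(2, nc), 1.3, 0.8, log = TRUE),
                 tolerance = 1e-10)
  }
  # y = 0 forces all-horizontal coverings with weight x^nc
  expect_equal(ln_z_ladder(6, 1.5, 0), 6 * log(1.5), tolerance = 1e-10)
  expect_equal(eval_matching_polynomial(matching_polynomial(grid_shape(2, 6)),
                                        1.5, 0), 1.5^6)
})

test_that("infinite chain free energy matches transfer-matrix growth", {
  expect_equal(ln_z_site_chain(1, 0), log(1) / 2)
  expect_equal(ln_z_site_chain(4, 0), log(4) / 2)
  expect_equal(ln_z_site_chain(0, 2), log(2))
  expect_equal(ln_z_site_chain(1, 1), log((1 + sqrt(5)) / 2))
  expect_equal(ln_z_site_chain3(0, 1, 1), log(2))
  expect_equal(ln_z_site_chain3(1, 0, 1), log((1 + sqrt(5)) / 2))
  # dominant eigenvalue of the 2x2 transfer matrix and the finite-N ratio
  set.seed(23)
  for (rep in 1:20) {
    x <- runif(1, 0.1, 3); z <- runif(1, 0.1, 3); v <- runif(1, 0.1, 3)
    lam <- ((z + v) + sqrt((z + v)^2 + 4 * x)) / 2
    expect_equal(exp(ln_z_site_chain3(x, z, v)), lam, tolerance = 1e-12)
    ratio <- chain_partition(201, x, z, v) / chain_partition(200, x, z, v)
    expect_equal(ratio, lam, tolerance = 1e-10)
    lnZ_N <- log(chain_partition(200, x, z, v)) / 200
    expect_lt(abs(lnZ_N - ln_z_site_chain3(x, z, v)), 1e-2)
  }
})

test_that("two-color monomer reduction equals binomial resummation", {
  # color the ladder rung dimers two ways: summing colorings of each
  # covering binomially must equal the one-color value at yr + yb
  set.seed(29)
  poly <- matching_polynomial(grid_shape(2, 6))
  for (rep in 1:10) {
    x <- runif(1, 0.2, 2); yr <- runif(1, 0.2, 2); yb <- runif(1, 0.2, 2)
    two_color <- sum(vapply(seq_len(nrow(poly)), function(i) {
      ny <- poly$n_y[i]
      colorings <- sum(choose(ny, 0:ny) * yr^(0:ny) * yb^(ny - (0:ny)))
      poly$weight[i] * x^poly$n_x[i] * colorings
    }, 1))
    expect_equal(two_color, eval_matching_polynomial(poly, x, yr + yb),
                 tolerance = 1e-12)
    expect_equal(two_color, z_closed(grid_shape(2, 6), x, yr + yb),
                 tolerance = 1e-8)
  }
})

test_that("analytic chain entropy matches the numerical beta derivative", {
  expect_equal(entropy_site_chain(0, 1, 1), log(2))
  expect_equal(entropy_site_chain(0, 0, 1), 0)
  set.seed(31)
  h <- 1e-4
  for (rep in 1:50) {
    eps_par <- runif(1, -2, 2); mu <- runif(1, -1, 1)
    eps_perp <- eps_par / 2
    s_analytic <- entropy_site_chain(activity(eps_par, mu),
                                     activity(eps_perp, mu))
    f <- function(beta) {
      ln_z_site_chain3(activity(eps_par, mu, beta),
                       activity(eps_perp, mu, beta)) / beta
    }
    # S/kB = -beta^2 d/dbeta [(1/beta) ln Z_site], centered at beta = 1
    s_numeric <- -(f(1 + h) - f(1 - h)) / (2 * h)
    expect_equal(s_analytic, s_numeric, tolerance = 1e-6)
  }
})

test_that("entropy plateaus under strong binding and is nonnegative", {
  beta_mu <- 0.79
  s_at <- function(be) {
    entropy_site_chain(exp(-be + beta_mu), exp(-be / 2 + beta_mu))
  }
  expect_gt(s_at(-30), 0.1)
  expect_lt(abs(s_at(-30) - s_at(-40)), 1e-3) # plateau flatness
  sweep_s <- vapply(seq(-20, 10, by = 0.5), s_at, 1)
  expect_true(all(sweep_s >= 0))
})

test_that("chain occupancies are normalized closed forms", {
  expect_equal(as.data.frame(occupancies_chain(0, 1, 1)),
               data.frame(n_perp = 0.5, n_par = 0, n_vac = 0.5))
  expect_equal(as.data.frame(occupancies_chain(3, 0, 0)),
               data.frame(n_perp = 0, n_par = 1, n_vac = 0))
  set.seed(37)
  for (rep in 1:25) {
    x <- runif(1, 0, 4); z <- runif(1, 0, 4); v <- runif(1, 0.01, 4)
    occ <- occupancies_chain(x, z, v)
    expect_true(all(unlist(occ) >= 0 & unlist(occ) <= 1))
    expect_equal(sum(unlist(occ)), 1, tolerance = 1e-12)
  }
})

test_that("net charge conventions behave as defined", {
  # symmetric monomer/vacancy activities carry zero signed charge
  expect_equal(charge_chain(0, 1, 1), 0)
  expect_equal(charge_chain(0, 1, 1, convention = "as_printed"), 1)
  # bare backbone: all vacancies, charge -1
  expect_equal(charge_chain(0, 0, 1), -1)
  # strong-binding plateau at the analytic value
  beta_mu <- 0.79
  be <- -40
  q <- charge_chain(exp(-be + beta_mu), exp(-be / 2 + beta_mu))
  expect_equal(q, (1 + 4 * exp(-beta_mu))^(-1 / 2), tolerance = 1e-2)
})

test_that("lattice-gas baseline entropy and occupancies", {
  gas <- lattice_gas(c(red = 1, blue = 1))
  expect_equal(gas$entropy, log(2))
  expect_equal(gas$occupancies$occupancy, c(0.5, 0.5))
  expect_equal(lattice_gas(c(a = 1))$entropy, 0)
  expect_equal(lattice_gas(c(r = 1, b = 1, g = 1))$occupancies$occupancy,
               rep(1 / 3, 3))
  # data-frame input and strong-binding limit: one dominant species
  gas2 <- lattice_gas(tibble::tibble(species = c("par", "perp", "vac"),
                                     activity = c(1e9, 1e4, 1)))
  expect_gt(gas2$occupancies$occupancy[1], 0.999)
  expect_lt(gas2$entropy, 1e-2)
})

test_that("broom-style methods return tidy tibbles", {
  ct <- chain_thermo(x_par = 2, z_perp = 0.7)
  td <- tidy(ct)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$species, c("perpendicular", "parallel", "vacancy"))
  expect_equal(sum(td$occupancy), 1, tolerance = 1e-12)
  gl <- glance(ct)
  expect_equal(gl$occupancy_sum, 1, tolerance = 1e-12)
  expect_equal(gl$entropy, entropy_site_chain(2, 0.7, 1))
  gas <- lattice_gas(c(a = 1, b = 2))
  expect_equal(glance(gas)$occupancy_sum, 1)
  expect_equal(nrow(tidy(gas)), 2)
})
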