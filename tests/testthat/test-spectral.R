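test_that("quantized angles and the normalization cosine sum", {
  ang <- dimer_angles(grid_shape(3, 11))
  expect_equal(ang$phi, pi / 2 + (1:11) * pi / 12)
  expect_equal(ang$theta, pi / 2 + (1:3) * pi / 4)
  # the finite cosine sum equals -1 for every winding number
  expect_equal(cosine_sum(11, 4), -1)
  for (nc in c(3, 7, 12)) for (w in seq_len(nc)) {
    expect_equal(cosine_sum(nc, w), -1)
  }
})

test_that("within-row block eigensystem is exact and orthonormal", {
  for (nc in c(2, 5, 11, 32)) {
    es <- x_block_eigensystem(nc, x = 1.7)
    xb <- skew_block_x(nc, 1.7) + 0i
    for (w in seq_len(nc)) {
      residual <- xb %*% es$vectors[, w] - es$values[w] * es$vectors[, w]
      expect_lt(max(Mod(residual)), 1e-12)
    }
    gram <- Conj(t(es$vectors)) %*% es$vectors
    expect_lt(max(Mod(gram - diag(nc))), 1e-12)
  }
})

test_that("conjugated row-coupling block is the closed-form antidiagonal", {
  # nc = 4: the (1,4) entry is i^3 (-1)^3 y = i y
  y <- 2.5
  t4 <- transformed_y_block(4, y, method = "conjugate")
  expect_equal(t4[1, 4], 1i^3 * (-1)^3 * y, tolerance = 1e-10)
  # nc = 2: antidiagonal magnitudes all equal y
  t2 <- transformed_y_block(2, y, method = "conjugate")
  expect_equal(Mod(t2[cbind(1:2, 2:1)]), c(y, y), tolerance = 1e-10)
  for (nc in 2:8) {
    num <- transformed_y_block(nc, y, method = "conjugate")
    closed <- transformed_y_block(nc, y, method = "closed")
    expect_lt(max(Mod(num - closed)), 1e-10)
    off <- num
    off[cbind(seq_len(nc), rev(seq_len(nc)))] <- 0
    expect_lt(max(Mod(off)), 1e-10)
  }
})

test_that("cruciform determinant equals a generic determinant routine", {
  # order 2 closed form
  b2 <- list(diagonal = c(2 + 1i, 3), antidiagonal = c(1, 4 - 2i))
  expect_equal(cruciform_determinant(b2),
               (2 + 1i) * 3 - 1 * (4 - 2i))
  set.seed(19)
  for (n in 2:7) {
    d <- complex(real = rnorm(n), imaginary = rnorm(n))
    a <- complex(real = rnorm(n), imaginary = rnorm(n))
    m <- matrix(0 + 0i, n, n)
    diag(m) <- d
    m[cbind(seq_len(n), rev(seq_len(n)))] <-
      m[cbind(seq_len(n), rev(seq_len(n)))] + a
    expect_equal(cruciform_determinant(list(diagonal = d, antidiagonal = a)),
                 det_complex(m), tolerance = 1e-10)
  }
  # blocks built from the lattice agree with their own matrix form
  blk <- cruciform_block(grid_shape(3, 4), 1.2, 0.8, W = 2)
  expect_equal(cruciform_determinant(blk), det_complex(blk$matrix),
               tolerance = 1e-10)
})

test_that("closed-form Z^2 equals the determinant of the activity matrix", {
  expect_equal(z_squared_closed(grid_shape(2, 2), 1, 1), 4)
  expect_equal(z_squared_closed(grid_shape(2, 4), 1, 1), 25)
  expect_equal(z_squared_closed(grid_shape(1, 2), 1.7, 0.3), 1.7^2)
  for (s in list(c(2, 3), c(3, 4), c(4, 4), c(3, 5), c(5, 4))) {
    for (acts in list(c(1, 1), c(0.5, 2), c(2, 0.25))) {
      shape <- grid_shape(s[1], s[2])
      expect_equal(
        z_squared_closed(shape, acts[1], acts[2]),
        det(unclass(build_skew_matrix(shape, acts[1], acts[2]))),
        tolerance = 1e-8,
        label = paste("det", s[1], "x", s[2], acts[1], acts[2]))
    }
  }
})

test_that("closed-form Z matches enumeration, symbolic and Pfaffian routes", {
  expect_equal(z_closed(grid_shape(3, 4), 1, 1), 11, tolerance = 1e-10)
  expect_equal(z_closed(grid_shape(4, 4), 1, 1), 36, tolerance = 1e-10)
  # 2 x 2 polynomial identity over sampled activities
  for (x in c(0.25, 1, 3)) for (y in c(0.5, 1, 2)) {
    expect_equal(z_closed(grid_shape(2, 2), x, y), x^2 + y^2,
                 tolerance = 1e-10)
  }
  expect_error(z_closed(grid_shape(2, 3), 1, 1), "even")
  # odd-row branch validated against enumeration beyond the worked case
  for (s in list(c(3, 4), c(3, 6), c(5, 4))) {
    shape <- grid_shape(s[1], s[2])
    expect_equal(z_closed(shape, 1.3, 0.6),
                 eval_matching_polynomial(matching_polynomial(shape),
                                          1.3, 0.6),
                 tolerance = 1e-8)
  }
})

test_that("closed form is symmetric under lattice transposition", {
  for (s in list(c(2, 2), c(2, 4), c(4, 2), c(4, 6))) {
    expect_equal(z_closed(grid_shape(s[1], s[2]), 1.4, 0.7),
                 z_closed(grid_shape(s[2], s[1]), 0.7, 1.4),
                 tolerance = 1e-10)
  }
})

test_that("squared closed form stays real-positive for large lattices", {
  lnz <- z_closed(grid_shape(32, 32), 1, 1, log = TRUE)
  expect_true(is.finite(lnz))
  # direct consistency on a lattice large enough to overflow naive products
  shape <- grid_shape(12, 12)
  expect_equal(2 * z_closed(shape, 1, 1, log = TRUE),
               log(z_squared_closed(shape, 1, 1)), tolerance = 1e-8)
})
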