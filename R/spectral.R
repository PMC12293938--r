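#' Quantized angles of the block diagonalization
#'
#' The analytic diagonalization of the block-tridiagonal activity matrix
#' rests on two families of quantized angles: column angles
#' `phi_omega = pi/2 + omega * pi / (nc + 1)` (omega = 1..nc), which fix the
#' within-row eigenvalues, and row angles
#' `theta_W = pi/2 + W * pi / (nr + 1)` (W = 1..nr), which label the block
#' eigenvalues. Both arise from vanishing boundary conditions on the padded
#' difference equation; note `sin(phi_omega) = cos(omega * pi / (nc + 1))`.
#'
#' @param shape A [grid_shape()].
#' @return A list with numeric vectors `phi` (length `nc`) and `theta`
#'   (length `nr`).
#' @export
dimer_angles <- function(shape) {
  shape <- as_grid_shape(shape)
  list(
    phi   = pi / 2 + seq_len(shape$nc) * pi / (shape$nc + 1),
    theta = pi / 2 + seq_len(shape$nr) * pi / (shape$nr + 1)
  )
}

#' Finite cosine sum entering the eigenvector normalization
#'
#' The sum `sum_{k=1}^{nc} cos(2 pi k omega / (nc + 1))`, which equals -1 for
#' every winding number omega = 1..nc (the full period of the cosine over
#' nc + 1 points sums to zero and the k = 0 term is +1). It fixes the
#' eigenvector normalization constant `1 / sqrt(2 (nc + 1))`.
#'
#' @param nc Number of columns.
#' @param omega Winding number in 1..nc.
#' @return The sum (numerically -1).
#' @export
cosine_sum <- function(nc, omega) {
  stopifnot(omega >= 1, omega <= nc)
  sum(cos(2 * pi * seq_len(nc) * omega / (nc + 1)))
}

#' Eigensystem of the within-row activity block
#'
#' The antisymmetric within-row block X ([skew_block_x()]) has eigenvalues
#' `lambda_omega = 2 i x sin(phi_omega)` with quantized angles
#' `phi_omega = pi/2 + omega pi/(nc+1)`, and orthonormal eigenvectors with
#' components `v_{k,omega} = sqrt(2/(nc+1)) i^(k+1) sin(pi k omega/(nc+1))`.
#'
#' @param nc Block order (number of columns).
#' @param x Horizontal dimer activity.
#' @return A list with complex vector `values` (length `nc`) and complex
#'   matrix `vectors` (`nc` x `nc`, eigenvectors in columns).
#' @export
x_block_eigensystem <- function(nc, x) {
  omega <- seq_len(nc)
  phi <- pi / 2 + omega * pi / (nc + 1)
  values <- 2i * x * sin(phi)
  k <- seq_len(nc)
  vectors <- sqrt(2 / (nc + 1)) *
    outer(k, omega, function(k, w) (1i)^(k + 1) * sin(pi * k * w / (nc + 1)))
  list(values = values, vectors = vectors)
}

#' Row-coupling block in the eigenbasis of the within-row block
#'
#' Conjugating the antidiagonal row-coupling block Y ([skew_block_y()]) by
#' the unitary U of within-row eigenvectors maps it onto a pure antidiagonal:
#' `t_{omega, omega'} = y i^(nc-1) (-1)^(nc-omega) delta_{omega', nc+1-omega}`.
#' The closed form is the default; `method = "conjugate"` computes
#' `U^dagger Y U` numerically instead (used to validate the closed form).
#'
#' @param nc Block order.
#' @param y Vertical dimer activity.
#' @param method `"closed"` (analytic antidiagonal) or `"conjugate"`
#'   (numerical conjugation).
#' @return A complex `nc` x `nc` matrix.
#' @export
transformed_y_block <- function(nc, y, method = c("closed", "conjugate")) {
  method <- match.arg(method)
  if (method == "conjugate") {
    u <- x_block_eigensystem(nc, 1)$vectors
    return(Conj(t(u)) %*% (skew_block_y(nc, y) + 0i) %*% u)
  }
  omega <- seq_len(nc)
  m <- matrix(0 + 0i, nc, nc)
  m[cbind(omega, nc + 1L - omega)] <- y * (1i)^(nc - 1) * (-1)^(nc - omega)
  m
}

#' Cruciform block of the fully transformed activity matrix
#'
#' After the two-stage diagonalization, each row block of the activity matrix
#' becomes cruciform: nonzero entries only on the diagonal
#' (`lambda_omega = 2 i x sin(phi_omega)`) and the antidiagonal
#' (`(-1)^(nc-omega) * xi` with `xi = 2 i^nc y sin(theta_W)`).
#'
#' @param shape A [grid_shape()] (supplies `nc` and the row angle family).
#' @param x,y Dimer activities.
#' @param W Row winding number in 1..nr selecting `theta_W`.
#' @return An object of class `cruciform_block`: list with complex vectors
#'   `diagonal` and `antidiagonal` (entry k of `antidiagonal` sits at matrix
#'   position (k, nc + 1 - k)) plus the full complex `matrix`.
#' @export
cruciform_block <- function(shape, x, y, W) {
  shape <- as_grid_shape(shape)
  nc <- shape$nc
  stopifnot(W >= 1, W <= shape$nr)
  ang <- dimer_angles(shape)
  omega <- seq_len(nc)
  d <- 2i * x * sin(ang$phi)
  xi <- 2 * (1i)^nc * y * sin(ang$theta[W])
  a <- (-1)^(nc - omega) * xi
  m <- matrix(0 + 0i, nc, nc)
  diag(m) <- d
  m[cbind(omega, nc + 1L - omega)] <- m[cbind(omega, nc + 1L - omega)] + a
  structure(list(diagonal = d, antidiagonal = a, matrix = m),
            class = "cruciform_block")
}

#' Determinant of a cruciform matrix
#'
#' A cruciform matrix has nonzero entries only on its diagonal and
#' antidiagonal. Expanding by the first row and, within each minor, by the
#' last row reduces the determinant to `floor((n+1)/2)` corner factors of the
#' form `d_k d_{n+1-k} - a_k a_{n+1-k}`, times the lone central element when
#' the order is odd.
#'
#' @param block A [cruciform_block()], or a list with components `diagonal`
#'   and `antidiagonal` (complex vectors of equal length; antidiagonal entry
#'   k at position (k, n + 1 - k)).
#' @return The determinant (complex).
#' @export
cruciform_determinant <- function(block) {
  d <- block$diagonal
  a <- block$antidiagonal
  n <- length(d)
  stopifnot(length(a) == n)
  acc <- 1 + 0i
  for (k in seq_len(n %/% 2)) {
    acc <- acc * (d[k] * d[n + 1 - k] - a[k] * a[n + 1 - k])
  }
  if (n %% 2 == 1L) {
    mid <- (n + 1L) %/% 2L
    acc <- acc * (d[mid] + a[mid])  # diagonal and antidiagonal coincide
  }
  acc
}

#' Squared partition function in closed form
#'
#' The determinant of the activity matrix, evaluated analytically from the
#' cruciform blocks:
#' `Z^2 = (-1)^(nr * floor(nc/2)) * prod_{omega=1}^{nc} prod_{W=1}^{nr}
#'  [2 x cos(pi omega/(nc+1)) + 2 i y cos(pi W/(nr+1))]`.
#' The product is accumulated as log-magnitude plus phase so large lattices
#' do not overflow; the residual phase must vanish (mod pi) and is checked.
#'
#' @param shape A [grid_shape()].
#' @param x,y Dimer activities (>= 0).
#' @return `Z^2`, a real double (complex factors pair into conjugates).
#' @examples
#' z_squared_closed(grid_shape(2, 4), 1, 1) # 25
#' @export
z_squared_closed <- function(shape, x, y) {
  shape <- as_grid_shape(shape)
  nr <- shape$nr; nc <- shape$nc
  cw <- cos(pi * seq_len(nc) / (nc + 1))
  cv <- cos(pi * seq_len(nr) / (nr + 1))
  f <- outer(2 * x * cw, 2i * y * cv, `+`)
  mag <- Mod(f)
  # a vanishing factor (both cosines at their zero, up to rounding) kills Z^2
  if (any(mag < 1e-14 * (2 * x + 2 * y + 1))) return(0)
  log_mag <- sum(log(mag))
  phase <- sum(Arg(f)) %% (2 * pi)
  # phase must be 0 or pi (mod 2 pi)
  k <- round(phase / pi)
  if (abs(phase - k * pi) > 1e-8 * (length(f) + 1)) {
    stop("non-real closed-form product: residual phase ", phase)
  }
  sign <- (-1)^(nr * (nc %/% 2)) * (-1)^(k %% 2)
  sign * exp(log_mag)
}

#' Partition function in closed form
#'
#' The analytic complete-filling partition function of an `nr` x `nc`
#' lattice:
#' `Z = 2^((nc/2) floor(nr/2)) *
#'  prod_{omega=1}^{nc/2} prod_{W=1}^{floor(nr/2)}
#'  [x^2 (1 + cos(2 pi omega/(nc+1))) + y^2 (1 + cos(2 pi W/(nr+1)))]`,
#' times `x^(nc/2)` when `nr` is odd (the unpaired central row must be packed
#' with horizontal dimers). Requires `nc` even; for `nc` odd with `nr` even
#' use the transposed lattice (x <-> y symmetry) or the squared form /
#' Pfaffian routes.
#'
#' @param shape A [grid_shape()] with `nc` even.
#' @param x,y Dimer activities (>= 0).
#' @param log If `TRUE` return `ln Z` (accumulated in log space, safe for
#'   large lattices).
#' @return Z (or `ln Z`).
#' @examples
#' z_closed(grid_shape(3, 4), 1, 1) # 11 coverings
#' @export
z_closed <- function(shape, x, y, log = FALSE) {
  shape <- as_grid_shape(shape)
  nr <- shape$nr; nc <- shape$nc
  if (nc %% 2 == 1L) {
    stop("closed form requires an even number of columns; ",
         "use the transposed lattice, z_squared_closed() or the Pfaffian route")
  }
  omega <- seq_len(nc %/% 2L)
  ws <- seq_len(nr %/% 2L)
  terms <- outer(x^2 * (1 + cos(2 * pi * omega / (nc + 1))),
                 y^2 * (1 + cos(2 * pi * ws / (nr + 1))), `+`)
  ln_z <- (nc / 2) * (nr %/% 2) * base::log(2) + sum(base::log(terms))
  if (nr %% 2 == 1L) ln_z <- ln_z + (nc / 2) * base::log(x)
  if (log) ln_z else exp(ln_z)
}

#' Complete-filling partition function (route dispatcher)
#'
#' Computes the partition function of a rectangular dimer lattice by any of
#' the four mutually validating routes: exhaustive enumeration, the
#' link-field trace expansion, the Pfaffian, or the analytic closed form.
#'
#' @param shape A [grid_shape()] with an even number of sites.
#' @param x,y Dimer activities (>= 0).
#' @param method One of `"closed"`, `"pfaffian"`, `"enumerate"`,
#'   `"symbolic"`.
#' @return Z, a double.
#' @examples
#' partition_function(grid_shape(3, 4), 1, 1, method = "closed") # 11
#' @export
partition_function <- function(shape, x, y,
                               method = c("closed", "pfaffian",
                                          "enumerate", "symbolic")) {
  shape <- as_grid_shape(shape)
  method <- match.arg(method)
  if (shape$n_sites %% 2 == 1L) {
    stop("complete dimer filling requires an even number of sites")
  }
  switch(method,
    closed = {
      if (shape$nc %% 2 == 0L) {
        z_closed(shape, x, y)
      } else if (shape$nr %% 2 == 0L) {
        z_closed(grid_shape(shape$nc, shape$nr), y, x)
      } else {
        sqrt(z_squared_closed(shape, x, y))
      }
    },
    pfaffian = partition_function_pfaffian(shape, x, y),
    enumerate = eval_matching_polynomial(matching_polynomial(shape), x, y),
    symbolic = eval_matching_polynomial(symbolic_partition_function(shape), x, y)
  )
}
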