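## Independent numerical oracles used to cross-check the closed-form and
## finite-volume implementations. These deliberately avoid the package's own
## computational paths.

## Bessel J0 by direct power series: J0(x) = sum_m (-1)^m (x/2)^(2m) / (m!)^2.
## Accurate to ~1e-12 for |x| <= 15 in double precision.
oracle_j0 <- function(x) {
  vapply(x, function(xx) {
    term <- 1
    total <- 1
    m <- 0
    while (abs(term) > 1e-17 && m < 80) {
      m <- m + 1
      term <- -term * (xx / 2)^2 / m^2
      total <- total + term
    }
    total
  }, numeric(1))
}

## Steady radial Poisson problem solved as a sparse linear system on a fine
## conservative grid (direct solve; independent of any time stepping):
##   (1/r) d/dr (r dc/dr) = -(k/D) for r <= R, 0 otherwise; c(S) = 0, c'(0) = 0.
## Returns cell centers and concentrations.
oracle_poisson_radial <- function(geom, k, D, n = 3000) {
  faces <- seq(0, geom$S, length.out = n + 1)
  dr <- geom$S / n
  centers <- (faces[-1] + faces[-(n + 1)]) / 2
  vol <- pi * (faces[-1]^2 - faces[-(n + 1)]^2)      # per unit height
  cond <- 2 * pi * faces / dr                        # D folded in below
  cond_outer <- 2 * pi * geom$S / (dr / 2)
  diag_main <- (cond[1:n] + c(cond[2:n], cond_outer)) / vol
  off <- cond[2:n] / vol[1:(n - 1)]                  # coupling i <-> i+1
  M <- Matrix::bandSparse(n, n,
                          k = c(-1, 0, 1),
                          diagonals = list(-cond[2:n] / vol[2:n],
                                           diag_main,
                                           -off),
                          symmetric = FALSE)
  s <- ifelse(centers <= geom$R, k / D, 0)
  cc <- as.numeric(Matrix::solve(M, s))
  list(r = centers, c = cc)
}

## Slowest decay rate (smallest eigenvalue) of the discrete radial diffusion
## operator with Dirichlet rim, via inverse power iteration with a sparse
## solve. Independent oracle for the 2.4048-based closed form.
oracle_slowest_rate <- function(geom, D, n = 2000, iters = 60) {
  faces <- seq(0, geom$S, length.out = n + 1)
  dr <- geom$S / n
  vol <- pi * (faces[-1]^2 - faces[-(n + 1)]^2)
  cond <- D * 2 * pi * faces / dr
  cond_outer <- D * 2 * pi * geom$S / (dr / 2)
  diag_main <- (cond[1:n] + c(cond[2:n], cond_outer)) / vol
  M <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                          diagonals = list(-cond[2:n] / vol[2:n],
                                           diag_main,
                                           -cond[2:n] / vol[1:(n - 1)]))
  x <- rep(1, n)
  fac <- Matrix::lu(M)
  for (i in seq_len(iters)) {
    x <- as.numeric(Matrix::solve(fac, x))
    x <- x / sqrt(sum(x^2))
  }
  ## V-weighted Rayleigh quotient (M is similar to a symmetric matrix
  ## under the cell-volume inner product)
  Mx <- as.numeric(M %*% x)
  sum(vol * x * Mx) / sum(vol * x * x)
}

## Standard small parameter set shared across tests.
test_geom <- function() synapse_geometry(R = 500e-9, S = 3e-6, h = 40e-9)
test_transport <- function() transport_params(2e-10)
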