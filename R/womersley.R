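## Analytic pulsatile pipe-flow (Womersley) velocity reconstruction.

# complex Bessel J0 and J1 by power series; accurate for |z| up to ~20,
# which covers Womersley numbers of cerebral arteries across the retained
# harmonics.
.besselJ0c <- function(z) {
  term <- rep(1 + 0i, length(z))
  acc <- term
  m <- 1
  repeat {
    term <- term * (-(z / 2)^2) / (m * m)
    acc <- acc + term
    if (all(Mod(term) < 1e-17 * pmax(Mod(acc), 1)) || m > 60) break
    m <- m + 1
  }
  acc
}

.besselJ1c <- function(z) {
  term <- rep(1 + 0i, length(z))
  acc <- term
  m <- 1
  repeat {
    term <- term * (-(z / 2)^2) / (m * (m + 1))
    acc <- acc + term
    if (all(Mod(term) < 1e-17 * pmax(Mod(acc), 1)) || m > 60) break
    m <- m + 1
  }
  (z / 2) * acc
}

# Gauss-Legendre nodes/weights on [0, 1] (Golub-Welsch)
.gauss_legendre01 <- function(n) {
  if (n == 1) return(list(x = 0.5, w = 1))
  i <- seq_len(n - 1)
  bsub <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- bsub
  J[cbind(i + 1, i)] <- bsub
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  o <- order(x)
  list(x = (x[o] + 1) / 2, w = w[o] / 2)
}

#' Reconstruct the analytic pulsatile velocity profile from an edge flow
#'
#' Fourier-decomposes a periodic flow series Q(t). The steady component maps
#' to the parabolic Poiseuille profile; each harmonic k maps to the
#' Womersley annular-Bessel profile at Womersley number
#' \eqn{\alpha_k = r \sqrt{k \omega \rho / \mu}}. Radial samples are placed
#' at Gauss-Legendre nodes so that the area quadrature of the reconstructed
#' profile reproduces Q(t) to a fraction of a percent.
#'
#' @param flow periodic flow samples (m^3/s) on a uniform grid covering one
#'   period (no duplicated endpoint).
#' @param period the period (s).
#' @param radius vessel radius (m).
#' @param fluid a [FluidProperties-class].
#' @param nHarmonics number of Fourier harmonics retained (0 = steady only);
#'   values beyond the Nyquist limit are truncated with a warning.
#' @param nRadial number of radial sample positions.
#' @return A [PlaneSample-class] with the velocity matrix (radial x time).
#' @export
womersleyProfile <- function(flow, period, radius,
                             fluid = fluidProperties(),
                             nHarmonics = 8, nRadial = 32) {
  if (radius <= 0) stop("radius must be > 0")
  if (nHarmonics < 0) stop("nHarmonics must be >= 0")
  N <- length(flow)
  nyq <- floor((N - 1) / 2)
  if (nHarmonics > nyq) {
    warning(sprintf("nHarmonics truncated to the Nyquist limit %d", nyq))
    nHarmonics <- nyq
  }
  Fh <- fft(flow) / N
  gl <- .gauss_legendre01(nRadial)
  r <- gl$x * radius
  weights <- 2 * pi * r * gl$w * radius  # integrates u(r) 2 pi r dr over [0, R]
  y <- r / radius
  A <- pi * radius^2
  tgrid <- (seq_len(N) - 1) * period / N
  omega <- 2 * pi / period
  ## steady part: parabolic profile
  U <- matrix(2 * Re(Fh[1]) / A * (1 - y^2), nRadial, N)
  if (nHarmonics >= 1) {
    for (k in seq_len(nHarmonics)) {
      Qk <- Fh[k + 1]
      if (Mod(Qk) == 0) next
      alpha <- radius * sqrt(k * omega * fluid@rho / fluid@mu)
      lam <- complex(real = -1 / sqrt(2), imaginary = 1 / sqrt(2)) * alpha  # i^{3/2} alpha
      J0l <- .besselJ0c(lam)
      J1l <- .besselJ1c(lam)
      shape <- (1 - .besselJ0c(lam * y) / J0l) /
               (1 - 2 * J1l / (lam * J0l))
      phase <- exp(1i * k * omega * tgrid)
      U <- U + 2 * Re((Qk / A) * outer(shape, phase))
    }
  }
  new("PlaneSample", radius = radius, r = r, weights = weights,
      velocity = U, Q = as.numeric(flow), time = tgrid)
}
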