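#' Slater radial term
#'
#' Radial building block \eqn{R(r) = c\, r^n e^{-\zeta r}} of a pseudoatom
#' density, with `c` in e/Angstrom^3 scale, integer `n >= 0` and
#' `zeta > 0` in 1/Angstrom.
#'
#' @param c Coefficient.
#' @param n Integer power of r.
#' @param zeta Exponent (1/Angstrom).
#' @return A `slater_term` list.
#' @export
slater_term <- function(c, n, zeta) {
  if (!is.finite(zeta) || zeta <= 0) stop("slater_term: zeta must be positive")
  if (n < 0 || n != round(n)) stop("slater_term: n must be a non-negative integer")
  structure(list(c = c, n = as.integer(n), zeta = zeta), class = "slater_term")
}

#' Radial norm of a Slater term
#'
#' \eqn{\int_0^\infty c\,r^{n+2} e^{-\zeta r} dr = c\,(n+2)!/\zeta^{n+3}}.
#'
#' @param term A [slater_term()].
#' @return Numeric scalar.
#' @export
slater_radial_integral <- function(term) {
  term$c * factorial(term$n + 2) / term$zeta^(term$n + 3)
}

#' Normalize Slater terms to an electron count
#'
#' Rescales the coefficients of a Slater sum so that
#' \eqn{4\pi \int R(r) r^2 dr} (or the plain radial integral when
#' `four_pi = FALSE`) equals `electrons`.
#'
#' @param terms List of [slater_term()].
#' @param electrons Target integral.
#' @param four_pi Include the solid-angle factor.
#' @return The rescaled list.
#' @export
slater_normalize <- function(terms, electrons, four_pi = TRUE) {
  tot <- sum(vapply(terms, slater_radial_integral, 0)) * (if (four_pi) 4 * pi else 1)
  if (abs(tot) < 1e-300) stop("slater_normalize: zero radial integral")
  lapply(terms, function(tm) { tm$c <- tm$c * electrons / tot; tm })
}

#' Fourier-Bessel transform of a Slater radial function
#'
#' Computes \eqn{\langle j_l \rangle(h) = \int_0^\infty R(r)\,
#' j_l(2\pi h r)\, r^2\, dr} for \eqn{R(r) = c\,r^n e^{-\zeta r}} and
#' \eqn{l \le 4}, the kernel convention being plane waves
#' \eqn{e^{2\pi i\, h\cdot r}} with \eqn{|h| = 1/d}. The closed form uses
#' the finite sine/cosine expansion of the spherical Bessel functions; at
#' small \eqn{2\pi h/\zeta} a power series is used to avoid cancellation.
#'
#' @param term A [slater_term()].
#' @param l Bessel order, 0..4.
#' @param hmag Scattering vector magnitude(s) \eqn{|h|} in 1/Angstrom
#'   (vectorized, each >= 0).
#' @return Numeric vector of transform values.
#' @export
slater_fourier_bessel <- function(term, l, hmag) {
  if (l < 0 || l > 4 || l != round(l)) stop("slater_fourier_bessel: l must be an integer in 0..4")
  if (term$n + 2 < l + 1) {
    stop("slater_fourier_bessel: need n >= l - 1 for an integrable kernel")
  }
  if (any(hmag < 0)) stop("slater_fourier_bessel: hmag must be >= 0")
  K <- 2 * pi * hmag
  zeta <- term$zeta
  N <- term$n + 2L
  out <- numeric(length(K))
  small <- K < 0.5 * zeta
  if (any(small)) out[small] <- sjb_series(term$c, N, zeta, l, K[small])
  if (any(!small)) out[!small] <- sjb_closed(term$c, N, zeta, l, K[!small])
  out
}

# power series sum_k (-1)^k K^(l+2k) / (2^k k! (2l+2k+1)!!) * (N+l+2k)! / zeta^(N+l+2k+1)
sjb_series <- function(c0, N, zeta, l, K) {
  out <- numeric(length(K))
  dfact <- function(m) if (m <= 0) 1 else prod(seq(m, 1, by = -2))
  for (i in seq_along(K)) {
    Ki <- K[i]
    if (Ki == 0) {
      out[i] <- if (l == 0) c0 * factorial(N) / zeta^(N + 1) else 0
      next
    }
    s <- 0
    term_k <- Ki^l / dfact(2 * l + 1) * factorial(N + l) / zeta^(N + l + 1)
    k <- 0
    repeat {
      s <- s + term_k
      ratio <- -Ki^2 * (N + l + 2 * k + 1) * (N + l + 2 * k + 2) /
        (zeta^2 * 2 * (k + 1) * (2 * l + 2 * k + 3))
      term_k <- term_k * ratio
      k <- k + 1
      if (abs(term_k) < 1e-17 * abs(s) || k > 200) break
    }
    out[i] <- c0 * s
  }
  out
}

# closed form via j_l(x) = s_l(x) sin x + c_l(x) cos x, rational in 1/x,
# and  int r^p e^(-zeta r) sin/cos(K r) dr = Im/Re[ p! / (zeta - iK)^(p+1) ]
sjb_closed <- function(c0, N, zeta, l, K) {
  # coefficient tables: alpha[k] multiplies x^-k sin x, beta[k] multiplies x^-k cos x
  ab <- switch(as.character(l),
    "0" = list(a = c(`1` = 1), b = numeric(0)),
    "1" = list(a = c(`2` = 1), b = c(`1` = -1)),
    "2" = list(a = c(`3` = 3, `1` = -1), b = c(`2` = -3)),
    "3" = list(a = c(`4` = 15, `2` = -6), b = c(`3` = -15, `1` = 1)),
    "4" = list(a = c(`5` = 105, `3` = -45, `1` = 1), b = c(`4` = -105, `2` = 10))
  )
  z <- complex(real = zeta, imaginary = -K)
  out <- numeric(length(K))
  for (k in as.integer(names(ab$a))) {
    p <- N - k
    out <- out + ab$a[as.character(k)] * K^(-k) * Im(factorial(p) / z^(p + 1))
  }
  for (k in as.integer(names(ab$b))) {
    p <- N - k
    out <- out + ab$b[as.character(k)] * K^(-k) * Re(factorial(p) / z^(p + 1))
  }
  c0 * out
}
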