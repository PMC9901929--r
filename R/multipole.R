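#' Hansen-Coppens pseudoatom parameter set
#'
#' Bundles everything needed to evaluate one pseudoatom's density and its
#' aspherical form factor: spherical core and valence Slater sums, the
#' populations \eqn{P_c}, \eqn{P_v}, the valence contraction \eqn{\kappa},
#' the per-\eqn{l} deformation contractions \eqn{\kappa'_l}, one deformation
#' Slater radial per \eqn{l}, and the multipole populations \eqn{P_{lm}}.
#'
#' Normalization conventions (enforced here):
#' core terms integrate to `n_core` electrons
#' (\eqn{4\pi\int \rho\, r^2 dr = N_{core}}), the valence shape to 1
#' electron, and each deformation radial to unit radial integral
#' (\eqn{\int R_l\, r^2 dr = 1}) so that a monopole population
#' \eqn{P_{00}} adds exactly \eqn{P_{00}} electrons. Consequently
#' \eqn{f(0) = P_c + P_v + P_{00}}, the pseudoatom electron count.
#'
#' @param element Element symbol.
#' @param core List of [slater_term()] (may be empty for H).
#' @param valence List of [slater_term()].
#' @param n_core Number of core electrons.
#' @param p_c Core population (electrons; default `n_core`).
#' @param p_v Valence population (electrons).
#' @param kappa Valence expansion/contraction parameter (> 0).
#' @param kappa_prime Numeric length 5, \eqn{\kappa'_l} for l = 0..4.
#' @param deformation List of up to 5 [slater_term()] (index l+1), or `NULL`
#'   entries for unused orders.
#' @param p_lm List of length 5; element l+1 is a numeric vector of length
#'   2l+1 holding \eqn{P_{lm}} for m = -l..l.
#' @param check If `TRUE`, verify the normalization invariants.
#' @return A `pseudoatom_parameters` object.
#' @export
pseudoatom_parameters <- function(element, core, valence, n_core,
                                  p_c = n_core, p_v,
                                  kappa = 1, kappa_prime = rep(1, 5),
                                  deformation = vector("list", 5),
                                  p_lm = empty_plm(), check = TRUE) {
  stopifnot(length(kappa_prime) == 5, length(p_lm) == 5)
  if (kappa <= 0 || any(kappa_prime <= 0)) {
    stop("pseudoatom_parameters: kappa and kappa_prime must be positive")
  }
  for (l in 0:4) {
    if (length(p_lm[[l + 1]]) != 2 * l + 1) {
      stop("pseudoatom_parameters: p_lm[[", l + 1, "]] must have length ", 2 * l + 1)
    }
    if (any(p_lm[[l + 1]] != 0) && is.null(deformation[[l + 1]])) {
      stop("pseudoatom_parameters: populations for l=", l, " but no deformation radial")
    }
  }
  # normalize deformation radials to unit radial integral
  deformation <- lapply(deformation, function(tm) {
    if (is.null(tm)) return(NULL)
    tm$c <- tm$c / slater_radial_integral(tm)
    tm
  })
  obj <- structure(list(
    element = element, core = core, valence = valence, n_core = n_core,
    p_c = p_c, p_v = p_v, kappa = kappa, kappa_prime = kappa_prime,
    deformation = deformation, p_lm = p_lm
  ), class = "pseudoatom_parameters")
  if (check) validate_pseudoatom(obj)
  obj
}

empty_plm <- function() lapply(0:4, function(l) numeric(2 * l + 1))

validate_pseudoatom <- function(p, tol = 1e-6) {
  core_int <- 4 * pi * sum(vapply(p$core, slater_radial_integral, 0))
  if (abs(core_int - p$n_core) > tol) {
    stop("pseudoatom_parameters (", p$element, "): core density integrates to ",
         signif(core_int, 8), " electrons, expected ", p$n_core)
  }
  val_int <- 4 * pi * sum(vapply(p$valence, slater_radial_integral, 0))
  if (abs(val_int - 1) > tol) {
    stop("pseudoatom_parameters (", p$element, "): valence shape integrates to ",
         signif(val_int, 8), ", expected 1")
  }
  invisible(p)
}

# electron count of the pseudoatom: f(0)
pseudoatom_electrons <- function(p) {
  p$p_c + p$p_v + p$p_lm[[1]][1]
}

#' Build a local coordinate frame from two directions
#'
#' The first direction becomes the local z axis exactly; the second is
#' Gram-Schmidt-orthogonalized into the local x axis; y = z cross x gives a
#' right-handed orthonormal frame. The returned `rotation` maps local to
#' (crystal-)Cartesian components: `cart = rotation %*% local`.
#'
#' @param axis1 Cartesian direction for local z (need not be normalized).
#' @param axis2 Cartesian direction defining the zx plane.
#' @param label Atom label used in error messages.
#' @return A `local_frame`: list with `rotation` (3x3, det +1).
#' @export
local_frame_from_vectors <- function(axis1, axis2, label = "?") {
  n1 <- sqrt(sum(axis1^2)); n2 <- sqrt(sum(axis2^2))
  if (n1 < 1e-10 || n2 < 1e-10) stop("local frame for ", label, ": zero-length axis vector")
  e3 <- axis1 / n1
  cosang <- abs(sum(e3 * axis2 / n2))
  if (cosang > cos(pi / 180)) {
    stop("local frame for ", label, ": axis directions are collinear (< 1 degree apart)")
  }
  v <- axis2 - sum(axis2 * e3) * e3
  e1 <- v / sqrt(sum(v^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  R <- cbind(e1, e2, e3)
  dimnames(R) <- NULL
  structure(list(rotation = R), class = "local_frame")
}

#' The identity local frame
#'
#' @return A `local_frame` whose rotation is the identity; appropriate for
#'   spherical atoms and whenever no axis recipe applies.
#' @export
identity_frame <- function() structure(list(rotation = diag(3)), class = "local_frame")

#' Aspherical (Hansen-Coppens) atomic form factor
#'
#' Analytic Fourier transform of the pseudoatom density at one or more
#' Bragg vectors, in the \eqn{e^{2\pi i h\cdot r}} convention with
#' \eqn{|h| = 1/d}:
#' \deqn{f(h) = P_c f_{core}(|h|) + P_v f_{val}(|h|/\kappa)
#'   + \sum_l 4\pi i^l \langle j_l\rangle(|h|/\kappa'_l)
#'     \sum_m P_{lm} d_{lm}(\hat u_{local})}
#' where \eqn{\hat u_{local}} is the unit scattering vector expressed in
#' the atom's local frame, and the \eqn{\kappa}-scalings implement the
#' real-space contractions \eqn{\kappa^3\rho(\kappa r)}.
#'
#' @param params A [pseudoatom_parameters()].
#' @param frame A `local_frame` (identity for purely spherical atoms).
#' @param h_cart Cartesian scattering vector(s) in 1/Angstrom: length-3
#'   vector or n x 3 matrix.
#' @return Complex vector of form-factor values (electrons).
#' @export
aspherical_form_factor <- function(params, frame = identity_frame(), h_cart) {
  if (is.null(dim(h_cart))) h_cart <- matrix(h_cart, nrow = 1)
  hmag <- sqrt(rowSums(h_cart^2))
  f <- complex(real = rep(0, length(hmag)), imaginary = 0)

  # spherical core (per-electron shape times P_c)
  if (params$n_core > 0 && length(params$core)) {
    fc <- rowSums(vapply(params$core, function(tm) {
      slater_fourier_bessel(tm, 0, hmag)
    }, numeric(length(hmag))) |> as_matrix_cols(length(hmag)))
    f <- f + params$p_c * (4 * pi * fc) / params$n_core
  }
  # kappa-scaled spherical valence
  if (length(params$valence)) {
    fv <- rowSums(vapply(params$valence, function(tm) {
      slater_fourier_bessel(tm, 0, hmag / params$kappa)
    }, numeric(length(hmag))) |> as_matrix_cols(length(hmag)))
    f <- f + params$p_v * 4 * pi * fv
  }
  # multipolar deformation
  any_def <- any(vapply(0:4, function(l) any(params$p_lm[[l + 1]] != 0), TRUE))
  if (any_def) {
    u <- h_cart / ifelse(hmag > 0, hmag, 1)
    u[hmag == 0, ] <- rep(c(0, 0, 1), each = sum(hmag == 0))
    u_loc <- u %*% frame$rotation    # rows: R^T u
    for (l in 0:4) {
      plm <- params$p_lm[[l + 1]]
      if (all(plm == 0)) next
      rad <- slater_fourier_bessel(params$deformation[[l + 1]], l,
                                   hmag / params$kappa_prime[l + 1])
      ang <- numeric(length(hmag))
      for (m in -l:l) {
        if (plm[m + l + 1] == 0) next
        ang <- ang + plm[m + l + 1] * real_spherical_harmonic_density(l, m, u_loc)
      }
      f <- f + 4 * pi * (1i)^l * rad * ang
    }
  }
  f
}

# vapply over a single row returns a vector; keep matrix orientation stable
as_matrix_cols <- function(x, nrow) {
  if (is.null(dim(x))) matrix(x, nrow = nrow) else x
}
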