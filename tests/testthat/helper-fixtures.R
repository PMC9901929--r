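# Shared small fixtures, built in code.

minimal_cif <- function() {
  paste(
    "data_test",
    "_cell_length_a 10.0",
    "_cell_length_b 10.0",
    "_cell_length_c 10.0",
    "_cell_angle_alpha 90",
    "_cell_angle_beta 90",
    "_cell_angle_gamma 90",
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "  'x,y,z'",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy",
    "_atom_site_U_iso_or_equiv",
    "C1 C 0.0 0.0 0.0 1.0 0.02",
    sep = "\n")
}

# a tiny P1 structure with one carbon, unit form factors make phases exact
point_scatterer_structure <- function(frac = c(0, 0, 0), u_iso = 0) {
  crystal_structure(
    unit_cell(8, 8, 8),
    list("x,y,z"),
    tibble::tibble(label = "C1", element = "C",
                   x = frac[1], y = frac[2], z = frac[3],
                   occ = 1, u_iso = u_iso, part = 0L, model = "iam"))
}

unit_ff_table <- function(structure, hkl) {
  closure <- hkl_symmetry_closure(structure, hkl)
  tsc_table(structure$atoms$label, closure,
            matrix(1 + 0i, nrow(closure), nrow(structure$atoms)))
}

# random pseudoatom parameter set for property tests
random_pseudoatom <- function() {
  core <- slater_normalize(list(slater_term(1, 0, runif(1, 18, 30))), 2)
  val <- slater_normalize(list(slater_term(1, 2, runif(1, 5, 10))), 1)
  defr <- lapply(0:4, function(l) slater_term(1, max(2, l), runif(1, 4, 9)))
  plm <- lapply(0:4, function(l) runif(2 * l + 1, -0.3, 0.3))
  pseudoatom_parameters("N", core, val, n_core = 2, p_c = 2,
                        p_v = runif(1, 4, 6), kappa = runif(1, 0.85, 1.15),
                        kappa_prime = runif(5, 0.85, 1.2),
                        deformation = defr, p_lm = plm)
}

random_frame <- function() {
  repeat {
    a <- rnorm(3); b <- rnorm(3)
    ok <- tryCatch({ local_frame_from_vectors(a, b); TRUE }, error = function(e) FALSE)
    if (ok) return(local_frame_from_vectors(a, b))
  }
}

# brute-force numerical Fourier transform of a pseudoatom density
# (radial Gauss-Legendre x product angular grid); the independent oracle
brute_force_form_factor <- function(params, frame, h_list,
                                    nr = 140, nt = 80, nphi = 90, rmax = 10) {
  gl <- function(n, a, b) {
    J <- matrix(0, n, n); i <- 1:(n - 1); bb <- i / sqrt(4 * i^2 - 1)
    for (j in i) { J[j, j + 1] <- bb[j]; J[j + 1, j] <- bb[j] }
    e <- eigen(J, symmetric = TRUE)
    list(x = (b - a) / 2 * e$values + (a + b) / 2, w = (b - a) / 2 * 2 * e$vectors[1, ]^2)
  }
  qr <- gl(nr, 0, rmax); qt <- gl(nt, -1, 1)
  phi <- (0:(nphi - 1) + 0.5) * 2 * pi / nphi
  ct <- qt$x; st <- sqrt(1 - ct^2)
  U <- cbind(as.vector(outer(st, cos(phi))), as.vector(outer(st, sin(phi))),
             rep(ct, nphi))
  WU <- rep(qt$w, nphi) * (2 * pi / nphi)
  Uloc <- U %*% frame$rotation
  eval_terms <- function(terms, r) {
    if (!length(terms)) return(rep(0, length(r)))
    rowSums(vapply(terms, function(tm) tm$c * r^tm$n * exp(-tm$zeta * r),
                   numeric(length(r))))
  }
  rho_sph <- function(r) {
    core <- if (params$n_core > 0) {
      params$p_c / params$n_core * eval_terms(params$core, r)
    } else 0
    val <- params$p_v * params$kappa^3 *
      eval_terms(params$valence, params$kappa * r)
    core + val
  }
  ang_tot <- matrix(0, nrow(U), 5)
  for (l in 0:4) {
    a <- rep(0, nrow(U))
    for (m in -l:l) {
      p <- params$p_lm[[l + 1]][m + l + 1]
      if (p != 0) a <- a + p * real_spherical_harmonic_density(l, m, Uloc)
    }
    ang_tot[, l + 1] <- a
  }
  def_rad <- vapply(0:4, function(l) {
    tm <- params$deformation[[l + 1]]
    if (is.null(tm)) return(rep(0, nr))
    kp <- params$kappa_prime[l + 1]
    kp^3 * tm$c * (kp * qr$x)^tm$n * exp(-tm$zeta * kp * qr$x)
  }, numeric(nr))
  sph <- rho_sph(qr$x)
  vapply(seq_len(nrow(h_list)), function(i) {
    h <- h_list[i, ]
    hU <- U %*% h
    acc <- 0 + 0i
    for (j in seq_len(nr)) {
      rho <- sph[j] + as.vector(ang_tot %*% def_rad[j, ])
      acc <- acc + qr$w[j] * qr$x[j]^2 * sum(WU * rho * exp(2i * pi * qr$x[j] * hU))
    }
    acc
  }, complex(1))
}

# minimal bank entry text for parse tests
mini_entry <- function(type_id, element, neighbors, ring = "false",
                       element_block = element) {
  # normalized valence term: c = zeta^(n+3) / ((n+2)! * 4*pi)
  nrm <- function(n, z) z^(n + 3) / (factorial(n + 2) * 4 * pi)
  val <- switch(element_block,
    H = paste(nrm(0, 3.7795), 0, 3.7795),
    C = paste(nrm(2, 6.14), 2, 6.14),
    N = paste(nrm(2, 7.37), 2, 7.37),
    O = paste(nrm(2, 8.60), 2, 8.60),
    Na = paste(nrm(4, 2.77), 4, 2.77))
  core <- switch(element_block,
    H = "none",
    Na = paste(10 * nrm(0, 40.4), 0, 40.4),
    paste(2 * nrm(0, 20), 0, 20))
  ncore <- switch(element_block, H = 0, Na = 10, 2)
  pv <- switch(element_block, H = 1, C = 4, N = 5, O = 6, Na = 0)
  paste(
    paste("TYPE", type_id),
    paste("ELEMENT", element),
    paste("NEIGHBORS", neighbors),
    paste("RING", ring),
    "AXES none",
    paste("RADIAL CORE", core),
    paste("RADIAL VALENCE", val),
    paste("POP NCORE", ncore, "PC", ncore, "PV", pv, "KAPPA 1 KPRIME 1 1 1 1 1"),
    "END", sep = "\n")
}
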