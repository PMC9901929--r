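test_that("Slater Fourier-Bessel closed form agrees with adaptive quadrature", {
  set.seed(101)
  jl_num <- function(l, x) {
    # reference spherical Bessel from the explicit trigonometric forms
    out <- numeric(length(x))
    nz <- x != 0
    xs <- x[nz]
    out[nz] <- switch(as.character(l),
      "0" = sin(xs) / xs,
      "1" = sin(xs) / xs^2 - cos(xs) / xs,
      "2" = (3 / xs^3 - 1 / xs) * sin(xs) - 3 * cos(xs) / xs^2,
      "3" = (15 / xs^4 - 6 / xs^2) * sin(xs) - (15 / xs^3 - 1 / xs) * cos(xs),
      "4" = (105 / xs^5 - 45 / xs^3 + 1 / xs) * sin(xs) - (105 / xs^4 - 10 / xs^2) * cos(xs))
    out[!nz] <- if (l == 0) 1 else 0
    out
  }
  checked <- 0
  while (checked < 100) {
    n <- sample(0:6, 1); l <- sample(0:4, 1)
    if (n + 2 < l + 1) next
    zeta <- runif(1, 2, 30); h <- runif(1, 0, 2.5); cc <- runif(1, 0.5, 2)
    tm <- slater_term(cc, n, zeta)
    a <- slater_fourier_bessel(tm, l, h)
    q <- stats::integrate(function(r) cc * r^(n + 2) * exp(-zeta * r) *
                            jl_num(l, 2 * pi * h * r),
                          0, 60 / zeta, rel.tol = 1e-13, subdivisions = 4000)$value
    # relative to the transform scale so near-zeros do not inflate the ratio
    scale0 <- cc * factorial(n + 2) / zeta^(n + 3)
    expect_lt(abs(a - q) / max(abs(q), 1e-3 * scale0), 1e-8)
    checked <- checked + 1
  }
})

test_that("Slater transform limits at h = 0 follow from j_l(0)", {
  tm <- slater_term(2, 3, 6)
  expect_equal(slater_fourier_bessel(tm, 0, 0), 2 * factorial(5) / 6^6)
  for (l in 1:4) expect_identical(slater_fourier_bessel(tm, l, 0), 0)
  expect_error(slater_fourier_bessel(tm, 5, 0.1), "0..4")
  expect_error(slater_fourier_bessel(slater_term(1, 0, 5), 3, 0.2), "integrable")
})

test_that("density-normalized spherical harmonics integrate correctly on the sphere", {
  # |d_lm| has absolute-value kinks along its nodal curves (theta = const and
  # phi = const), so the quadrature splits both axes at the zeros and applies
  # Gauss-Legendre on each smooth patch.
  gl24 <- local({
    n <- 24
    J <- matrix(0, n, n); i <- 1:(n - 1); bb <- i / sqrt(4 * i^2 - 1)
    for (j in i) { J[j, j + 1] <- bb[j]; J[j + 1, j] <- bb[j] }
    e <- eigen(J, symmetric = TRUE)
    list(x = e$values, w = 2 * e$vectors[1, ]^2)
  })
  piece_nodes <- function(breaks) {
    xs <- ws <- numeric(0)
    for (i in seq_len(length(breaks) - 1)) {
      a <- breaks[i]; b <- breaks[i + 1]
      xs <- c(xs, (b - a) / 2 * gl24$x + (a + b) / 2)
      ws <- c(ws, (b - a) / 2 * gl24$w)
    }
    list(x = xs, w = ws)
  }
  sphere_sum <- function(f, l, m) {
    phi_breaks <- if (m == 0) c(0, 2 * pi) else {
      sort(unique(c(0, 2 * pi, (0:(4 * abs(m))) * pi / (2 * abs(m)))))
    }
    phi_breaks <- phi_breaks[phi_breaks >= 0 & phi_breaks <= 2 * pi + 1e-12]
    # theta zeros located from the package function itself along a reference phi
    phi_ref <- if (m >= 0) 0 else pi / (2 * abs(m))
    th_grid <- seq(1e-6, pi - 1e-6, length.out = 2001)
    vals <- vapply(th_grid, function(th) {
      real_spherical_harmonic_density(l, m, c(sin(th) * cos(phi_ref),
                                              sin(th) * sin(phi_ref), cos(th)))
    }, 0)
    sgn <- sign(vals)
    flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    th_breaks <- c(0, vapply(flips, function(i) {
      stats::uniroot(function(th) real_spherical_harmonic_density(
        l, m, c(sin(th) * cos(phi_ref), sin(th) * sin(phi_ref), cos(th))),
        c(th_grid[i], th_grid[i + 1]), tol = 1e-14)$root
    }, 0), pi)
    qth <- piece_nodes(sort(unique(th_breaks)))
    qph <- piece_nodes(phi_breaks)
    total <- 0
    for (i in seq_along(qth$x)) {
      th <- qth$x[i]
      u <- cbind(sin(th) * cos(qph$x), sin(th) * sin(qph$x), rep(cos(th), length(qph$x)))
      total <- total + qth$w[i] * sin(th) * sum(qph$w * f(u))
    }
    total
  }
  expect_equal(sphere_sum(function(u) real_spherical_harmonic_density(0, 0, u), 0, 0),
               1, tolerance = 1e-10)
  for (l in 1:4) for (m in -l:l) {
    expect_equal(sphere_sum(function(u) abs(real_spherical_harmonic_density(l, m, u)), l, m),
                 2, tolerance = 1e-6)
    expect_equal(sphere_sum(function(u) real_spherical_harmonic_density(l, m, u), l, m),
                 0, tolerance = 1e-10)  # zero net charge for l >= 1
  }
  # dipole geometry: maximal along +z, zero along x
  expect_gt(real_spherical_harmonic_density(1, 0, c(0, 0, 1)), 0.3)
  expect_equal(real_spherical_harmonic_density(1, 0, c(1, 0, 0)), 0)
  expect_error(real_spherical_harmonic_density(5, 0, c(0, 0, 1)), "0..4")
})

test_that("aspherical form factor matches the brute-force 3D Fourier oracle", {
  set.seed(202)
  for (rep in 1:3) {
    p <- random_pseudoatom()
    fr <- random_frame()
    H <- matrix(rnorm(9, 0, 0.4), 3, 3)
    fa <- aspherical_form_factor(p, fr, H)
    fn <- brute_force_form_factor(p, fr, H)
    expect_lt(max(Mod(fa - fn) / Mod(fn)), 1e-5)
  }
})

test_that("form factor at h = 0 is the pseudoatom electron count and the spherical limit is real", {
  p <- random_pseudoatom()
  f0 <- aspherical_form_factor(p, identity_frame(), c(0, 0, 0))
  expect_equal(Re(f0), p$p_c + p$p_v + p$p_lm[[1]][1], tolerance = 1e-10)
  expect_equal(Im(f0), 0)
  # spherical limit: all P_lm zero, kappa = kappa' = 1 -> real everywhere
  ps <- pseudoatom_parameters(p$element, p$core, p$valence, n_core = p$n_core,
                              p_c = p$p_c, p_v = p$p_v)
  H <- matrix(rnorm(30, 0, 0.5), 10, 3)
  f <- aspherical_form_factor(ps, identity_frame(), H)
  expect_equal(max(abs(Im(f))), 0)
  hmag <- sqrt(rowSums(H^2))
  # spherically symmetric: equal |h| gives equal f
  f2 <- aspherical_form_factor(ps, identity_frame(),
                               cbind(hmag, 0, 0))
  expect_equal(Re(f), Re(f2), tolerance = 1e-12)
})

test_that("form factors are Hermitian and frame-equivariant", {
  set.seed(203)
  p <- random_pseudoatom()
  fr <- random_frame()
  H <- matrix(rnorm(15, 0, 0.5), 5, 3)
  f_plus <- aspherical_form_factor(p, fr, H)
  f_minus <- aspherical_form_factor(p, fr, -H)
  expect_lt(max(Mod(f_minus - Conj(f_plus))), 1e-12)
  # rotating both frame and h leaves f unchanged
  Q <- random_frame()$rotation
  fr_rot <- structure(list(rotation = Q %*% fr$rotation), class = "local_frame")
  f_rot <- aspherical_form_factor(p, fr_rot, H %*% t(Q))
  expect_lt(max(Mod(f_rot - f_plus)), 1e-10)
})

test_that("local frames are orthonormal, right-handed, equivariant, and reject degenerate axes", {
  fr <- local_frame_from_vectors(c(0, 0, 1), c(1, 0, 1))
  expect_equal(fr$rotation, diag(3), tolerance = 1e-12)
  set.seed(204)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    if (abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)) > 0.99) next
    fr <- local_frame_from_vectors(a, b)
    R <- fr$rotation
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
    Q <- random_frame()$rotation
    fr2 <- local_frame_from_vectors(as.numeric(Q %*% a), as.numeric(Q %*% b))
    expect_lt(max(abs(fr2$rotation - Q %*% R)), 1e-8)
  }
  expect_error(local_frame_from_vectors(c(0, 0, 1), c(0, 0, -2), "X9"), "X9")
})
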