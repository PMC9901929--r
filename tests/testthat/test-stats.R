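test_that("R factors reproduce hand-computed values and the gt threshold", {
  # perfect fit
  s <- r_factors(c(100, 25, 9), c(1, 1, 1), sqrt(c(100, 25, 9)), k = 1)
  expect_equal(s$r1_all, 0)
  expect_equal(s$wr2_all, 0)
  # worked 3-reflection example: |Fo| = 10, 20, 30; k|Fc| = 9, 22, 30
  s2 <- r_factors(c(100, 400, 900), c(1, 1, 1), c(9, 22, 30), k = 1)
  expect_equal(s2$r1_all, 100 * (1 + 2 + 0) / 60)
  # gt counting: Fo2 = 5 sigma and 1 sigma
  s3 <- r_factors(c(5, 1), c(1, 1), c(2, 1), k = 1)
  expect_equal(s3$n_gt, 1)
  expect_equal(s3$n_all, 2)
  expect_warning(r_factors(c(1, 1), c(1, 1), c(1, 1), k = 1), "gt")
})

test_that("a model fitted to its own data yields a flat difference map", {
  st <- make_structure("water_P1bar")
  refl <- simulate_reflections(st, simulation_recipe(d_min = 0.8, noise_fraction = 0,
                                                     floor = 0, seed = 1),
                               model = "iam")
  st$atoms$model <- "iam"
  H <- as.matrix(refl[, c("h", "k", "l")])
  tb <- make_form_factor_table(st, H)
  fc <- structure_factors(st, tb, H)$f_calc
  map <- difference_map(st, refl, fc, k = 1)
  expect_lt(max(abs(map$values)), 1e-6)
  ph <- peak_hole(map)
  expect_lt(abs(ph$peak), 1e-6)
  expect_lt(abs(ph$hole), 1e-6)
  # zero-mean map (origin term excluded)
  expect_lt(abs(mean(map$values)), 1e-10)
})

test_that("an omitted scatterer shows up as the map maximum at its site, an extra one as the minimum", {
  # the retained model must carry most of the scattering power, otherwise its
  # phases are too poor for the difference synthesis to localize the missing
  # atom (as in real omit maps)
  st_full <- crystal_structure(unit_cell(8, 8, 8), list("x,y,z"),
    tibble::tibble(label = c("O1", "N1", "O2", "S1", "C1"),
                   element = c("O", "N", "O", "S", "C"),
                   x = c(0.10, 0.80, 0.15, 0.45, 0.62),
                   y = c(0.20, 0.15, 0.75, 0.55, 0.37),
                   z = c(0.30, 0.25, 0.70, 0.15, 0.71),
                   occ = 1, u_iso = 0.02, part = 0L, model = "iam"))
  st_omit <- st_full
  st_omit$atoms <- st_omit$atoms[1:4, ]
  refl <- simulate_reflections(st_full, simulation_recipe(d_min = 0.8,
                                                          noise_fraction = 0,
                                                          floor = 0, seed = 1),
                               model = "iam")
  H <- as.matrix(refl[, c("h", "k", "l")])
  tb <- make_form_factor_table(st_omit, H)
  fc <- structure_factors(st_omit, tb, H)$f_calc
  map <- difference_map(st_omit, refl, fc, k = 1)
  ph <- peak_hole(map)
  expect_gt(ph$peak, 3 * abs(ph$hole))
  # peak located within one voxel of the omitted atom
  d <- ph$peak_frac - c(0.62, 0.37, 0.71)
  expect_lt(max(abs(d - round(d))), 1.5 / min(map$dim))

  # inverted case: model has an extra atom -> hole at its site
  refl_omit <- simulate_reflections(st_omit, simulation_recipe(d_min = 0.8,
                                                               noise_fraction = 0,
                                                               floor = 0, seed = 1),
                                    model = "iam")
  tb_full <- make_form_factor_table(st_full, H)
  fc_full <- structure_factors(st_full, tb_full, H)$f_calc
  map2 <- difference_map(st_full, refl_omit, fc_full, k = 1)
  ph2 <- peak_hole(map2)
  expect_lt(ph2$hole, 0)
  expect_gt(abs(ph2$hole), 3 * ph2$peak)
  d2 <- ph2$hole_frac - c(0.62, 0.37, 0.71)
  expect_lt(max(abs(d2 - round(d2))), 1.5 / min(map2$dim))
})

test_that("omit-map localization succeeds for at least 19 of 20 random placements", {
  set.seed(31)
  hits <- 0
  base <- tibble::tibble(label = c("O1", "N1", "S1"),
                         element = c("O", "N", "S"),
                         x = c(0.15, 0.80, 0.45), y = c(0.25, 0.20, 0.70),
                         z = c(0.35, 0.30, 0.15),
                         occ = 1, u_iso = 0.02, part = 0L, model = "iam")
  for (i in 1:20) {
    pos <- runif(3, 0.05, 0.95)
    cl <- unit_cell(7, 7, 7)
    too_close <- any(vapply(seq_len(nrow(base)), function(j) {
      taamkit:::frac_distance(cl, as.numeric(base[j, c("x", "y", "z")]), pos) < 1.2
    }, TRUE))
    if (too_close) next
    st_full <- crystal_structure(cl, list("x,y,z"),
      dplyr::bind_rows(base, tibble::tibble(
        label = "C9", element = "C", x = pos[1], y = pos[2], z = pos[3],
        occ = 1, u_iso = 0.02, part = 0L, model = "iam")))
    st_omit <- st_full; st_omit$atoms <- st_omit$atoms[seq_len(nrow(base)), ]
    refl <- simulate_reflections(st_full, simulation_recipe(d_min = 0.9,
                                                            noise_fraction = 0,
                                                            floor = 0, seed = i),
                                 model = "iam")
    H <- as.matrix(refl[, c("h", "k", "l")])
    tb <- make_form_factor_table(st_omit, H)
    fc <- structure_factors(st_omit, tb, H)$f_calc
    ph <- peak_hole(difference_map(st_omit, refl, fc, k = 1, spacing = 0.2))
    d <- ph$peak_frac - pos
    d <- d - round(d)
    if (max(abs(d)) < 1.5 / min(difference_map(st_omit, refl, fc, k = 1, spacing = 0.2)$dim)) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 19)
})

test_that("fractal curves behave correctly for Gaussian, constant and bimodal maps", {
  skeleton <- function(values, n) {
    structure(list(values = array(values, dim = n), dim = n,
                   cell = unit_cell(5, 5, 5), spacing = 0.1),
              class = "residual_map")
  }
  set.seed(33)
  n <- c(40L, 40L, 40L)
  g <- skeleton(rnorm(prod(n), 0, 0.05), n)
  fc <- fractal_dimension(g)
  apex <- fc$rho0[which.max(fc$df)]
  binw <- diff(fc$rho0[1:2])
  expect_lt(abs(apex), binw + 1e-12)
  expect_gte(max(fc$df), 2.9)
  expect_lte(max(fc$df), 3.0)
  # unimodal around the apex (allowing flat zero tails)
  pos <- fc$df[fc$df > 0]
  peak_at <- which.max(pos)
  expect_true(all(diff(pos[1:peak_at]) > -1e-9) ||
                sum(diff(sign(diff(pos))) != 0) <= 6)

  cm <- skeleton(rep(0.2, prod(n)), n)
  fcc <- fractal_dimension(cm)
  expect_equal(nrow(fcc), 1)
  expect_equal(fcc$df, 3)

  bi <- skeleton(sample(c(-0.3, 0.3), prod(n), replace = TRUE), n)
  fcb <- fractal_dimension(bi)
  mx <- max(fcb$df)
  at_ends <- fcb$df[c(1, nrow(fcb))]
  # the two end levels are the (near-equal) maxima; the plateau between is lower
  expect_equal(at_ends[1], mx, tolerance = 1e-3)
  expect_equal(at_ends[2], mx, tolerance = 1e-3)
  mid <- fcb$df[abs(fcb$rho0) < 0.05]
  expect_true(all(mid < min(at_ends)))
})

test_that("U_eq summaries follow the trace definition and compare variants per element", {
  st <- make_structure("water_P1bar")
  u <- u_eq(st)
  # isotropic atom: U_eq equals U_iso
  expect_equal(u$u_eq[u$label == "H1"], 0.035)
  # near-orthogonal cell: U_eq of the aniso atom is the plain trace / 3
  expect_equal(u$u_eq[u$label == "O1"], mean(c(0.015, 0.018, 0.020)),
               tolerance = 1e-10)
  st2 <- st
  st2$atoms$u_iso <- st$atoms$u_iso * 1.2
  for (cn in c("u11", "u22", "u33", "u12", "u13", "u23")) {
    st2$atoms[[cn]] <- st$atoms[[cn]] * 1.2
  }
  s <- adp_summary(list(ref = st, scaled = st2))
  expect_equal(s$element_ratios$mean_ratio,
               rep(1.2, nrow(s$element_ratios)), tolerance = 1e-10)
  st3 <- st2
  st3$atoms$label[1] <- "OX"
  expect_error(adp_summary(list(a = st, b = st3)), "OX|O1")
})

test_that("bond esds propagate from coordinate uncertainties with the closed-form check", {
  # two atoms 1.54 apart along x, equal isotropic coordinate esds, no correlation
  cl <- unit_cell(10, 10, 10)
  st <- crystal_structure(cl, list("x,y,z"),
    tibble::tibble(label = c("C1", "C2"), element = "C",
                   x = c(0.1, 0.254), y = 0.1, z = 0.1, occ = 1,
                   u_iso = 0.02, part = 0L, model = "iam"))
  sd_frac <- 0.001 / 10   # 0.001 Angstrom per Cartesian component
  pv <- tibble::tibble(
    atom = rep(c("C1", "C2"), each = 3),
    name = rep(c("x", "y", "z"), 2),
    value = 0, esd = sd_frac)
  cov <- diag(sd_frac^2, 6)
  fake_fit <- structure(list(structure = st, esd_covariance = cov, params = pv),
                        class = "taam_refinement")
  rep <- bond_report(fake_fit)
  expect_equal(nrow(rep$bonds), 1)
  expect_equal(rep$bonds$length, 1.54, tolerance = 1e-12)
  expect_equal(rep$bonds$esd, 0.001 * sqrt(2), tolerance = 1e-10)
  expect_equal(rep$mean_cc_esd, 0.001 * sqrt(2), tolerance = 1e-10)
})

test_that("bond classification separates water, amide and carbon classes", {
  st <- make_structure("amide_water_P21c")
  rep <- bond_report(st)
  cls <- stats::setNames(rep$bonds$class, paste(rep$bonds$a, rep$bonds$b))
  expect_equal(unname(cls["OW HW1"]), "O-H(water)")
  expect_equal(unname(cls["N1 HN1"]), "N-H")
  expect_equal(unname(cls["C2 H2"]), "C-H")
  expect_equal(unname(cls["C1 O1"]), "C-O")
  expect_equal(unname(cls["C1 C2"]), "C-C")
  expect_true(all(is.na(rep$bonds$esd)))  # no refinement -> no esds
  expect_equal(rep$bonds$delta[rep$bonds$class == "N-H"],
               rep$bonds$length[rep$bonds$class == "N-H"] - 1.01,
               tolerance = 1e-12)
})
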