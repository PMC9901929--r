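# small, fast refinement scenarios on the water fixture
water_case <- function(noise = 0.01, seed = 42, d_min = 0.9) {
  st <- make_structure("water_P1bar")
  refl <- simulate_reflections(
    st, simulation_recipe(d_min = d_min, noise_fraction = noise,
                          floor = if (noise > 0) 0.1 else 0, seed = seed),
    model = "taam")
  list(st = st, refl = refl)
}

prepared_model <- function(st, refl) {
  g <- build_bond_graph(st)
  asg <- electroneutrality_rescale(assign_types(st, g, default_bank()), st)
  frames <- bind_axes(asg, g, st)
  make_form_factor_table(st, as.matrix(refl[, c("h", "k", "l")]), asg, frames)
}

test_that("a cycle at the generating truth of noise-free data produces no shift", {
  cs <- water_case(noise = 0, seed = 1)
  tb <- prepared_model(cs$st, cs$refl)
  pv <- make_param_vector(cs$st, refine_config())
  res <- lsq_cycle(cs$st, cs$refl, tb, pv, refine_config())
  expect_lt(res$shift_norm, 1e-8)
})

test_that("scale-only refinement reproduces its closed form in one cycle", {
  cs <- water_case(noise = 0.02, seed = 5)
  tb <- prepared_model(cs$st, cs$refl)
  cfg <- refine_config(refine_xyz = FALSE, refine_adp = FALSE, refine_occ = FALSE,
                       weight_a = 0)
  pv <- make_param_vector(cs$st, cfg, scale = 0.8)
  res <- lsq_cycle(cs$st, cs$refl, tb, pv, cfg)
  fc2 <- structure_factors(cs$st, tb, as.matrix(cs$refl[, c("h", "k", "l")]))$f_calc_mod^2
  w <- 1 / (cs$refl$sig^2 + 0)  # weights at the starting state (a = b = 0)
  k_closed <- sum(w * cs$refl$f2 * fc2) / sum(w * fc2^2)
  # one Gauss-Newton step on a linear-in-k model lands exactly on the optimum
  expect_equal(res$pv$value[res$pv$name == "scale"], k_closed, tolerance = 1e-12)
})

test_that("finite-difference Jacobian columns match an independent five-point stencil", {
  cs <- water_case(noise = 0.01, seed = 9)
  tb <- prepared_model(cs$st, cs$refl)
  cfg <- refine_config()
  pv <- make_param_vector(cs$st, cfg)
  res <- lsq_cycle(cs$st, cs$refl, tb, pv, cfg, return_jacobian = TRUE)
  H <- as.matrix(cs$refl[, c("h", "k", "l")])
  # pick the x coordinate of O1
  p_idx <- which(pv$atom == "O1" & pv$name == "x")
  expect_length(p_idx, 1)
  model_at <- function(xval) {
    st2 <- cs$st
    st2$atoms$x[st2$atoms$label == "O1"] <- xval
    structure_factors(st2, tb, H)$f_calc_mod^2   # scale = 1 at start
  }
  x0 <- cs$st$atoms$x[cs$st$atoms$label == "O1"]
  h5 <- 2e-5
  stencil <- (-model_at(x0 + 2 * h5) + 8 * model_at(x0 + h5)
              - 8 * model_at(x0 - h5) + model_at(x0 - 2 * h5)) / (12 * h5)
  Jcol <- res$jacobian[, p_idx]
  expect_lt(max(abs(Jcol - stencil)) / max(abs(stencil)), 1e-6)
})

test_that("under-determined problems and singular normal matrices raise informative errors", {
  cs <- water_case(noise = 0.01, seed = 3, d_min = 2.6)
  tb <- prepared_model(cs$st, cs$refl)
  pv <- make_param_vector(cs$st, refine_config())
  expect_error(lsq_cycle(cs$st, cs$refl, tb, pv, refine_config()),
               "under-determined")
})

test_that("refinement recovers the generating truth from a perturbed start", {
  cs <- water_case(noise = 0.01, seed = 42)
  start <- perturb(cs$st, xyz = 0.05, u_rel = 0.2, occ = 0, seed = 7)
  fit <- refine(start, cs$refl, bank = default_bank())
  expect_true(fit$converged)
  expect_lte(fit$n_outer, 10)
  rec <- position_recovery(cs$st, fit$structure)
  esd_xyz <- fit$params$esd[fit$params$name %in% c("x", "y", "z")]
  expect_lt(max(rec$dist), 1e-3 + 2 * max(esd_xyz, na.rm = TRUE) *
              max(cs$st$cell$a, cs$st$cell$b, cs$st$cell$c))
  # damping enforces monotone descent at fixed weights: every accepted step
  # ends at or below the objective it started from
  log <- fit$cycle_log[fit$cycle_log$accepted, ]
  expect_true(all(log$objective <= log$objective_before * (1 + 1e-12)))
})

test_that("noise-free self-refinement sits at the optimum with vanishing R1 and GooF", {
  cs <- water_case(noise = 0, seed = 2)
  fit <- refine(cs$st, cs$refl, bank = default_bank())
  expect_lt(fit$stats$r1_all, 0.1)     # percent
  expect_lt(fit$goof, 1e-3)
  expect_true(fit$converged)
})

test_that("esds shrink by about 1/sqrt(2) when every reflection is duplicated", {
  cs <- water_case(noise = 0.02, seed = 11)
  start <- perturb(cs$st, xyz = 0.01, u_rel = 0.05, occ = 0, seed = 3)
  fit1 <- refine(start, cs$refl, bank = default_bank())
  # duplicating every observation doubles the information content
  refl2 <- cs$refl[rep(seq_len(nrow(cs$refl)), 2), ]
  fit2 <- refine(start, refl2, bank = default_bank())
  r <- fit2$params$esd / fit1$params$esd
  r <- r[is.finite(r) & fit1$params$esd > 0]
  expect_equal(median(r), 1 / sqrt(2), tolerance = 0.05)
})

test_that("refinement results do not depend on atom ordering", {
  cs <- water_case(noise = 0.01, seed = 13)
  start <- perturb(cs$st, xyz = 0.02, u_rel = 0.1, occ = 0, seed = 5)
  fit1 <- refine(start, cs$refl, bank = default_bank())
  start2 <- start
  start2$atoms <- start2$atoms[c(2, 3, 1), ]
  fit2 <- refine(start2, cs$refl, bank = default_bank())
  expect_equal(fit2$stats$r1_all, fit1$stats$r1_all, tolerance = 1e-6)
  for (lb in start$atoms$label) {
    x1 <- as.numeric(fit1$structure$atoms[fit1$structure$atoms$label == lb, c("x", "y", "z")])
    x2 <- as.numeric(fit2$structure$atoms[fit2$structure$atoms$label == lb, c("x", "y", "z")])
    expect_equal(x2, x1, tolerance = 1e-6)
  }
})

test_that("fractional statistics are invariant under uniform data rescaling", {
  cs <- water_case(noise = 0.01, seed = 17)
  start <- perturb(cs$st, xyz = 0.02, u_rel = 0.1, occ = 0, seed = 5)
  fit1 <- refine(start, cs$refl, bank = default_bank())
  refl_s <- cs$refl
  refl_s$f2 <- refl_s$f2 * 10
  refl_s$sig <- refl_s$sig * 10
  fit2 <- refine(start, refl_s, bank = default_bank())
  expect_equal(fit2$stats$r1_all, fit1$stats$r1_all, tolerance = 1e-4)
  expect_equal(fit2$stats$wr2_all, fit1$stats$wr2_all, tolerance = 1e-2)
  expect_equal(fit2$scale / fit1$scale, 10, tolerance = 1e-3)
})

test_that("strongly negative intensities are rejected with a warning", {
  cs <- water_case(noise = 0.01, seed = 19)
  refl <- cs$refl
  refl$f2[1] <- -10 * refl$sig[1]
  expect_warning(fit <- refine(cs$st, refl, bank = default_bank()),
                 "rejecting")
  expect_equal(fit$stats$n_all, sum(refl$f2 >= -3 * refl$sig))
})

test_that("disorder occupancies are recovered with honest esds", {
  st <- make_structure("two_conformer_chain", occ = 0.65)
  refl <- simulate_reflections(st, simulation_recipe(d_min = 0.85, seed = 21),
                               model = "taam")
  start <- perturb(st, xyz = 0.02, u_rel = 0.1, occ = 0.1, seed = 8)
  fit <- refine(start, refl, bank = default_bank())
  occ_row <- fit$params[fit$params$name == "occ", ]
  expect_equal(nrow(occ_row), 1)
  expect_lt(abs(occ_row$value - 0.65), 2 * occ_row$esd + 1e-3)
  p1_occ <- fit$structure$atoms$occ[fit$structure$atoms$part == 1]
  p2_occ <- fit$structure$atoms$occ[fit$structure$atoms$part == 2]
  expect_equal(unique(p1_occ) + unique(p2_occ), 1)
})

test_that("a symmetric half-occupied disorder refines back to one half", {
  st <- make_structure("two_conformer_chain", occ = 0.5)
  refl <- simulate_reflections(st, simulation_recipe(d_min = 0.9, seed = 23),
                               model = "taam")
  start <- perturb(st, xyz = 0, u_rel = 0, occ = 0.08, seed = 2)
  fit <- refine(start, refl, bank = default_bank())
  occ_row <- fit$params[fit$params$name == "occ", ]
  expect_lt(abs(occ_row$value - 0.5), 3 * occ_row$esd + 1e-3)
})
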