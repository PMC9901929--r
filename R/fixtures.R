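#' Built-in fixture pseudoatom bank
#'
#' A small, self-contained transferable bank covering the fixture
#' chemistry: water and organic hydrogens, sp3/aromatic/amide/carboxylate
#' carbons, amide nitrogen, water/carbonyl/carboxylate oxygens and sodium.
#' Radial functions are single-zeta Slater densities with Slater-rule
#' exponents; multipole populations are chemically plausible and
#' bond-concentrating (dipoles toward the bonded neighbour, positive
#' quadrupole/octupole terms along the primary bond axis, magnitudes in
#' the range typical of experimental multipole refinements) but make no
#' claim of reproducing any published databank — internal consistency and
#' realistic residual-map magnitudes, not chemical accuracy, are what the
#' package tests against this bank.
#'
#' @return A `taam_bank`.
#' @export
default_bank <- function() {
  # density-scale exponents (1/Angstrom): 2 * zeta_orbital / a0
  zH <- 3.7795; zC1s <- 21.54; zC2 <- 6.14; zN1s <- 25.32; zN2 <- 7.37
  zO1s <- 29.10; zO2 <- 8.60
  zNa1s <- 40.4; zNa2 <- 12.94; zNa3 <- 2.77

  core_of <- function(terms, ncore) slater_normalize(terms, ncore)
  val_of <- function(terms) slater_normalize(terms, 1)

  mk <- function(type_id, element, signature, ring, axes,
                 core, valence, n_core, p_v, kappa, kprime,
                 def_zeta, def_orders, plm_list) {
    defr <- vector("list", 5)
    for (l in def_orders) defr[[l + 1]] <- slater_term(1, max(2L, l), def_zeta)
    plm <- empty_plm()
    for (e in plm_list) plm[[e[1] + 1]][e[2] + e[1] + 1] <- e[3]
    params <- pseudoatom_parameters(element, core, valence, n_core = n_core,
                                    p_c = n_core, p_v = p_v, kappa = kappa,
                                    kappa_prime = rep(kprime, 5),
                                    deformation = defr, p_lm = plm)
    list(type_id = type_id, element = element, signature = signature,
         ring = ring, axes = axes, params = params)
  }
  axZ1X2 <- list(Z = "N1", X = "N2")
  axZ1Xnn <- list(Z = "N1", X = "NN1")
  axZmX1 <- list(Z = "NMEAN", X = "N1")

  h_core <- list(); h_val <- val_of(list(slater_term(1, 0, zH)))
  c_core <- core_of(list(slater_term(1, 0, zC1s)), 2)
  c_val <- val_of(list(slater_term(1, 2, zC2)))
  n_core_t <- core_of(list(slater_term(1, 0, zN1s)), 2)
  n_val <- val_of(list(slater_term(1, 2, zN2)))
  o_core <- core_of(list(slater_term(1, 0, zO1s)), 2)
  o_val <- val_of(list(slater_term(1, 2, zO2)))
  na_core <- core_of(list(slater_term(2, 0, zNa1s), slater_term(1, 2, zNa2)), 10)
  na_val <- val_of(list(slater_term(1, 4, zNa3)))

  # H deformation radial: dipole-dominant, contracted
  hdef <- 4.2

  types <- list(
    mk("H_w", "H", c("O:0"), "false", axZ1Xnn, h_core, h_val, 0, 0.85, 1.15, 1.2,
       hdef, 1:2, list(c(1, 0, 0.18), c(2, 0, 0.06))),
    mk("H_c", "H", c("C:*"), "any", axZ1Xnn, h_core, h_val, 0, 0.90, 1.12, 1.2,
       hdef, 1:2, list(c(1, 0, 0.16), c(2, 0, 0.05))),
    mk("H_n", "H", c("N:*"), "false", axZ1Xnn, h_core, h_val, 0, 0.83, 1.16, 1.2,
       hdef, 1:2, list(c(1, 0, 0.18), c(2, 0, 0.06))),
    mk("H_o", "H", c("O:*"), "false", axZ1Xnn, h_core, h_val, 0, 0.86, 1.14, 1.2,
       hdef, 1:2, list(c(1, 0, 0.18), c(2, 0, 0.06))),
    mk("C_sp3", "C", c("C:*", "C:*", "H:1", "H:1"), "false", axZ1X2,
       c_core, c_val, 2, 4.05, 1.01, 0.95, zC2, 1:3,
       list(c(1, 0, 0.10), c(2, 0, 0.15), c(3, 0, 0.25))),
    mk("C_ar", "C", c("C:*", "C:*", "H:1"), "true", axZ1X2,
       c_core, c_val, 2, 4.00, 1.01, 0.95, zC2, 1:3,
       list(c(1, 0, 0.10), c(2, 0, 0.15), c(3, 0, 0.25))),
    mk("C_amide", "C", c("C:*", "N:*", "O:1"), "false", axZ1X2,
       c_core, c_val, 2, 3.90, 1.02, 0.95, zC2, 1:3,
       list(c(1, 0, 0.12), c(2, 0, 0.15), c(3, 0, 0.25))),
    mk("C_carboxyl", "C", c("H:1", "O:1", "O:1"), "false", axZ1X2,
       c_core, c_val, 2, 3.85, 1.02, 0.95, zC2, 1:3,
       list(c(1, 0, 0.10), c(2, 0, 0.15), c(3, 0, 0.22))),
    mk("C_vinyl", "C", c("C:*", "H:1", "H:1"), "false", axZ1X2,
       c_core, c_val, 2, 4.05, 1.01, 0.95, zC2, 1:3,
       list(c(1, 0, 0.10), c(2, 0, 0.15), c(3, 0, 0.22))),
    mk("C_vinyl2", "C", c("C:*", "C:*", "H:1"), "false", axZ1X2,
       c_core, c_val, 2, 4.05, 1.01, 0.95, zC2, 1:3,
       list(c(1, 0, 0.10), c(2, 0, 0.15), c(3, 0, 0.22))),
    mk("C_any", "C", "any", "any", axZ1X2,
       c_core, c_val, 2, 4.0, 1.0, 1.0, zC2, 1:2,
       list(c(1, 0, 0.10), c(2, 0, 0.12))),
    mk("N_amide", "N", c("C:*", "H:1", "H:1"), "false", axZ1X2,
       n_core_t, n_val, 2, 5.10, 1.00, 0.95, zN2, 1:3,
       list(c(1, 0, 0.18), c(2, 0, 0.12), c(3, 0, 0.18))),
    mk("O_w", "O", c("H:1", "H:1"), "false", axZmX1,
       o_core, o_val, 2, 6.15, 0.98, 1.05, zO2, 1:4,
       list(c(1, 0, 0.15), c(2, 0, 0.12), c(4, 0, 0.03))),
    mk("O_carbonyl", "O", c("C:*"), "false", axZ1Xnn,
       o_core, o_val, 2, 6.20, 0.98, 1.05, zO2, 1:4,
       list(c(1, 0, 0.15), c(2, 0, 0.12))),
    mk("O_h", "O", c("C:*", "H:*"), "false", axZ1X2,
       o_core, o_val, 2, 6.18, 0.98, 1.05, zO2, 1:4,
       list(c(1, 0, 0.14), c(2, 0, 0.12))),
    mk("O_carboxyl", "O", c("C:2"), "false", axZ1Xnn,
       o_core, o_val, 2, 6.30, 0.98, 1.05, zO2, 1:4,
       list(c(1, 0, 0.14), c(2, 0, 0.12))),
    mk("Na", "Na", "any", "any", NULL,
       na_core, na_val, 10, 0.0, 1.0, 1.0, zNa3, integer(0), list())
  )
  names(types) <- vapply(types, function(e) e$type_id, "")
  structure(list(version = "1.0", types = types), class = "taam_bank")
}

#' Fixture structure templates
#'
#' Chemically sensible toy crystal structures used throughout the test
#' suite and documentation:
#' \describe{
#'   \item{`water_P1bar`}{One water molecule on a general position of a
#'     two-operator inversion cell; the smallest refinable fixture.}
#'   \item{`amide_water_P21c`}{Acrylamide plus one water under a
#'     two-fold screw operator (`-x,y+1/2,-z+1/2`); the workhorse fixture
#'     (3 C, 1 N, 2 O, 7 H in the asymmetric unit).}
#'   \item{`two_conformer_chain`}{A propanol-like chain whose terminal
#'     carbon is disordered over two rotamer sites in parts 1/2 with a
#'     shared occupancy constraint (default 0.65/0.35).}
#'   \item{`metal_salt_Pm`}{Na+ with a formate anion and one water under
#'     a mirror operator (`x,-y,z`); the hybrid-refinement fixture.}
#' }
#'
#' @param template Template id.
#' @param occ Major-conformer occupancy for `two_conformer_chain`.
#' @return A [crystal_structure()].
#' @export
make_structure <- function(template = c("water_P1bar", "amide_water_P21c",
                                        "two_conformer_chain", "metal_salt_Pm"),
                           occ = 0.65) {
  template <- match.arg(template)
  switch(template,
    water_P1bar = template_water(),
    amide_water_P21c = template_amide_water(),
    two_conformer_chain = template_two_conformer(occ),
    metal_salt_Pm = template_metal_salt()
  )
}

# place Cartesian coordinates (rows) into the cell at a Cartesian offset
place_atoms <- function(cell, labels, elements, cart, offset,
                        u_iso = 0.03, aniso = NULL, occ = 1, part = 0L,
                        model = "taam") {
  frac <- t(cell$cart2frac %*% (t(cart) + offset))
  at <- tibble::tibble(label = labels, element = elements,
                       x = frac[, 1], y = frac[, 2], z = frac[, 3],
                       occ = occ, u_iso = u_iso, part = as.integer(part),
                       model = model)
  for (cn in c("u11", "u22", "u33", "u12", "u13", "u23")) at[[cn]] <- NA_real_
  if (!is.null(aniso)) {
    for (lb in names(aniso)) {
      i <- match(lb, at$label)
      at[i, c("u11", "u22", "u33", "u12", "u13", "u23")] <- as.list(aniso[[lb]])
    }
    at$u_iso[at$label %in% names(aniso)] <- NA_real_
  }
  at
}

template_water <- function() {
  cell <- unit_cell(5.5, 6.0, 6.5)
  cart <- rbind(
    O1 = c(0, 0, 0),
    H1 = c(0.76, 0, -0.59),
    H2 = c(-0.23, 0.89, 0.28))
  at <- place_atoms(cell, rownames(cart), c("O", "H", "H"), cart,
                    offset = c(1.4, 1.8, 1.8),
                    u_iso = c(NA, 0.035, 0.035),
                    aniso = list(O1 = c(0.015, 0.018, 0.020, 0.002, 0.001, 0.000)))
  crystal_structure(cell, list("x,y,z", "-x,-y,-z"), at)
}

template_amide_water <- function() {
  cell <- unit_cell(7.5, 10.0, 8.5, beta = 90)
  cart <- rbind(
    C1 = c(0, 0, 0),        # carbonyl C
    O1 = c(1.23, 0, 0),
    N1 = c(-0.67, 1.16, 0),
    C2 = c(-0.745, -1.29, 0),
    C3 = c(-2.075, -1.29, 0),
    H2 = c(-0.205, -2.225, 0),
    H31 = c(-2.615, -0.355, 0),
    H32 = c(-2.615, -2.225, 0),
    HN1 = c(-0.165, 2.035, 0),
    HN2 = c(-1.68, 1.16, 0),
    OW = c(-2.9, -3.1, 4.65),
    HW1 = c(-2.14, -3.1, 4.06),
    HW2 = c(-3.13, -2.21, 4.93))
  el <- c("C", "O", "N", "C", "C", "H", "H", "H", "H", "H", "O", "H", "H")
  aniso <- list(
    C1 = c(0.016, 0.018, 0.020, 0.001, 0.000, 0.001),
    O1 = c(0.020, 0.024, 0.028, 0.003, 0.001, 0.000),
    N1 = c(0.018, 0.020, 0.024, 0.002, 0.000, 0.001),
    C2 = c(0.018, 0.021, 0.023, 0.001, 0.001, 0.000),
    C3 = c(0.024, 0.027, 0.030, 0.002, 0.001, 0.001),
    OW = c(0.022, 0.025, 0.028, 0.002, 0.001, 0.002))
  at <- place_atoms(cell, rownames(cart), el, cart, offset = c(3.4, 3.6, 0.85),
                    u_iso = 0.04, aniso = aniso)
  crystal_structure(cell, list("x,y,z", "-x,y+1/2,-z+1/2"), at)
}

template_two_conformer <- function(occ = 0.65) {
  cell <- unit_cell(7.0, 7.5, 8.0)
  o1 <- c(0, 0, 0)
  c1 <- c(1.42, 0, 0)
  c2 <- c1 + 1.52 * c(cos(70.5 * pi / 180), sin(70.5 * pi / 180), 0)
  # terminal carbon: tetrahedral from c2, two rotamers about the c1-c2 axis
  rot_pos <- function(dihedral_deg) {
    axis <- (c2 - c1) / sqrt(sum((c2 - c1)^2))
    # reference direction perpendicular to axis, in the molecular plane
    ref <- c(0, 0, 1)
    perp1 <- ref - sum(ref * axis) * axis
    perp1 <- perp1 / sqrt(sum(perp1^2))
    perp2 <- c(axis[2] * perp1[3] - axis[3] * perp1[2],
               axis[3] * perp1[1] - axis[1] * perp1[3],
               axis[1] * perp1[2] - axis[2] * perp1[1])
    th <- 109.5 * pi / 180
    phi <- dihedral_deg * pi / 180
    dirv <- cos(pi - th) * axis + sin(pi - th) * (cos(phi) * perp1 + sin(phi) * perp2)
    c2 + 1.52 * dirv
  }
  c3a <- rot_pos(90)
  c3b <- rot_pos(210)
  h_o <- o1 + 0.96 * c(cos(108 * pi / 180), sin(108 * pi / 180), 0)
  # two H on c1, tetrahedral out of plane
  bis <- -( (o1 - c1) / 1.42 + (c2 - c1) / 1.52 )
  bis <- bis / sqrt(sum(bis^2))
  oop <- c(0, 0, 1)
  h11 <- c1 + 1.08 * (cos(54.7 * pi / 180) * bis + sin(54.7 * pi / 180) * oop)
  h12 <- c1 + 1.08 * (cos(54.7 * pi / 180) * bis - sin(54.7 * pi / 180) * oop)
  cart <- rbind(O1 = o1, C1 = c1, C2 = c2, C3A = c3a, C3B = c3b,
                HO = h_o, H11 = h11, H12 = h12)
  el <- c("O", "C", "C", "C", "C", "H", "H", "H")
  aniso <- list(
    O1 = c(0.018, 0.020, 0.024, 0.002, 0.001, 0.000),
    C1 = c(0.016, 0.019, 0.021, 0.001, 0.000, 0.001),
    C2 = c(0.017, 0.020, 0.022, 0.001, 0.001, 0.000))
  at <- place_atoms(cell, rownames(cart), el, cart, offset = c(1.6, 1.7, 2.6),
                    u_iso = 0.04, aniso = aniso)
  at$part[at$label == "C3A"] <- 1L
  at$part[at$label == "C3B"] <- 2L
  at$occ[at$label == "C3A"] <- occ
  at$occ[at$label == "C3B"] <- 1 - occ
  at$u_iso[at$label %in% c("C3A", "C3B")] <- 0.045
  crystal_structure(cell, list("x,y,z", "-x,-y,-z"), at)
}

template_metal_salt <- function() {
  cell <- unit_cell(7.0, 8.0, 7.5)
  ang <- 120 * pi / 180
  # formate plane kept flat in y so mirror images stay distant
  cart <- rbind(
    C1 = c(0, 0, 0),
    O1 = 1.25 * c(cos(ang / 2), 0, sin(ang / 2)),
    O2 = 1.25 * c(cos(ang / 2), 0, -sin(ang / 2)),
    H1 = c(-1.09, 0, 0),
    NA1 = c(3.28, -0.51, 0.44),
    OW = c(3.90, -0.65, 3.98),
    HW1 = c(4.66, -0.65, 3.39),
    HW2 = c(3.64, -0.04, 4.67))
  el <- c("C", "O", "O", "H", "Na", "O", "H", "H")
  aniso <- list(
    C1 = c(0.015, 0.017, 0.019, 0.001, 0.000, 0.001),
    O1 = c(0.019, 0.022, 0.025, 0.002, 0.001, 0.000),
    O2 = c(0.019, 0.023, 0.024, 0.001, 0.001, 0.001),
    NA1 = c(0.014, 0.015, 0.016, 0.001, 0.000, 0.000),
    OW = c(0.021, 0.024, 0.027, 0.002, 0.001, 0.001))
  at <- place_atoms(cell, rownames(cart), el, cart, offset = c(1.8, 2.0, 1.6),
                    u_iso = 0.04, aniso = aniso)
  crystal_structure(cell, list("x,y,z", "x,-y,z"), at)
}

#' Simulation recipe for synthetic reflection data
#'
#' @param d_min Resolution limit in Angstrom (>= 0.4).
#' @param noise_fraction Relative noise level:
#'   \eqn{\sigma = noise\_fraction \cdot |F_c|^2 + floor}.
#' @param floor Absolute noise floor on \eqn{F^2}.
#' @param k_true Generating intensity scale.
#' @param seed Mandatory random seed.
#' @return A `simulation_recipe` list.
#' @export
simulation_recipe <- function(d_min = 0.8, noise_fraction = 0.01,
                              floor = 0.1, k_true = 1, seed) {
  if (missing(seed)) stop("simulation_recipe: seed is mandatory")
  if (d_min < 0.4) stop("simulation_recipe: d_min must be >= 0.4 Angstrom")
  structure(list(d_min = d_min, noise_fraction = noise_fraction,
                 floor = floor, k_true = k_true, seed = as.integer(seed)),
            class = "simulation_recipe")
}

#' Simulate reflection intensities from a structure
#'
#' Enumerates the full reflection sphere to `recipe$d_min`, computes model
#' structure factors under the requested scattering model and produces
#' \eqn{F_o^2 = k_{true} |F_c|^2 + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma^2)},
#' \eqn{\sigma = noise\_fraction\,|F_c|^2 + floor}; the sigma column
#' reports the generating sigma. Deterministic given the seed.
#'
#' @param structure A [crystal_structure()].
#' @param recipe A [simulation_recipe()].
#' @param model `"taam"`, `"iam"` or `"hybrid"` (hybrid keeps each atom's
#'   own `model` tag).
#' @param bank Bank for TAAM atoms (default [default_bank()]).
#' @param charge_groups Optional electroneutrality groups.
#' @return A `reflection_set`; the generating scale and model are attached
#'   as attributes `k_true` and `sim_model`.
#' @export
simulate_reflections <- function(structure, recipe, model = c("taam", "iam", "hybrid"),
                                 bank = default_bank(), charge_groups = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(recipe, "simulation_recipe"))
  st <- structure
  if (model != "hybrid") st$atoms$model <- model
  H <- hkl_sphere(st$cell, recipe$d_min)
  assignment <- NULL; frames <- NULL
  if (any(st$atoms$model == "taam")) {
    graph <- build_bond_graph(st)
    assignment <- assign_types(st, graph, bank)
    assignment <- suppressWarnings(
      electroneutrality_rescale(assignment, st, groups = charge_groups))
    frames <- bind_axes(assignment, graph, st)
  }
  table <- make_form_factor_table(st, H, assignment = assignment, frames = frames)
  fc <- structure_factors(st, table, H)
  sig <- recipe$noise_fraction * fc$f_calc_mod^2 + recipe$floor
  set.seed(recipe$seed)
  f2 <- recipe$k_true * fc$f_calc_mod^2 + stats::rnorm(nrow(H), 0, sig)
  # a noiseless recipe still needs a positive sigma column
  sig <- pmax(sig, 1e-6)
  refl <- reflection_set(tibble::tibble(h = fc$h, k = fc$k, l = fc$l,
                                        f2 = f2, sig = sig))
  attr(refl, "k_true") <- recipe$k_true
  attr(refl, "sim_model") <- model
  refl
}

#' Randomly perturb a structure (recovery-test starting models)
#'
#' Adds Gaussian noise of the stated magnitudes: each Cartesian coordinate
#' component gets sd `xyz` (Angstrom), displacement parameters are scaled
#' by `1 + N(0, u_rel)`, and each disorder-group fraction is shifted by
#' `N(0, occ)` (clamped to (0.05, 0.95), partner kept at `1 - p`).
#' Reproducible given the seed; the input is returned unchanged alongside
#' as attribute `truth`.
#'
#' @param structure A [crystal_structure()].
#' @param xyz Positional noise per Cartesian component (Angstrom).
#' @param u_rel Relative ADP noise.
#' @param occ Absolute occupancy noise.
#' @param seed Random seed.
#' @return Perturbed [crystal_structure()] with attribute `truth`.
#' @export
perturb <- function(structure, xyz = 0.05, u_rel = 0.2, occ = 0.1, seed) {
  if (missing(seed)) stop("perturb: seed is mandatory")
  set.seed(seed)
  at <- structure$atoms
  n <- nrow(at)
  if (xyz > 0) {
    dcart <- matrix(stats::rnorm(3 * n, 0, xyz), n, 3)
    dfrac <- t(structure$cell$cart2frac %*% t(dcart))
    at$x <- (at$x + dfrac[, 1]) %% 1
    at$y <- (at$y + dfrac[, 2]) %% 1
    at$z <- (at$z + dfrac[, 3]) %% 1
  }
  if (u_rel > 0) {
    for (i in seq_len(n)) {
      f <- max(1 + stats::rnorm(1, 0, u_rel), 0.2)
      if (atom_is_aniso(at[i, ])) {
        for (cn in c("u11", "u22", "u33", "u12", "u13", "u23")) {
          at[[cn]][i] <- at[[cn]][i] * f
        }
      } else {
        at$u_iso[i] <- at$u_iso[i] * f
      }
    }
  }
  if (occ > 0 && any(at$part > 0)) {
    parts <- sort(unique(at$part[at$part > 0]))
    for (gi in seq(1, length(parts), by = 2)) {
      if (gi + 1 > length(parts)) break
      p <- unique(at$occ[at$part == parts[gi]])[1]
      p_new <- min(max(p + stats::rnorm(1, 0, occ), 0.05), 0.95)
      at$occ[at$part == parts[gi]] <- p_new
      at$occ[at$part == parts[gi + 1]] <- 1 - p_new
    }
  }
  out <- structure
  out$atoms <- at
  attr(out, "truth") <- structure
  out
}

#' Score positional recovery against the generating truth
#'
#' Per-atom Cartesian distances between a refined structure and the truth
#' after removing the mean displacement along floating (polar) lattice
#' directions, which are physically indeterminate.
#'
#' @param truth,refined [crystal_structure()] objects with matching labels.
#' @return Tibble `label`, `element`, `dist` (Angstrom).
#' @export
position_recovery <- function(truth, refined) {
  stopifnot(identical(truth$atoms$label, refined$atoms$label))
  d <- as.matrix(refined$atoms[, c("x", "y", "z")]) -
    as.matrix(truth$atoms[, c("x", "y", "z")])
  d <- d - round(d)
  fl <- floating_directions(truth)
  for (dim in fl) d[, dim] <- d[, dim] - mean(d[, dim])
  dc <- t(truth$cell$frac2cart %*% t(d))
  tibble::tibble(label = truth$atoms$label, element = truth$atoms$element,
                 dist = sqrt(rowSums(dc^2)))
}
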