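#' Refinement configuration
#'
#' @param weight_a,weight_b Weighting-scheme constants in
#'   \eqn{w = 1/[\sigma^2(F_o^2) + (aP)^2 + bP]},
#'   \eqn{P = (\max(F_o^2,0) + 2F_c^2)/3} (with \eqn{F_c^2} on the scale
#'   of the observations).
#' @param max_outer Maximum outer cycles (graph/type/frame/form-factor
#'   regeneration followed by inner least squares).
#' @param max_inner Maximum Gauss-Newton steps per outer cycle.
#' @param outer_tol Outer-loop convergence: largest fractional coordinate
#'   change below this ends the iteration.
#' @param damping Initial step damping factor.
#' @param max_shift_angstrom Per-cycle cap on the largest atomic Cartesian
#'   displacement.
#' @param fd_step_frac,fd_step_u Central finite-difference steps for
#'   coordinates (fractional) and displacement parameters (Angstrom^2).
#' @param refine_xyz,refine_adp,refine_occ,refine_scale Toggle parameter
#'   classes.
#' @param hydrogen_mode IAM hydrogen treatment (`"bonded"` or `"free"`).
#' @param anchor Label of the atom whose coordinates along floating
#'   (polar) directions are held fixed; `NULL` picks the heaviest atom.
#' @return A `refine_config` list.
#' @export
refine_config <- function(weight_a = 0.01, weight_b = 0,
                          max_outer = 10L, max_inner = 20L,
                          outer_tol = 1e-4, damping = 1,
                          max_shift_angstrom = 0.2,
                          fd_step_frac = 1e-5, fd_step_u = 1e-5,
                          refine_xyz = TRUE, refine_adp = TRUE,
                          refine_occ = TRUE, refine_scale = TRUE,
                          hydrogen_mode = "bonded", anchor = NULL) {
  structure(as.list(environment()), class = "refine_config")
}

# --- parameter vector --------------------------------------------------------

# Floating (polar) lattice directions: translations t with R_s t = t for all
# symops. Only axis-aligned floats are handled (sufficient for explicit
# operator lists of the supported settings).
floating_directions <- function(structure) {
  P <- Reduce(`+`, lapply(structure$symops, function(op) op$R)) / length(structure$symops)
  keep <- abs(diag(P) - 1) < 1e-9
  offd <- abs(P - diag(diag(P)))
  if (any(keep) && max(offd) > 1e-9) {
    warning("floating_directions: non-axis-aligned floating subspace; origin fixing may be incomplete")
  }
  which(keep)
}

# disorder occupancy groups: consecutive pairs of part ids (1,2), (3,4), ...
occupancy_groups <- function(structure) {
  parts <- sort(unique(structure$atoms$part[structure$atoms$part > 0]))
  if (!length(parts)) return(list())
  if (length(parts) %% 2 != 0) {
    stop("occupancy_groups: disorder parts must come in pairs (found ids ",
         paste(parts, collapse = ", "), ")")
  }
  lapply(seq(1, length(parts), by = 2), function(i) {
    list(part_p = parts[i], part_q = parts[i + 1])
  })
}

#' Build the refinement parameter vector
#'
#' One row per refinable quantity: the global scale, per-atom coordinates
#' and displacement parameters, and one fraction per disorder-part pair
#' (occupancies `p` and `1-p`). Coordinates of the anchor atom along
#' floating (polar) directions are excluded to fix the origin.
#'
#' @param structure A [crystal_structure()].
#' @param config A [refine_config()].
#' @param scale Current scale value.
#' @return Tibble with `atom`, `name`, `value`; attribute `occ_groups`.
#' @export
make_param_vector <- function(structure, config = refine_config(), scale = 1) {
  at <- structure$atoms
  rows <- list()
  if (config$refine_scale) {
    rows[[length(rows) + 1L]] <- tibble::tibble(atom = "GLOBAL", name = "scale", value = scale)
  }
  float_dims <- floating_directions(structure)
  anchor <- config$anchor
  if (is.null(anchor) && length(float_dims)) {
    Z <- element_numbers()
    heavy <- at$label[order(-Z[at$element], at$label)]
    anchor <- heavy[1]
  }
  if (config$refine_xyz) {
    for (i in seq_len(nrow(at))) {
      for (d in 1:3) {
        if (identical(at$label[i], anchor) && d %in% float_dims) next
        rows[[length(rows) + 1L]] <- tibble::tibble(
          atom = at$label[i], name = c("x", "y", "z")[d],
          value = as.numeric(at[i, c("x", "y", "z")[d]]))
      }
    }
  }
  if (config$refine_adp) {
    for (i in seq_len(nrow(at))) {
      if (atom_is_aniso(at[i, ])) {
        for (nm in c("u11", "u22", "u33", "u12", "u13", "u23")) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            atom = at$label[i], name = nm, value = as.numeric(at[i, nm]))
        }
      } else {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          atom = at$label[i], name = "u_iso", value = at$u_iso[i])
      }
    }
  }
  groups <- occupancy_groups(structure)
  if (config$refine_occ && length(groups)) {
    for (g in seq_along(groups)) {
      p_atoms <- at$label[at$part == groups[[g]]$part_p]
      p_val <- unique(round(at$occ[at$part == groups[[g]]$part_p], 12))
      if (length(p_val) != 1) stop("make_param_vector: atoms of part ",
                                   groups[[g]]$part_p, " carry unequal occupancies")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        atom = paste0("part", groups[[g]]$part_p, "|part", groups[[g]]$part_q),
        name = "occ", value = p_val)
    }
  }
  pv <- dplyr::bind_rows(rows)
  attr(pv, "occ_groups") <- groups
  attr(pv, "anchor") <- anchor
  pv
}

# write parameter values back into (structure, scale)
apply_param_vector <- function(structure, pv) {
  at <- structure$atoms
  scale <- 1
  for (r in seq_len(nrow(pv))) {
    nm <- pv$name[r]; lab <- pv$atom[r]; v <- pv$value[r]
    if (nm == "scale") { scale <- v; next }
    if (nm == "occ") {
      parts <- as.integer(sub("part", "", strsplit(lab, "|", fixed = TRUE)[[1]]))
      v <- min(max(v, 0.01), 0.99)
      at$occ[at$part == parts[1]] <- v
      at$occ[at$part == parts[2]] <- 1 - v
      next
    }
    i <- match(lab, at$label)
    if (nm %in% c("x", "y", "z")) at[[nm]][i] <- v %% 1
    else at[[nm]][i] <- max(v, if (nm %in% c("u_iso", "u11", "u22", "u33")) 1e-6 else v)
  }
  structure$atoms <- at
  list(structure = structure, scale = scale)
}

# --- weighted least squares --------------------------------------------------

lsq_weights <- function(f2_obs, sig, k_fc2, a, b) {
  P <- (pmax(f2_obs, 0) + 2 * k_fc2) / 3
  w <- 1 / (sig^2 + (a * P)^2 + b * P)
  if (any(!is.finite(w)) || any(w <= 0)) stop("lsq_weights: non-positive weight")
  w
}

# environment caching per-symop index lookups for fast per-atom recomputation
sf_workspace <- function(structure, table, H) {
  ops <- structure$symops
  ws <- list(H = H, ops = ops,
             idx = lapply(ops, function(op) tsc_lookup(table, H %*% op$R)),
             Hs = lapply(ops, function(op) H %*% op$R),
             col = match(structure$atoms$label, table$labels),
             mult = vapply(structure$atoms$label,
                           function(lb) symmetry_images(structure, lb)$multiplicity_factor, 0))
  if (anyNA(ws$col)) stop("sf_workspace: table lacks columns for some atoms")
  ws
}

# contribution column of atom j given its current row (coords/adp/occ)
atom_contrib_ws <- function(ws, cell, table, atom_row, j) {
  x <- as.numeric(atom_row[, c("x", "y", "z")])
  acc <- complex(real = rep(0, nrow(ws$H)))
  for (s in seq_along(ws$ops)) {
    op <- ws$ops[[s]]
    xs <- as.numeric(op$R %*% x + op$t)
    phase <- exp(2i * pi * as.numeric(ws$H %*% xs))
    dw <- dw_from_row(cell, atom_row, ws$Hs[[s]])
    acc <- acc + table$f[ws$idx[[s]], ws$col[j]] * dw * phase
  }
  acc * ws$mult[j] * atom_row$occ
}

all_contribs_ws <- function(ws, structure, table) {
  at <- structure$atoms
  sapply(seq_len(nrow(at)), function(j) atom_contrib_ws(ws, structure$cell, table, at[j, ], j))
}

#' One Gauss-Newton least-squares cycle
#'
#' Minimizes \eqn{\sum w (F_o^2 - k|F_c|^2)^2} by a single damped
#' Gauss-Newton step. Derivatives are analytic for the scale and the
#' disorder occupancies and central finite differences for coordinates and
#' displacement parameters. Shifts are capped so no atom moves more than
#' `max_shift_angstrom` per cycle and damped until the objective does not
#' increase.
#'
#' @param structure A [crystal_structure()].
#' @param refl A `reflection_set`.
#' @param table Form-factor table covering the symmetry closure.
#' @param pv Parameter vector from [make_param_vector()].
#' @param config A [refine_config()].
#' @param return_jacobian Attach the design matrix as element `jacobian`
#'   (for diagnostics).
#' @return List: updated `pv`, `structure`, `scale`, `objective`,
#'   `shift_norm`, `max_shift_angstrom`, `normal_matrix`, `weights`,
#'   `residuals`, `condition` (reciprocal condition estimate), `r1`.
#' @export
lsq_cycle <- function(structure, refl, table, pv, config = refine_config(),
                      return_jacobian = FALSE) {
  n_par <- nrow(pv)
  n_obs <- nrow(refl)
  if (n_obs < max(10, 5 * n_par)) {
    stop("lsq_cycle: under-determined problem: ", n_obs, " reflections for ",
         n_par, " parameters (need >= ", max(10, 5 * n_par), ")")
  }
  H <- as.matrix(refl[, c("h", "k", "l")])
  ws <- sf_workspace(structure, table, H)
  st <- apply_param_vector(structure, pv)
  structure <- st$structure; k <- st$scale

  contribs <- all_contribs_ws(ws, structure, table)
  Fc <- rowSums(contribs)
  fc2 <- Mod(Fc)^2
  w <- lsq_weights(refl$f2, refl$sig, k * fc2, config$weight_a, config$weight_b)
  r <- refl$f2 - k * fc2
  obj0 <- sum(w * r^2)

  at <- structure$atoms
  J <- matrix(0, n_obs, n_par)
  for (p in seq_len(n_par)) {
    nm <- pv$name[p]
    if (nm == "scale") { J[, p] <- fc2; next }
    if (nm == "occ") {
      parts <- as.integer(sub("part", "", strsplit(pv$atom[p], "|", fixed = TRUE)[[1]]))
      j1 <- which(at$part == parts[1]); j2 <- which(at$part == parts[2])
      pval <- pv$value[p]
      dF <- rowSums(contribs[, j1, drop = FALSE]) / pval -
        rowSums(contribs[, j2, drop = FALSE]) / (1 - pval)
      J[, p] <- k * 2 * Re(Conj(Fc) * dF)
      next
    }
    j <- match(pv$atom[p], at$label)
    step <- if (nm %in% c("x", "y", "z")) config$fd_step_frac else config$fd_step_u
    row_p <- at[j, ]; row_m <- at[j, ]
    row_p[[nm]] <- row_p[[nm]] + step
    row_m[[nm]] <- row_m[[nm]] - step
    dF <- (atom_contrib_ws(ws, structure$cell, table, row_p, j) -
             atom_contrib_ws(ws, structure$cell, table, row_m, j)) / (2 * step)
    J[, p] <- k * 2 * Re(Conj(Fc) * dF)
  }

  sw <- sqrt(w)
  A <- crossprod(J * sw)
  g <- crossprod(J * sw, sw * r)
  cond <- tryCatch(1 / kappa(A, exact = FALSE), error = function(e) 0)
  delta <- tryCatch(solve(A, g), error = function(e) {
    ev <- eigen(A, symmetric = TRUE)
    null_idx <- which(abs(ev$values) < max(abs(ev$values)) * 1e-12)
    bad <- unique(unlist(lapply(null_idx, function(ii) {
      comp <- abs(ev$vectors[, ii])
      paste(pv$atom[comp > 0.3], pv$name[comp > 0.3])
    })))
    stop("lsq_cycle: singular normal matrix; null space involves: ",
         paste(bad, collapse = ", "))
  })
  delta <- as.numeric(delta)

  # cap the largest Cartesian displacement
  shift_cart <- cap_factor <- 0
  xyz_idx <- which(pv$name %in% c("x", "y", "z"))
  if (length(xyz_idx)) {
    per_atom <- split(xyz_idx, pv$atom[xyz_idx])
    max_disp <- 0
    for (ix in per_atom) {
      d_frac <- c(x = 0, y = 0, z = 0)
      d_frac[pv$name[ix]] <- delta[ix]
      max_disp <- max(max_disp, sqrt(sum((structure$cell$frac2cart %*% d_frac)^2)))
    }
    shift_cart <- max_disp
    if (max_disp > config$max_shift_angstrom) {
      delta <- delta * config$max_shift_angstrom / max_disp
    }
  }

  # damped monotone-descent acceptance (weights held fixed)
  lambda <- config$damping
  accepted <- FALSE
  obj1 <- obj0
  pv_new <- pv
  for (try in 1:10) {
    pv_try <- pv
    pv_try$value <- pv$value + lambda * delta
    st_try <- apply_param_vector(structure, pv_try)
    contribs_try <- all_contribs_ws(ws, st_try$structure, table)
    fc2_try <- Mod(rowSums(contribs_try))^2
    obj_try <- sum(w * (refl$f2 - st_try$scale * fc2_try)^2)
    if (obj_try <= obj0 * (1 + 1e-12)) {
      pv_new <- pv_try; obj1 <- obj_try; accepted <- TRUE
      break
    }
    lambda <- lambda / 2
  }
  st_new <- apply_param_vector(structure, pv_new)
  fo <- sqrt(pmax(refl$f2, 0))
  fcmod <- {
    cn <- all_contribs_ws(ws, st_new$structure, table)
    Mod(rowSums(cn))
  }
  r1 <- sum(abs(fo - sqrt(st_new$scale) * fcmod)) / sum(fo)

  list(pv = pv_new, structure = st_new$structure, scale = st_new$scale,
       jacobian = if (return_jacobian) J else NULL,
       objective = obj1, objective_before = obj0,
       shift = (pv_new$value - pv$value), shift_norm = sqrt(sum((pv_new$value - pv$value)^2)),
       max_shift_angstrom = shift_cart, accepted = accepted,
       normal_matrix = A, weights = w, residuals = refl$f2 - st_new$scale * fcmod^2,
       condition = cond, r1 = r1)
}

#' Parameter standard uncertainties from the normal matrix
#'
#' \eqn{esd_p = \sqrt{GooF^2 (A^{-1})_{pp}}} with
#' \eqn{GooF = \sqrt{\sum w (F_o^2 - kF_c^2)^2 / (n_{obs} - n_{par})}}.
#'
#' @param normal_matrix Weighted normal matrix \eqn{J^T W J}.
#' @param weights Weights.
#' @param residuals Residuals \eqn{F_o^2 - k F_c^2}.
#' @param n_obs,n_params Observation and parameter counts.
#' @return List with `esd` (vector, `NA` if the matrix is singular),
#'   `goof` and `covariance` (or `NULL`).
#' @export
estimate_esds <- function(normal_matrix, weights, residuals, n_obs, n_params) {
  if (n_obs <= n_params) stop("estimate_esds: n_obs must exceed n_params")
  goof <- sqrt(sum(weights * residuals^2) / (n_obs - n_params))
  inv <- tryCatch(solve(normal_matrix), error = function(e) NULL)
  if (is.null(inv)) {
    return(list(esd = rep(NA_real_, ncol(normal_matrix)), goof = goof, covariance = NULL))
  }
  list(esd = goof * sqrt(pmax(diag(inv), 0)), goof = goof, covariance = goof^2 * inv)
}

#' Refine a structure against intensities
#'
#' The full iterative workflow: an outer loop that (re)builds the bond
#' graph, transfers bank parameters, rebinds local frames and regenerates
#' the form-factor table, and an inner loop of damped Gauss-Newton cycles.
#' The outer loop stops when the largest fractional coordinate change
#' drops below `config$outer_tol` or after `config$max_outer` cycles;
#' convergence status is reported honestly either way.
#'
#' @param structure Starting [crystal_structure()] (model tags resolved).
#' @param refl A `reflection_set`.
#' @param bank A [parse_bank()] bank (required when any atom is `"taam"`).
#' @param config A [refine_config()].
#' @param external Optional external [tsc_table()] for `"external_tsc"` atoms.
#' @param charge_groups Optional electroneutrality groups (see
#'   [electroneutrality_rescale()]).
#' @return A `taam_refinement` object; see [tidy.taam_refinement()] and
#'   [glance.taam_refinement()].
#' @export
refine <- function(structure, refl, bank = NULL, config = refine_config(),
                   external = NULL, charge_groups = NULL) {
  stopifnot(inherits(structure, "crystal_structure"))
  if (any(structure$atoms$model == "taam") && is.null(bank)) {
    stop("refine: structure contains taam atoms but no bank was supplied")
  }
  bad <- refl$f2 < -3 * refl$sig
  if (any(bad)) {
    warning("refine: rejecting ", sum(bad), " reflection(s) with F_o^2 < -3 sigma")
    refl <- reflection_set(refl[!bad, ], wavelength = attr(refl, "wavelength"))
  }

  pv <- make_param_vector(structure, config)
  # initialize scale by its closed form against a first model evaluation
  cycle_log <- list()
  r1_hist <- numeric(0)
  last_xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  converged <- FALSE
  n_outer <- 0L
  final <- NULL
  table <- NULL
  assignment <- NULL

  for (outer in seq_len(config$max_outer)) {
    n_outer <- outer
    # regenerate typing, frames, form factors from current geometry
    if (any(structure$atoms$model == "taam")) {
      graph <- build_bond_graph(structure)
      assignment <- assign_types(structure, graph, bank)
      assignment <- suppressWarnings(
        electroneutrality_rescale(assignment, structure, groups = charge_groups))
      frames <- bind_axes(assignment, graph, structure)
    } else {
      frames <- NULL
    }
    table <- make_form_factor_table(structure, as.matrix(refl[, c("h", "k", "l")]),
                                    assignment = assignment, frames = frames,
                                    external = external,
                                    hydrogen_mode = config$hydrogen_mode)
    if (outer == 1L && config$refine_scale) {
      sf0 <- structure_factors(structure, table, as.matrix(refl[, c("h", "k", "l")]))
      fc2 <- sf0$f_calc_mod^2
      w0 <- 1 / refl$sig^2
      k0 <- sum(w0 * refl$f2 * fc2) / sum(w0 * fc2^2)
      pv$value[pv$name == "scale"] <- max(k0, 1e-12)
    }

    # inner Gauss-Newton loop
    for (inner in seq_len(config$max_inner)) {
      res <- lsq_cycle(structure, refl, table, pv, config)
      pv <- res$pv
      structure <- res$structure
      cycle_log[[length(cycle_log) + 1L]] <- tibble::tibble(
        outer = outer, inner = inner, objective = res$objective,
        objective_before = res$objective_before,
        r1 = res$r1, shift_norm = res$shift_norm, accepted = res$accepted)
      if (!res$accepted || res$shift_norm < 1e-8) break
      if (res$shift_norm < 1e-7 * max(1, sqrt(sum(pv$value^2)))) break
    }
    final <- res
    r1_hist <- c(r1_hist, res$r1)
    if (length(r1_hist) >= 4 &&
        all(diff(utils::tail(r1_hist, 4)) > 0)) {
      stop("refine: diverging (R1 increased over 3 consecutive outer cycles: ",
           paste(signif(utils::tail(r1_hist, 4), 4), collapse = " -> "), ")")
    }
    xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
    dxyz <- xyz - last_xyz
    dxyz <- dxyz - round(dxyz)
    max_dx <- max(abs(dxyz))
    last_xyz <- xyz
    if (outer > 1L && max_dx < config$outer_tol) { converged <- TRUE; break }
    if (outer == 1L && max_dx < config$outer_tol && res$shift_norm < 1e-8) {
      converged <- TRUE; break
    }
  }

  es <- estimate_esds(final$normal_matrix, final$weights, final$residuals,
                      n_obs = nrow(refl), n_params = nrow(pv))
  pv$esd <- es$esd
  scale <- pv$value[pv$name == "scale"]
  if (!length(scale)) scale <- 1

  stats <- r_factors(refl$f2, refl$sig,
                     structure_factors(structure, table, as.matrix(refl[, c("h", "k", "l")]))$f_calc_mod,
                     k = scale, weights = final$weights)
  stats$goof <- es$goof

  out <- list(structure = structure, scale = scale, params = pv,
              esd_covariance = es$covariance, goof = es$goof,
              cycle_log = dplyr::bind_rows(cycle_log),
              n_outer = n_outer, converged = converged,
              stats = stats, table = table, refl = refl,
              assignment = assignment, config = config)
  class(out) <- "taam_refinement"
  out
}

#' @export
print.taam_refinement <- function(x, ...) {
  cat(sprintf("<taam_refinement> %s after %d outer cycle(s)\n",
              if (x$converged) "converged" else "NOT converged", x$n_outer))
  cat(sprintf("  R1(gt) %.3f%%  R1(all) %.3f%%  wR2 %.3f%%  GooF %.3f  scale %.5g\n",
              x$stats$r1_gt, x$stats$r1_all, x$stats$wr2_all, x$goof, x$scale))
  invisible(x)
}
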