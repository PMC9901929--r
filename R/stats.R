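#' Crystallographic agreement factors
#'
#' \eqn{R1 = \sum ||F_o| - \sqrt{k}|F_c|| / \sum |F_o|} with
#' \eqn{|F_o| = \sqrt{\max(F_o^2, 0)}}, over the gt subset
#' (\eqn{F_o^2 > 2\sigma}) and over all reflections, and
#' \eqn{wR2 = \sqrt{\sum w (F_o^2 - k F_c^2)^2 / \sum w (F_o^2)^2}}.
#' `k` is the intensity scale (the model for \eqn{F_o^2} is
#' \eqn{k|F_c|^2}). Reported in percent.
#'
#' @param f2_obs,sig Observed intensities and their uncertainties.
#' @param f_calc_mod Model structure-factor moduli \eqn{|F_c|}.
#' @param k Intensity scale factor.
#' @param weights Optional weights (default \eqn{1/\sigma^2}).
#' @return A `statistics_block` list: `r1_gt`, `r1_all`, `wr2_gt`,
#'   `wr2_all` (percent), `n_gt`, `n_all`.
#' @export
r_factors <- function(f2_obs, sig, f_calc_mod, k = 1, weights = NULL) {
  stopifnot(length(f2_obs) == length(f_calc_mod), length(f2_obs) == length(sig))
  if (is.null(weights)) weights <- 1 / sig^2
  fo <- sqrt(pmax(f2_obs, 0))
  fc <- sqrt(k) * f_calc_mod
  gt <- f2_obs > 2 * sig
  r1 <- function(sel) {
    if (!any(sel)) return(NA_real_)
    100 * sum(abs(fo[sel] - fc[sel])) / sum(fo[sel])
  }
  wr2 <- function(sel) {
    if (!any(sel)) return(NA_real_)
    100 * sqrt(sum(weights[sel] * (f2_obs[sel] - k * f_calc_mod[sel]^2)^2) /
                 sum(weights[sel] * f2_obs[sel]^2))
  }
  if (!any(gt)) warning("r_factors: empty gt subset (no F_o^2 > 2 sigma)")
  out <- list(r1_gt = r1(gt), r1_all = r1(rep(TRUE, length(fo))),
              wr2_gt = wr2(gt), wr2_all = wr2(rep(TRUE, length(fo))),
              n_gt = sum(gt), n_all = length(fo))
  class(out) <- "statistics_block"
  out
}

#' @export
print.statistics_block <- function(x, ...) {
  cat(sprintf("R1(gt) %.3f%% [n=%d]  R1(all) %.3f%% [n=%d]  wR2(all) %.3f%%\n",
              x$r1_gt, x$n_gt, x$r1_all, x$n_all, x$wr2_all))
  if (!is.null(x$peak)) cat(sprintf("peak/hole %+.3f/%+.3f e/A^3\n", x$peak, x$hole))
  invisible(x)
}

#' Difference-Fourier residual density map
#'
#' \deqn{\Delta\rho(r) = \frac{1}{V} \sum_h (|F_o|/\sqrt{k} - |F_c|)
#'   e^{i\phi_c(h)} e^{-2\pi i h\cdot r}}
#' evaluated by FFT on a grid with spacing at most `spacing` Angstrom.
#' The sum is Friedel-completed (a missing mate is added as the conjugate
#' coefficient) so the synthesis is real; F(000) is excluded, making the
#' map zero-mean. All reflections enter by default (`gt_only = FALSE`).
#'
#' @param structure A [crystal_structure()] (for the cell).
#' @param refl A `reflection_set`.
#' @param f_calc Complex model structure factors matching `refl` rows.
#' @param k Intensity scale.
#' @param spacing Target grid spacing in Angstrom (must be <= 0.2).
#' @param gt_only Restrict the synthesis to the gt subset.
#' @return A `residual_map`: list with `values` (3D array, e/Angstrom^3),
#'   `dim`, `cell`.
#' @export
difference_map <- function(structure, refl, f_calc, k = 1, spacing = 0.1,
                           gt_only = FALSE) {
  stopifnot(inherits(structure, "crystal_structure"), spacing <= 0.2)
  cl <- structure$cell
  sel <- if (gt_only) refl$f2 > 2 * refl$sig else rep(TRUE, nrow(refl))
  H <- as.matrix(refl[sel, c("h", "k", "l")])
  dF <- (sqrt(pmax(refl$f2[sel], 0) / k) - Mod(f_calc[sel])) *
    exp(1i * Arg(f_calc[sel]))
  # Friedel completion
  key <- paste(H[, 1], H[, 2], H[, 3])
  mate <- paste(-H[, 1], -H[, 2], -H[, 3])
  need <- !(mate %in% key)
  if (any(need)) {
    H <- rbind(H, -H[need, , drop = FALSE])
    dF <- c(dF, Conj(dF[need]))
  }
  hmax <- apply(abs(H), 2, max)
  n <- pmax(ceiling(c(cl$a, cl$b, cl$c) / spacing), 2 * hmax + 2)
  A <- array(complex(1), dim = n)
  idx <- cbind(H[, 1] %% n[1] + 1, H[, 2] %% n[2] + 1, H[, 3] %% n[3] + 1)
  # duplicate hkl cannot occur (reflection_set invariant), so plain assignment
  A[idx] <- dF
  rho <- Re(stats::fft(A)) / cl$volume
  structure(list(values = rho, dim = n, cell = cl, spacing = spacing),
            class = "residual_map")
}

#' @export
print.residual_map <- function(x, ...) {
  cat(sprintf("<residual_map> %d x %d x %d grid, range [%+.4f, %+.4f] e/A^3\n",
              x$dim[1], x$dim[2], x$dim[3], min(x$values), max(x$values)))
  invisible(x)
}

#' Extreme residual densities
#'
#' Largest and smallest map values, refined by a local quadratic fit on
#' the 3x3x3 neighbourhood of the extreme voxel (offset clamped to one
#' voxel).
#'
#' @param map A [difference_map()] result.
#' @return List: `peak`, `hole` (e/Angstrom^3), `peak_frac`, `hole_frac`
#'   (fractional coordinates of the interpolated extrema).
#' @export
peak_hole <- function(map) {
  pk <- interpolate_extremum(map, which.max(map$values), maximize = TRUE)
  hl <- interpolate_extremum(map, which.min(map$values), maximize = FALSE)
  list(peak = pk$value, hole = hl$value,
       peak_frac = pk$frac, hole_frac = hl$frac)
}

interpolate_extremum <- function(map, flat_idx, maximize = TRUE) {
  n <- map$dim
  ijk <- arrayInd(flat_idx, n)
  # central-difference quadratic model on the periodic 3x3x3 neighbourhood
  val <- function(di, dj, dk) {
    map$values[(ijk[1] - 1 + di) %% n[1] + 1,
               (ijk[2] - 1 + dj) %% n[2] + 1,
               (ijk[3] - 1 + dk) %% n[3] + 1]
  }
  g <- numeric(3); Hm <- matrix(0, 3, 3)
  f0 <- val(0, 0, 0)
  for (d in 1:3) {
    e <- c(0, 0, 0); e[d] <- 1
    fp <- val(e[1], e[2], e[3]); fm <- val(-e[1], -e[2], -e[3])
    g[d] <- (fp - fm) / 2
    Hm[d, d] <- fp - 2 * f0 + fm
  }
  for (d1 in 1:2) for (d2 in (d1 + 1):3) {
    e1 <- c(0, 0, 0); e1[d1] <- 1
    e2 <- c(0, 0, 0); e2[d2] <- 1
    Hm[d1, d2] <- Hm[d2, d1] <-
      (val(e1[1] + e2[1], e1[2] + e2[2], e1[3] + e2[3]) -
         val(e1[1] - e2[1], e1[2] - e2[2], e1[3] - e2[3]) -
         val(e2[1] - e1[1], e2[2] - e1[2], e2[3] - e1[3]) +
         val(-e1[1] - e2[1], -e1[2] - e2[2], -e1[3] - e2[3])) / 4
  }
  off <- tryCatch(-solve(Hm, g), error = function(e) c(0, 0, 0))
  if (any(!is.finite(off)) || max(abs(off)) > 1) off <- c(0, 0, 0)
  value <- f0 + sum(g * off) + 0.5 * sum(off * (Hm %*% off))
  if (maximize && value < f0) { off <- c(0, 0, 0); value <- f0 }
  if (!maximize && value > f0) { off <- c(0, 0, 0); value <- f0 }
  frac <- ((ijk - 1 + off) / n) %% 1
  list(value = value, frac = as.numeric(frac))
}

#' Fractal-dimension plot of a residual map
#'
#' Box-counting transform of the residual density: for each iso-level
#' \eqn{\rho_0} (bin centres spanning the map range),
#' \eqn{N(\rho_0)} counts the grid cells whose 2x2x2 corner values bracket
#' \eqn{\rho_0} (periodic), and
#' \eqn{d^f(\rho_0) = 3 \ln N(\rho_0) / \ln N_{total}} (0 where no cell
#' brackets the level). A parabolic curve peaking near \eqn{\rho_0 = 0}
#' with apex close to 3 indicates featureless Gaussian noise.
#'
#' @param map A [difference_map()] result.
#' @param n_bins Number of iso-levels (default 101).
#' @return A `fractal_curve` tibble with `rho0` (e/Angstrom^3) and `df`.
#' @export
fractal_dimension <- function(map, n_bins = 101L) {
  v <- map$values
  n <- map$dim
  rng <- range(v)
  if (diff(rng) == 0) {
    out <- tibble::tibble(rho0 = rng[1], df = 3)
    class(out) <- c("fractal_curve", class(out))
    return(out)
  }
  rho0 <- seq(rng[1], rng[2], length.out = n_bins)
  # per-cell min/max over the 8 corners (periodic shifts)
  shift <- function(a, d) {
    idx <- lapply(seq_along(n), function(ax) {
      if (d[ax] == 0) seq_len(n[ax]) else c(2:n[ax], 1L)
    })
    a[idx[[1]], idx[[2]], idx[[3]]]
  }
  lo <- v; hi <- v
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    if (di + dj + dk == 0) next
    s <- shift(v, c(di, dj, dk))
    lo <- pmin(lo, s); hi <- pmax(hi, s)
  }
  lo_s <- sort(as.vector(lo)); hi_s <- sort(as.vector(hi))
  ntot <- length(lo_s)
  # N(rho0) = #cells with lo <= rho0 <= hi
  nlo <- findInterval(rho0, lo_s)                # lo <= rho0
  nhi <- ntot - findInterval(rho0, hi_s, left.open = TRUE)  # hi >= rho0
  N <- nlo + nhi - ntot
  N[N < 0] <- 0
  df <- ifelse(N > 0, 3 * log(N) / log(ntot), 0)
  out <- tibble::tibble(rho0 = rho0, df = df)
  class(out) <- c("fractal_curve", class(out))
  out
}

#' Compare displacement parameters across refinement variants
#'
#' @param structures Named list of [crystal_structure()] objects (or
#'   `taam_refinement` objects) sharing identical atom labels.
#' @return List: `per_atom` (tibble of U_eq/U_iso per variant, wide) and
#'   `element_ratios` (per-element mean U_eq ratio of every variant to the
#'   first).
#' @export
adp_summary <- function(structures) {
  structures <- lapply(structures, function(s) {
    if (inherits(s, "taam_refinement")) s$structure else s
  })
  if (is.null(names(structures)) || any(!nzchar(names(structures)))) {
    names(structures) <- paste0("variant", seq_along(structures))
  }
  labs <- lapply(structures, function(s) s$atoms$label)
  for (i in seq_along(labs)[-1]) {
    if (!identical(sort(labs[[1]]), sort(labs[[i]]))) {
      stop("adp_summary: atom labels differ between variants: ",
           paste(c(setdiff(labs[[1]], labs[[i]]), setdiff(labs[[i]], labs[[1]])),
                 collapse = ", "))
    }
  }
  tabs <- lapply(names(structures), function(nm) {
    u <- u_eq(structures[[nm]])
    u$variant <- nm
    u
  })
  long <- dplyr::bind_rows(tabs)
  wide <- tidyr::pivot_wider(long, id_cols = c("label", "element"),
                             names_from = "variant", values_from = "u_eq")
  ref <- names(structures)[1]
  ratios <- long |>
    dplyr::left_join(long |> dplyr::filter(.data$variant == ref) |>
                       dplyr::select("label", u_ref = "u_eq"),
                     by = "label") |>
    dplyr::filter(.data$variant != ref) |>
    dplyr::group_by(.data$element, .data$variant) |>
    dplyr::summarise(mean_ratio = mean(.data$u_eq / .data$u_ref), .groups = "drop")
  list(per_atom = wide, element_ratios = ratios)
}

#' Default neutron-reference X-H bond lengths
#'
#' A small built-in table of typical neutron-diffraction bond lengths
#' (Angstrom) for the bond classes produced by [bond_report()]; meant as a
#' convenience default, replaceable by the user.
#' @return Named numeric vector.
#' @export
neutron_reference_default <- function() {
  c("O-H(water)" = 0.96, "N-H" = 1.01, "C-H" = 1.08, "C-H(ar)" = 1.08)
}

#' Bond-length report with esds and reference comparison
#'
#' Tabulates every bond with its length, the propagated esd (from the
#' coordinate block of the refinement covariance: per-atom position
#' covariances, cross-atom terms neglected), a chemical class, and the
#' difference to a neutron-reference value for X-H classes. Also reports
#' the mean C-C esd, the conventional precision metric.
#'
#' @param refinement A `taam_refinement` (or a [crystal_structure()], in
#'   which case esds are absent).
#' @param neutron_reference Named vector class -> Angstrom.
#' @return List: `bonds` (tibble `a`, `b`, `class`, `length`, `esd`,
#'   `ref`, `delta`), `class_means`, `mean_cc_esd`.
#' @export
bond_report <- function(refinement, neutron_reference = neutron_reference_default()) {
  if (inherits(refinement, "taam_refinement")) {
    st <- refinement$structure
    cov <- refinement$esd_covariance
    pv <- refinement$params
  } else {
    st <- refinement; cov <- NULL; pv <- NULL
  }
  graph <- build_bond_graph(st)
  at <- st$atoms
  el <- stats::setNames(at$element, at$label)
  pos <- stats::setNames(lapply(seq_len(nrow(at)), function(i) as.numeric(at[i, c("x", "y", "z")])),
                         at$label)
  M <- st$cell$frac2cart
  ring <- graph$ring_atoms
  hdeg <- heavy_degree(graph, st)

  classify <- function(a, b) {
    ea <- el[a]; eb <- el[b]
    if (ea == "H" || eb == "H") {
      hv <- if (ea == "H") b else a
      if (el[hv] == "O" && all(el[graph$adjacency[[hv]]] == "H")) return("O-H(water)")
      if (el[hv] == "O") return("O-H")
      if (el[hv] == "N") return("N-H")
      if (el[hv] == "C" && hv %in% ring) return("C-H(ar)")
      return(paste0(el[hv], "-H"))
    }
    paste(sort(c(ea, eb)), collapse = "-")
  }

  coord_cov <- function(lab) {
    C <- matrix(0, 3, 3)
    if (is.null(cov) || is.null(pv)) return(C)
    for (d1 in 1:3) for (d2 in 1:3) {
      i1 <- which(pv$atom == lab & pv$name == c("x", "y", "z")[d1])
      i2 <- which(pv$atom == lab & pv$name == c("x", "y", "z")[d2])
      if (length(i1) && length(i2)) C[d1, d2] <- cov[i1, i2]
    }
    C
  }

  rows <- lapply(seq_len(nrow(graph$bonds)), function(r) {
    a <- graph$bonds$a[r]; b <- graph$bonds$b[r]
    d <- pos[[a]] - pos[[b]]
    d <- d - round(d)
    v <- as.numeric(M %*% d)
    len <- sqrt(sum(v^2))
    gfrac <- as.numeric(t(M) %*% (v / len))   # d(len)/d(frac_a) = -d/d(frac_b)
    var <- as.numeric(t(gfrac) %*% coord_cov(a) %*% gfrac +
                        t(gfrac) %*% coord_cov(b) %*% gfrac)
    cls <- classify(a, b)
    ref <- if (cls %in% names(neutron_reference)) neutron_reference[[cls]] else NA_real_
    tibble::tibble(a = a, b = b, class = cls, length = len,
                   esd = if (!is.null(cov)) sqrt(max(var, 0)) else NA_real_,
                   ref = ref, delta = len - ref)
  })
  bonds <- dplyr::bind_rows(rows)
  class_means <- bonds |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = dplyr::n(), mean_length = mean(.data$length),
                     mean_esd = mean(.data$esd),
                     mean_delta = mean(.data$delta), .groups = "drop")
  cc <- bonds$esd[bonds$class == "C-C"]
  list(bonds = bonds, class_means = class_means,
       mean_cc_esd = if (length(cc)) mean(cc) else NA_real_)
}
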