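#' Symmetry closure of an hkl list
#'
#' The union of \eqn{R_s^T h} over all symmetry operators and requested
#' indices: every index at which a form factor may be looked up during the
#' symmetry-expanded structure-factor sum.
#'
#' @param structure A [crystal_structure()].
#' @param hkl n x 3 integer matrix.
#' @return Integer matrix (unique rows, requested indices first).
#' @export
hkl_symmetry_closure <- function(structure, hkl) {
  H <- to_hkl_matrix(hkl)
  all_h <- do.call(rbind, lapply(structure$symops, function(op) H %*% op$R))
  all_h <- rbind(H, all_h)
  storage.mode(all_h) <- "integer"
  all_h[!duplicated(paste(all_h[, 1], all_h[, 2], all_h[, 3])), , drop = FALSE]
}

#' Build the form-factor table for a structure
#'
#' Evaluates, for every atom and every index in the symmetry closure of
#' `hkl`, the scattering factor dictated by the atom's `model` tag:
#' `"taam"` atoms use the transferred Hansen-Coppens parameters and local
#' frames, `"iam"` atoms the spherical reference (with the bonded-H option
#' for hydrogen), and `"external_tsc"` atoms copy their column from a
#' supplied table. Unmatched TAAM atoms fall back to IAM with a warning.
#'
#' @param structure A [crystal_structure()].
#' @param hkl Requested n x 3 index matrix (the table covers its closure).
#' @param assignment Optional [assign_types()] result (required if any
#'   atom is tagged `"taam"`).
#' @param frames Optional [bind_axes()] result (defaults to identity frames).
#' @param external Optional [tsc_table()] supplying `"external_tsc"` atoms.
#' @param hydrogen_mode IAM hydrogen treatment, `"bonded"` or `"free"`.
#' @return A [tsc_table()] whose header records each atom's source model.
#' @export
make_form_factor_table <- function(structure, hkl, assignment = NULL,
                                   frames = NULL, external = NULL,
                                   hydrogen_mode = "bonded") {
  at <- structure$atoms
  closure <- hkl_symmetry_closure(structure, hkl)
  hcart <- hkl_to_cart(structure$cell, closure)
  hmag <- sqrt(rowSums(hcart^2))
  f <- matrix(complex(1), nrow(closure), nrow(at))
  sources <- stats::setNames(character(nrow(at)), at$label)
  params <- if (!is.null(assignment)) attr(assignment, "params") else NULL

  for (j in seq_len(nrow(at))) {
    lb <- at$label[j]
    model <- at$model[j]
    if (model == "taam") {
      pj <- params[[lb]]
      if (is.null(pj)) {
        warning("make_form_factor_table: atom ", lb,
                " is tagged taam but unmatched in the bank; using IAM fallback")
        model <- "iam"
      }
    }
    if (model == "taam") {
      fr <- if (!is.null(frames) && !is.null(frames[[lb]])) frames[[lb]] else identity_frame()
      f[, j] <- aspherical_form_factor(pj, fr, hcart)
      sources[lb] <- "taam"
    } else if (model == "iam") {
      f[, j] <- iam_form_factor(at$element[j], hmag, hydrogen_mode = hydrogen_mode)
      sources[lb] <- "iam"
    } else if (model == "external_tsc") {
      if (is.null(external) || !lb %in% external$labels) {
        stop("make_form_factor_table: atom ", lb,
             " is tagged external_tsc but missing from the supplied table")
      }
      idx <- tsc_lookup(external, closure)
      f[, j] <- external$f[idx, match(lb, external$labels)]
      sources[lb] <- "external_tsc"
    }
  }
  tsc_table(at$label, closure, f,
            title = "taamkit model form factors", symm = "closure",
            sources = sources)
}

#' Debye-Waller attenuation factor
#'
#' Isotropic: \eqn{\exp(-8\pi^2 U_{iso} (\sin\theta/\lambda)^2)}.
#' Anisotropic (CIF reciprocal-basis \eqn{U^{ij}}):
#' \eqn{\exp(-2\pi^2 \sum_{ij} h'_i h'_j a^*_i a^*_j U^{ij})} with
#' \eqn{h' = R_s^T h}, the symmetry-transformed index.
#'
#' @param structure A [crystal_structure()].
#' @param label Atom label.
#' @param hkl n x 3 index matrix.
#' @param symop_index Which symmetry operator transforms the index.
#' @return Numeric attenuations in (0, 1].
#' @export
debye_waller <- function(structure, label, hkl, symop_index = 1L) {
  i <- match(label, structure$atoms$label)
  if (is.na(i)) stop("debye_waller: no atom labelled ", label)
  H <- to_hkl_matrix(hkl) %*% structure$symops[[symop_index]]$R
  dw_from_row(structure$cell, structure$atoms[i, ], H)
}

# attenuation for pre-rotated indices Hs (n x 3)
dw_from_row <- function(cell, atom_row, Hs) {
  if (atom_is_aniso(atom_row)) {
    U <- atom_u_matrix(atom_row)
    N <- diag(c(cell$recip$a_star, cell$recip$b_star, cell$recip$c_star))
    A <- N %*% U %*% N
    exp(-2 * pi^2 * rowSums((Hs %*% A) * Hs))
  } else {
    inv_d2 <- rowSums((Hs %*% cell$metric_star) * Hs)
    exp(-8 * pi^2 * atom_row$u_iso * (inv_d2 / 4))
  }
}

#' Per-atom structure-factor contributions
#'
#' The symmetry-expanded sum
#' \deqn{A_j(h) = m_j\, occ_j \sum_s f_j(R_s^T h)\, T_j(h,s)\,
#'   e^{2\pi i\, h\cdot(R_s x_j + t_s)}}
#' with \eqn{m_j} the special-position multiplicity factor. The total
#' structure factor is the row sum over atoms.
#'
#' @param structure A [crystal_structure()].
#' @param table A [tsc_table()] covering the symmetry closure of `hkl`.
#' @param hkl n x 3 index matrix.
#' @return Complex n_hkl x n_atoms matrix (columns named by label).
#' @export
structure_factor_contribs <- function(structure, table, hkl) {
  at <- structure$atoms
  H <- to_hkl_matrix(hkl)
  n <- nrow(H)
  contrib <- matrix(complex(1), n, nrow(at), dimnames = list(NULL, at$label))
  mult <- vapply(at$label, function(lb) symmetry_images(structure, lb)$multiplicity_factor, 0)
  X <- t(as.matrix(at[, c("x", "y", "z")]))
  col <- match(at$label, table$labels)
  if (anyNA(col)) {
    stop("structure_factor_contribs: table lacks column(s) for atom(s) ",
         paste(at$label[is.na(col)], collapse = ", "))
  }
  for (op in structure$symops) {
    Hs <- H %*% op$R
    idx <- tsc_lookup(table, Hs)
    Xs <- op$R %*% X + op$t   # 3 x n_atoms
    phase <- exp(2i * pi * (H %*% Xs))
    for (j in seq_len(nrow(at))) {
      dw <- dw_from_row(structure$cell, at[j, ], Hs)
      contrib[, j] <- contrib[, j] + table$f[idx, col[j]] * dw * phase[, j]
    }
  }
  sweep(contrib, 2, mult * at$occ, `*`)
}

#' Model structure factors
#'
#' @inheritParams structure_factor_contribs
#' @return Tibble with `h`, `k`, `l`, complex `f_calc`, `f_calc_mod` and
#'   `phase` (radians).
#' @export
structure_factors <- function(structure, table, hkl) {
  H <- to_hkl_matrix(hkl)
  Fc <- rowSums(structure_factor_contribs(structure, table, hkl))
  tibble::tibble(h = as.integer(H[, 1]), k = as.integer(H[, 2]), l = as.integer(H[, 3]),
                 f_calc = Fc, f_calc_mod = Mod(Fc), phase = Arg(Fc))
}

# expand a structure to P1 (all symmetry images as independent atoms,
# duplicates on special positions collapsed); the strongest symmetry oracle
expand_to_p1 <- function(structure) {
  at <- structure$atoms
  rows <- list()
  for (i in seq_len(nrow(at))) {
    im <- symmetry_images(structure, at$label[i])
    keep <- !duplicated(im$images$image_group)
    sel <- im$images[keep, ]
    for (r in seq_len(nrow(sel))) {
      row <- at[i, ]
      row$label <- paste0(at$label[i], "_s", sel$symop[r])
      row$x <- sel$x[r]; row$y <- sel$y[r]; row$z <- sel$z[r]
      if (atom_is_aniso(row)) {
        R <- structure$symops[[sel$symop[r]]]$R
        U <- R %*% atom_u_matrix(row) %*% t(R)  # fractional-basis congruence
        row$u11 <- U[1, 1]; row$u22 <- U[2, 2]; row$u33 <- U[3, 3]
        row$u12 <- U[1, 2]; row$u13 <- U[1, 3]; row$u23 <- U[2, 3]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  crystal_structure(structure$cell, list("x,y,z"), dplyr::bind_rows(rows),
                    formula_charge = structure$formula_charge)
}
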