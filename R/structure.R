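#' Assemble a crystal structure
#'
#' The central container of the package: unit cell, explicit symmetry
#' operator list and an atom table. Symmetry comes only from the operator
#' list; no space-group lookup is performed.
#'
#' @param cell A [unit_cell()].
#' @param symops List of `symop` objects (or xyz strings). Must contain the
#'   identity exactly once.
#' @param atoms A data frame with one row per atom in the asymmetric unit.
#'   Required columns: `label` (unique), `element`, `x`, `y`, `z`
#'   (fractional, wrapped to [0,1) on ingest), `occ` in (0,1]. Optional:
#'   `u_iso` (Angstrom^2), `u11`,`u22`,`u33`,`u12`,`u13`,`u23` (CIF
#'   reciprocal-basis convention; when present and non-NA they override
#'   `u_iso`), `part` (integer disorder group, 0 = ordered), `model`
#'   (`"iam"`, `"taam"` or `"external_tsc"`).
#' @param formula_charge Integer total charge of the formula unit.
#' @return An object of class `crystal_structure`.
#' @export
crystal_structure <- function(cell, symops, atoms, formula_charge = 0L) {
  stopifnot(inherits(cell, "unit_cell"))
  symops <- lapply(symops, function(s) if (is.character(s)) parse_symop(s) else s)
  if (!all(vapply(symops, inherits, TRUE, "symop"))) {
    stop("crystal_structure: symops must be symop objects or xyz strings")
  }
  n_id <- sum(vapply(symops, function(s) symop_equal(s, symop_identity()), TRUE))
  if (n_id != 1) stop("crystal_structure: identity operator must be present exactly once (found ", n_id, ")")

  atoms <- tibble::as_tibble(atoms)
  need <- c("label", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("crystal_structure: atom table lacks column(s) ", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$label)) {
    stop("crystal_structure: duplicate atom labels: ",
         paste(unique(atoms$label[duplicated(atoms$label)]), collapse = ", "))
  }
  if (!"occ" %in% names(atoms)) atoms$occ <- 1
  if (!"u_iso" %in% names(atoms)) atoms$u_iso <- 0.02
  for (cn in c("u11", "u22", "u33", "u12", "u13", "u23")) {
    if (!cn %in% names(atoms)) atoms[[cn]] <- NA_real_
  }
  if (!"part" %in% names(atoms)) atoms$part <- 0L
  if (!"model" %in% names(atoms)) atoms$model <- "taam"
  atoms$part <- as.integer(atoms$part)
  if (!all(atoms$model %in% c("iam", "taam", "external_tsc"))) {
    stop("crystal_structure: model must be one of iam, taam, external_tsc")
  }
  if (any(!is.finite(atoms$occ)) || any(atoms$occ <= 0) || any(atoms$occ > 1)) {
    stop("crystal_structure: occupancies must lie in (0, 1]")
  }
  unknown <- setdiff(unique(atoms$element), names(element_numbers()))
  if (length(unknown)) {
    stop("crystal_structure: unknown element symbol(s): ", paste(unknown, collapse = ", "),
         " (atoms ", paste(atoms$label[atoms$element %in% unknown], collapse = ", "), ")")
  }
  atoms$x <- atoms$x %% 1; atoms$y <- atoms$y %% 1; atoms$z <- atoms$z %% 1

  # ADP sanity
  for (i in seq_len(nrow(atoms))) {
    if (atom_is_aniso(atoms[i, ])) {
      U <- atom_u_matrix(atoms[i, ])
      ev <- eigen(u_cif_to_cart(cell, U), symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8) {
        stop("crystal_structure: U^ij of atom ", atoms$label[i], " is not positive semi-definite")
      }
    } else if (is.finite(atoms$u_iso[i]) && atoms$u_iso[i] < 0) {
      stop("crystal_structure: negative U_iso for atom ", atoms$label[i])
    }
  }

  st <- list(cell = cell, symops = symops, atoms = atoms,
             formula_charge = as.integer(formula_charge))
  class(st) <- "crystal_structure"
  st
}

atom_is_aniso <- function(atom_row) {
  all(is.finite(unlist(atom_row[c("u11", "u22", "u33", "u12", "u13", "u23")])))
}

atom_u_matrix <- function(atom_row) {
  u <- unlist(atom_row[c("u11", "u22", "u33", "u12", "u13", "u23")])
  matrix(c(u[1], u[4], u[5],
           u[4], u[2], u[6],
           u[5], u[6], u[3]), 3, 3)
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("<crystal_structure> %d atom(s), %d symop(s), charge %+d\n",
              nrow(x$atoms), length(x$symops), x$formula_charge))
  print(x$cell)
  print(utils::head(x$atoms, 10))
  invisible(x)
}

#' Element atomic numbers known to the package
#'
#' @return Named integer vector of atomic numbers for the supported elements.
#' @export
element_numbers <- function() {
  c(H = 1L, C = 6L, N = 7L, O = 8L, Na = 11L, S = 16L)
}

#' Symmetry images of an atom
#'
#' Applies every symmetry operator to an atom's fractional coordinates,
#' wraps the images to [0,1), and collapses duplicates (special positions,
#' within `tol` in fractional lattice distance). The multiplicity factor
#' `n_unique / n_symops` enters the structure-factor sum so that sites on
#' special positions are not over-counted.
#'
#' @param structure A [crystal_structure()].
#' @param label Atom label.
#' @param tol Fractional tolerance for duplicate-image collapse.
#' @return List with `images` (tibble: symop index, x, y, z, representative
#'   flag), `n_unique`, and `multiplicity_factor` = n_unique / n_symops.
#' @export
symmetry_images <- function(structure, label, tol = 1e-4) {
  stopifnot(inherits(structure, "crystal_structure"))
  i <- match(label, structure$atoms$label)
  if (is.na(i)) stop("symmetry_images: no atom labelled ", label)
  x0 <- as.numeric(structure$atoms[i, c("x", "y", "z")])
  n <- length(structure$symops)
  img <- matrix(0, n, 3)
  for (s in seq_len(n)) img[s, ] <- apply_symop(structure$symops[[s]], x0) %% 1
  # duplicate collapse by minimum-image fractional distance
  group <- integer(n)
  reps <- list()
  for (s in seq_len(n)) {
    hit <- 0L
    for (g in seq_along(reps)) {
      dd <- (img[s, ] - reps[[g]])
      dd <- dd - round(dd)
      if (max(abs(dd)) < tol) {
        hit <- g; break
      }
    }
    if (hit == 0L) { reps[[length(reps) + 1L]] <- img[s, ]; hit <- length(reps) }
    group[s] <- hit
  }
  n_unique <- length(reps)
  list(
    images = tibble::tibble(symop = seq_len(n),
                            x = img[, 1], y = img[, 2], z = img[, 3],
                            image_group = group),
    n_unique = n_unique,
    multiplicity_factor = n_unique / n
  )
}

#' Equivalent isotropic displacement parameter
#'
#' \eqn{U_{eq}} is one third of the trace of the Cartesianized displacement
#' tensor; for isotropic atoms it equals \eqn{U_{iso}}.
#'
#' @param structure A [crystal_structure()].
#' @return Tibble with `label`, `element`, `adp_type` and `u_eq` (Angstrom^2).
#' @export
u_eq <- function(structure) {
  stopifnot(inherits(structure, "crystal_structure"))
  at <- structure$atoms
  ueq <- numeric(nrow(at))
  type <- character(nrow(at))
  for (i in seq_len(nrow(at))) {
    if (atom_is_aniso(at[i, ])) {
      ueq[i] <- sum(diag(u_cif_to_cart(structure$cell, atom_u_matrix(at[i, ])))) / 3
      type[i] <- "aniso"
    } else {
      ueq[i] <- at$u_iso[i]
      type[i] <- "iso"
    }
  }
  tibble::tibble(label = at$label, element = at$element, adp_type = type, u_eq = ueq)
}

# minimum-image Cartesian distance between two fractional positions
frac_distance <- function(cell, xa, xb) {
  d <- xa - xb
  d <- d - round(d)
  sqrt(sum((cell$frac2cart %*% d)^2))
}
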