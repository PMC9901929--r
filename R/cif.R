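#' Parse a small-molecule CIF document
#'
#' Reads the core-dictionary subset used throughout the package: cell
#' parameters, explicit symmetry operators
#' (`_symmetry_equiv_pos_as_xyz` / `_space_group_symop_operation_xyz`),
#' the `_atom_site` loop (with occupancy and `_atom_site_disorder_group`)
#' and the `_atom_site_aniso` loop. Anisotropic entries override `U_iso`.
#' Values may carry standard uncertainties in parentheses; these are
#' stripped.
#'
#' @param text CIF document as a single string or character vector of lines.
#' @return A [crystal_structure()].
#' @export
parse_cif <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\r$", "", lines)
  toks <- cif_tokenize(lines)
  items <- toks$items
  loops <- toks$loops

  need_cell <- c("_cell_length_a", "_cell_length_b", "_cell_length_c",
                 "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma")
  miss <- setdiff(need_cell, names(items))
  if (length(miss)) stop("parse_cif: missing cell item(s): ", paste(miss, collapse = ", "))
  cv <- vapply(items[need_cell], cif_number, 0)
  cell <- unit_cell(cv[1], cv[2], cv[3], cv[4], cv[5], cv[6])

  sym_tags <- c("_symmetry_equiv_pos_as_xyz", "_space_group_symop_operation_xyz")
  symxyz <- NULL
  for (lp in loops) {
    hit <- intersect(sym_tags, names(lp))
    if (length(hit)) symxyz <- lp[[hit[1]]]
  }
  if (is.null(symxyz)) {
    # accept a non-loop single operator item
    hit <- intersect(sym_tags, names(items))
    if (length(hit)) symxyz <- items[[hit[1]]]
  }
  if (is.null(symxyz)) symxyz <- "x,y,z"
  symops <- lapply(gsub("'", "", symxyz), parse_symop)

  site <- NULL
  aniso <- NULL
  for (lp in loops) {
    if ("_atom_site_label" %in% names(lp) && !"_atom_site_aniso_label" %in% names(lp)) site <- lp
    if ("_atom_site_aniso_label" %in% names(lp)) aniso <- lp
  }
  if (is.null(site)) stop("parse_cif: missing _atom_site loop")

  n <- length(site[["_atom_site_label"]])
  get_col <- function(tag, default) {
    if (tag %in% names(site)) site[[tag]] else rep(default, n)
  }
  num_col <- function(tag, default) {
    unname(vapply(get_col(tag, default), cif_number, 0))
  }
  atoms <- tibble::tibble(
    label = unname(site[["_atom_site_label"]]),
    element = unname(get_col("_atom_site_type_symbol", NA_character_)),
    x = num_col("_atom_site_fract_x", "0"),
    y = num_col("_atom_site_fract_y", "0"),
    z = num_col("_atom_site_fract_z", "0"),
    occ = num_col("_atom_site_occupancy", "1"),
    u_iso = num_col("_atom_site_U_iso_or_equiv", "0.02"),
    part = unname(vapply(get_col("_atom_site_disorder_group", "0"), function(v) {
      if (v %in% c(".", "?")) 0L else as.integer(cif_number(v))
    }, 0L))
  )
  if (all(is.na(atoms$element))) {
    atoms$element <- gsub("[0-9].*$", "", atoms$label)
  }
  for (cn in c("u11", "u22", "u33", "u12", "u13", "u23")) atoms[[cn]] <- NA_real_

  if (!is.null(aniso)) {
    lab <- aniso[["_atom_site_aniso_label"]]
    map <- c(u11 = "_atom_site_aniso_U_11", u22 = "_atom_site_aniso_U_22",
             u33 = "_atom_site_aniso_U_33", u12 = "_atom_site_aniso_U_12",
             u13 = "_atom_site_aniso_U_13", u23 = "_atom_site_aniso_U_23")
    for (j in seq_along(lab)) {
      i <- match(lab[j], atoms$label)
      if (is.na(i)) stop("parse_cif: aniso entry for unknown atom ", lab[j])
      for (cn in names(map)) atoms[[cn]][i] <- cif_number(aniso[[map[cn]]][j])
      atoms$u_iso[i] <- NA_real_   # the aniso tensor overrides U_iso
    }
  }

  chg <- if ("_chemical_formula_charge" %in% names(items)) {
    as.integer(cif_number(items[["_chemical_formula_charge"]]))
  } else 0L
  crystal_structure(cell, symops, atoms, formula_charge = chg)
}

#' Write a crystal structure as a CIF document
#'
#' Emits the same subset [parse_cif()] reads, plus (optionally) refinement
#' statistics under the standard `_refine_ls_*` / `_refine_diff_density_*`
#' data names. R factors are written as fractions to 4 decimals.
#'
#' @param structure A [crystal_structure()].
#' @param stats Optional statistics block (see [r_factors()]); a list with
#'   any of `r1_gt`, `r1_all`, `wr2_all`, `goof`, `peak`, `hole` (R factors
#'   in percent, densities in e/Angstrom^3).
#' @param data_name CIF data block name.
#' @return Character scalar: the CIF document.
#' @export
write_cif <- function(structure, stats = NULL, data_name = "taamkit") {
  stopifnot(inherits(structure, "crystal_structure"))
  cl <- structure$cell
  out <- c(
    paste0("data_", data_name),
    sprintf("_cell_length_a    %.6f", cl$a),
    sprintf("_cell_length_b    %.6f", cl$b),
    sprintf("_cell_length_c    %.6f", cl$c),
    sprintf("_cell_angle_alpha %.6f", cl$alpha),
    sprintf("_cell_angle_beta  %.6f", cl$beta),
    sprintf("_cell_angle_gamma %.6f", cl$gamma),
    sprintf("_cell_volume      %.6f", cl$volume),
    sprintf("_chemical_formula_charge %d", structure$formula_charge),
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    vapply(structure$symops, function(s) paste0("  '", symop_to_xyz(s), "'"), "")
  )
  if (!is.null(stats)) {
    fmt <- function(tag, v, scale = 1) {
      if (!is.null(v) && is.finite(v)) sprintf("%s %.4f", tag, v * scale) else character(0)
    }
    out <- c(out,
      fmt("_refine_ls_R_factor_gt", stats$r1_gt, 0.01),
      fmt("_refine_ls_R_factor_all", stats$r1_all, 0.01),
      fmt("_refine_ls_wR_factor_ref", stats$wr2_all, 0.01),
      fmt("_refine_ls_goodness_of_fit_ref", stats$goof),
      fmt("_refine_diff_density_max", stats$peak),
      fmt("_refine_diff_density_min", stats$hole))
  }
  at <- structure$atoms
  u_print <- ifelse(is.finite(at$u_iso), at$u_iso, u_eq(structure)$u_eq)
  out <- c(out,
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy",
    "_atom_site_U_iso_or_equiv",
    "_atom_site_disorder_group",
    sprintf("%s %s %.8f %.8f %.8f %.6f %.6f %d",
            at$label, at$element, at$x, at$y, at$z, at$occ, u_print, at$part))
  ani <- at[vapply(seq_len(nrow(at)), function(i) atom_is_aniso(at[i, ]), TRUE), ]
  if (nrow(ani)) {
    out <- c(out,
      "loop_",
      "_atom_site_aniso_label",
      "_atom_site_aniso_U_11",
      "_atom_site_aniso_U_22",
      "_atom_site_aniso_U_33",
      "_atom_site_aniso_U_12",
      "_atom_site_aniso_U_13",
      "_atom_site_aniso_U_23",
      sprintf("%s %.8f %.8f %.8f %.8f %.8f %.8f",
              ani$label, ani$u11, ani$u22, ani$u33, ani$u12, ani$u13, ani$u23))
  }
  paste(c(out, ""), collapse = "\n")
}

# --- CIF lexer helpers -------------------------------------------------------

# strips an esd suffix "(..)" and converts to numeric
cif_number <- function(v) {
  v <- sub("\\([0-9]+\\)$", "", v)
  if (v %in% c(".", "?")) return(NA_real_)
  as.numeric(v)
}

cif_split_fields <- function(line) {
  # quoted or bare fields
  m <- gregexpr("'[^']*'|\"[^\"]*\"|[^[:space:]]+", line)
  f <- regmatches(line, m)[[1]]
  gsub("^['\"]|['\"]$", "", f)
}

cif_tokenize <- function(lines) {
  items <- list()
  loops <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, "data_")) { i <- i + 1L; next }
    if (tolower(ln) == "loop_") {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && grepl("^_", trimws(lines[i]))) {
        tags <- c(tags, trimws(lines[i])); i <- i + 1L
      }
      vals <- character(0)
      while (i <= n) {
        l2 <- trimws(lines[i])
        if (!nzchar(l2) || grepl("^(_|loop_|data_|#)", l2, ignore.case = TRUE)) break
        vals <- c(vals, cif_split_fields(l2)); i <- i + 1L
      }
      if (length(tags)) {
        if (length(vals) %% length(tags) != 0) {
          stop("parse_cif: loop with tags ", paste(tags, collapse = ","),
               " has a ragged value list")
        }
        m <- matrix(vals, ncol = length(tags), byrow = TRUE)
        lp <- stats::setNames(lapply(seq_along(tags), function(j) m[, j]), tags)
        loops[[length(loops) + 1L]] <- lp
      }
    } else if (startsWith(ln, "_")) {
      f <- cif_split_fields(ln)
      if (length(f) >= 2) items[[f[1]]] <- paste(f[-1], collapse = " ")
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  list(items = items, loops = loops)
}
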