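#' Parse a transferable pseudoatom bank
#'
#' Reads the package's plain-text bank dialect: a version header line
#' `TAAMBANK 1.0`, `#` comments, and one keyed block per atom type:
#'
#' ```
#' TYPE O_w
#' ELEMENT O
#' NEIGHBORS H:0 H:0        # element:heavy-degree tokens; * wildcard; none; any
#' RING false               # true | false | any
#' AXES Z=NMEAN X=N1        # roles N1, N2, NMEAN, NN1; or AXES none
#' RADIAL CORE c n zeta ; c n zeta ...
#' RADIAL VALENCE c n zeta
#' RADIAL DEF l c n zeta    # one line per deformation order used
#' POP NCORE 2 PC 2 PV 6.2 KAPPA 0.98 KPRIME 1 1 1 1 1
#' PLM 1 0 0.02             # l m value, repeated
#' END
#' ```
#'
#' Core and valence radial coefficients must already integrate to `NCORE`
#' and 1 electron respectively (checked at load, 1e-6); deformation radials
#' are normalized internally to unit radial integral.
#'
#' @param text Bank document (single string or lines).
#' @return A `taam_bank`: list with `version` and `types` (named list of
#'   entries; each entry holds `type_id`, `element`, `signature`, `ring`,
#'   `axes`, and `params`, a [pseudoatom_parameters()]).
#' @export
parse_bank <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("#.*$", "", sub("\r$", "", lines))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !grepl("^TAAMBANK", lines[1])) {
    stop("parse_bank: missing 'TAAMBANK <version>' header")
  }
  version <- sub("^TAAMBANK\\s+", "", lines[1])
  lines <- lines[-1]

  types <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "TYPE ")) stop("parse_bank: expected TYPE, got '", lines[i], "'")
    blk <- character(0)
    tid <- trimws(sub("^TYPE", "", lines[i]))
    i <- i + 1L
    while (i <= length(lines) && lines[i] != "END") {
      blk <- c(blk, lines[i]); i <- i + 1L
    }
    if (i > length(lines)) stop("parse_bank: unterminated block for type ", tid)
    i <- i + 1L
    if (tid %in% names(types)) stop("parse_bank: duplicate type_id ", tid)
    types[[tid]] <- parse_bank_block(tid, blk)
  }
  structure(list(version = version, types = types), class = "taam_bank")
}

parse_bank_block <- function(tid, blk) {
  take1 <- function(key, required = TRUE) {
    hit <- blk[startsWith(blk, paste0(key, " ")) | blk == key]
    if (!length(hit)) {
      if (required) stop("parse_bank: type ", tid, " lacks ", key)
      return(NULL)
    }
    trimws(sub(paste0("^", key), "", hit[1]))
  }
  element <- take1("ELEMENT")
  sig_raw <- take1("NEIGHBORS")
  signature <- if (sig_raw %in% c("none", "")) character(0)
    else if (sig_raw == "any") "any"
    else sort(strsplit(sig_raw, "[[:space:],]+")[[1]])
  ring <- take1("RING")
  if (!ring %in% c("true", "false", "any")) stop("parse_bank: type ", tid, ": RING must be true/false/any")
  ax_raw <- take1("AXES")
  axes <- if (ax_raw == "none") NULL else {
    kv <- strsplit(ax_raw, "[[:space:]]+")[[1]]
    ax <- list()
    for (t in kv) {
      p <- strsplit(t, "=", fixed = TRUE)[[1]]
      if (length(p) != 2 || !p[1] %in% c("Z", "X") || !p[2] %in% c("N1", "N2", "NMEAN", "NN1")) {
        stop("parse_bank: type ", tid, ": bad AXES token '", t, "'")
      }
      ax[[p[1]]] <- p[2]
    }
    if (is.null(ax$Z) || is.null(ax$X)) stop("parse_bank: type ", tid, ": AXES needs Z= and X=")
    ax
  }

  parse_terms <- function(s) {
    if (s == "none") return(list())
    lapply(strsplit(s, ";", fixed = TRUE)[[1]], function(chunk) {
      v <- as.numeric(strsplit(trimws(chunk), "[[:space:]]+")[[1]])
      if (length(v) != 3 || any(is.na(v))) stop("parse_bank: type ", tid, ": bad radial term '", chunk, "'")
      slater_term(v[1], v[2], v[3])
    })
  }
  core <- parse_terms(take1("RADIAL CORE"))
  valence <- parse_terms(take1("RADIAL VALENCE"))
  defr <- vector("list", 5)
  for (ln in blk[startsWith(blk, "RADIAL DEF ")]) {
    v <- as.numeric(strsplit(trimws(sub("^RADIAL DEF", "", ln)), "[[:space:]]+")[[1]])
    if (length(v) != 4 || any(is.na(v))) stop("parse_bank: type ", tid, ": bad RADIAL DEF line")
    defr[[v[1] + 1]] <- slater_term(v[2], v[3], v[4])
  }
  pop_raw <- strsplit(take1("POP"), "[[:space:]]+")[[1]]
  pop <- list()
  j <- 1L
  while (j <= length(pop_raw)) {
    key <- pop_raw[j]
    nval <- if (key == "KPRIME") 5L else 1L
    pop[[key]] <- as.numeric(pop_raw[(j + 1):(j + nval)])
    j <- j + 1L + nval
  }
  for (k in c("NCORE", "PC", "PV", "KAPPA", "KPRIME")) {
    if (is.null(pop[[k]])) stop("parse_bank: type ", tid, ": POP lacks ", k)
  }
  plm <- empty_plm()
  for (ln in blk[startsWith(blk, "PLM ")]) {
    v <- as.numeric(strsplit(trimws(sub("^PLM", "", ln)), "[[:space:]]+")[[1]])
    if (length(v) != 3 || any(is.na(v))) stop("parse_bank: type ", tid, ": bad PLM line")
    l <- v[1]; m <- v[2]
    if (l < 0 || l > 4 || abs(m) > l) stop("parse_bank: type ", tid, ": PLM out of range")
    plm[[l + 1]][m + l + 1] <- v[3]
  }
  params <- tryCatch(
    pseudoatom_parameters(element, core, valence, n_core = pop$NCORE,
                          p_c = pop$PC, p_v = pop$PV, kappa = pop$KAPPA,
                          kappa_prime = pop$KPRIME, deformation = defr, p_lm = plm),
    error = function(e) stop("parse_bank: type ", tid, ": ", conditionMessage(e)))
  list(type_id = tid, element = element, signature = signature,
       ring = ring, axes = axes, params = params)
}

#' Serialize a pseudoatom bank
#'
#' Inverse of [parse_bank()]; coefficients are printed with 12 significant
#' digits so a write/parse round trip is lossless at validation tolerance.
#'
#' @param bank A `taam_bank`.
#' @return Character scalar.
#' @export
write_bank <- function(bank) {
  out <- paste("TAAMBANK", bank$version)
  fmt <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)
  terms_str <- function(terms) {
    if (!length(terms)) return("none")
    paste(vapply(terms, function(tm) paste(fmt(tm$c), tm$n, fmt(tm$zeta)), ""),
          collapse = " ; ")
  }
  for (e in bank$types) {
    p <- e$params
    out <- c(out,
      paste("TYPE", e$type_id),
      paste("ELEMENT", e$element),
      paste("NEIGHBORS", if (!length(e$signature)) "none" else paste(e$signature, collapse = " ")),
      paste("RING", e$ring),
      if (is.null(e$axes)) "AXES none" else paste0("AXES Z=", e$axes$Z, " X=", e$axes$X),
      paste("RADIAL CORE", terms_str(p$core)),
      paste("RADIAL VALENCE", terms_str(p$valence)),
      unlist(lapply(0:4, function(l) {
        tm <- p$deformation[[l + 1]]
        if (is.null(tm)) character(0)
        else paste("RADIAL DEF", l, fmt(tm$c), tm$n, fmt(tm$zeta))
      })),
      paste("POP NCORE", fmt(p$n_core), "PC", fmt(p$p_c), "PV", fmt(p$p_v),
            "KAPPA", fmt(p$kappa), "KPRIME", paste(fmt(p$kappa_prime), collapse = " ")),
      unlist(lapply(0:4, function(l) {
        plm <- p$p_lm[[l + 1]]
        idx <- which(plm != 0)
        if (!length(idx)) return(character(0))
        paste("PLM", l, idx - l - 1, fmt(plm[idx]))
      })),
      "END")
  }
  paste(c(out, ""), collapse = "\n")
}

#' Assign bank atom types on the bond graph
#'
#' Deterministic most-specific-match typing. An atom's signature is the
#' sorted multiset of `element:heavy-degree` tokens over its bonded
#' neighbours (heavy-degree = the neighbour's count of non-H neighbours),
#' plus its own ring membership (rings of size 3-7). Matching tiers:
#' exact signature and ring flag first; then signatures with wildcard `*`
#' degrees; then an element-only fallback entry (`NEIGHBORS any`) if the
#' bank provides one; otherwise `UNMATCHED`. Ties break on sorted type_id,
#' so the result is independent of atom and bank ordering.
#'
#' @param structure A [crystal_structure()].
#' @param graph A [build_bond_graph()] result.
#' @param bank A [parse_bank()] result.
#' @return A `type_assignment`: tibble with `label`, `element`, `signature`,
#'   `ring`, `type_id` (`"UNMATCHED"` when no entry applies), plus the bank
#'   in attribute `bank` and per-atom transferred parameters in attribute
#'   `params` (named list; `NULL` for unmatched atoms).
#' @export
assign_types <- function(structure, graph, bank) {
  at <- structure$atoms
  el <- stats::setNames(at$element, at$label)
  hdeg <- heavy_degree(graph, structure)
  sig_of <- function(lb) {
    nbs <- effective_neighbors(graph, structure, lb)
    if (!length(nbs)) return(character(0))
    unname(sort(vapply(nbs, function(nb) paste0(el[nb], ":", hdeg[nb]), "")))
  }
  res_type <- character(nrow(at))
  res_sig <- character(nrow(at))
  res_ring <- at$label %in% graph$ring_atoms
  params <- stats::setNames(vector("list", nrow(at)), at$label)
  type_ids <- sort(names(bank$types))

  for (i in seq_len(nrow(at))) {
    lb <- at$label[i]
    sig <- sig_of(lb)
    res_sig[i] <- paste(sig, collapse = ",")
    best_tier <- Inf; best_id <- "UNMATCHED"
    for (tid in type_ids) {
      e <- bank$types[[tid]]
      if (e$element != at$element[i]) next
      tier <- signature_match_tier(sig, res_ring[i], e)
      if (is.na(tier)) next
      if (tier < best_tier) { best_tier <- tier; best_id <- tid }
    }
    res_type[i] <- best_id
    if (best_id != "UNMATCHED") params[[lb]] <- bank$types[[best_id]]$params
  }
  out <- tibble::tibble(label = at$label, element = at$element,
                        signature = res_sig, ring = res_ring, type_id = res_type)
  attr(out, "bank") <- bank
  attr(out, "params") <- params
  class(out) <- c("type_assignment", class(out))
  out
}

# tier 1 = exact signature + ring, 2 = wildcard degrees, 3 = element fallback;
# NA when the entry does not match
signature_match_tier <- function(sig, ring, entry) {
  ring_ok <- entry$ring == "any" || (entry$ring == "true") == ring
  if (!ring_ok) return(NA_real_)
  if (identical(entry$signature, "any")) return(3)
  if (length(entry$signature) != length(sig)) return(NA_real_)
  if (identical(unname(sort(entry$signature)), unname(sig))) return(1)
  # wildcard matching: greedy — consume exact tokens, then wildcards by element
  pool <- sig
  wild <- character(0)
  for (tok in entry$signature) {
    if (grepl(":\\*$", tok)) { wild <- c(wild, sub(":\\*$", "", tok)); next }
    j <- match(tok, pool)
    if (is.na(j)) return(NA_real_)
    pool <- pool[-j]
  }
  pool_el <- sub(":.*$", "", pool)
  if (length(wild) != length(pool)) return(NA_real_)
  if (!identical(sort(wild), sort(pool_el))) return(NA_real_)
  2
}

#' Rescale valence populations to a target charge
#'
#' Multiplies every matched atom's \eqn{P_v} by one factor per charge
#' group so that the group's pseudoatom electron count satisfies
#' \eqn{\sum_j (P_c + P_v + P_{00})_j - \sum_j Z_j = -q}. The default is a
#' single group spanning all matched atoms with
#' `q = structure$formula_charge`; for multi-moiety crystals pass explicit
#' groups (e.g. metal +1, organic anion -1). Unmatched atoms are excluded
#' and reported via a warning.
#'
#' @param assignment A [assign_types()] result.
#' @param structure The matching [crystal_structure()].
#' @param groups Optional list of `list(labels =, charge =)`.
#' @return The assignment with rescaled parameters; per-group factors in
#'   attribute `electroneutrality_factors`.
#' @export
electroneutrality_rescale <- function(assignment, structure, groups = NULL) {
  params <- attr(assignment, "params")
  matched <- assignment$label[assignment$type_id != "UNMATCHED"]
  un <- setdiff(assignment$label, matched)
  if (length(un)) {
    warning("electroneutrality_rescale: unmatched atom(s) excluded: ",
            paste(un, collapse = ", "))
  }
  if (is.null(groups)) {
    groups <- list(all = list(labels = matched, charge = structure$formula_charge))
  }
  Z <- element_numbers()
  el <- stats::setNames(structure$atoms$element, structure$atoms$label)
  factors <- numeric(0)
  for (gname in names(groups)) {
    g <- groups[[gname]]
    labs <- intersect(g$labels, matched)
    if (!length(labs)) next
    sum_pc <- sum(vapply(labs, function(lb) params[[lb]]$p_c, 0))
    sum_pv <- sum(vapply(labs, function(lb) params[[lb]]$p_v, 0))
    sum_p00 <- sum(vapply(labs, function(lb) params[[lb]]$p_lm[[1]][1], 0))
    sum_z <- sum(Z[el[labs]])
    target_electrons <- sum_z - g$charge
    need_pv <- target_electrons - sum_pc - sum_p00
    if (abs(sum_pv) < 1e-12) {
      if (abs(need_pv) > 1e-9) {
        stop("electroneutrality_rescale: group ", gname,
             " has zero total P_v but needs ", signif(need_pv, 6), " valence electrons")
      }
      factors[gname] <- 1
      next
    }
    f <- need_pv / sum_pv
    factors[gname] <- f
    for (lb in labs) params[[lb]]$p_v <- params[[lb]]$p_v * f
  }
  attr(assignment, "params") <- params
  attr(assignment, "electroneutrality_factors") <- factors
  assignment
}

#' Bind axis recipes to concrete neighbours and build local frames
#'
#' Resolves each typed atom's axis roles against the bond graph
#' (`N1` = highest-priority neighbour — heaviest element, ties by label
#' sort; `N2` = second; `NMEAN` = mean neighbour direction; `NN1` =
#' heaviest atom bonded to N1 other than the atom itself). When a recipe
#' asks for `N2` but only one neighbour exists, the axis falls back to
#' `NN1`. Directions are Cartesian minimum-image vectors. Atoms whose type
#' has no axis recipe (or unmatched atoms) get the identity frame.
#'
#' @param assignment A [assign_types()] result.
#' @param graph The bond graph used for the assignment.
#' @param structure The structure.
#' @return Named list label -> `local_frame`.
#' @export
bind_axes <- function(assignment, graph, structure) {
  at <- structure$atoms
  Z <- element_numbers()
  el <- stats::setNames(at$element, at$label)
  pos <- stats::setNames(lapply(seq_len(nrow(at)), function(i) as.numeric(at[i, c("x", "y", "z")])),
                         at$label)
  M <- structure$cell$frac2cart
  # minimum-image Cartesian direction from a to b
  dir_to <- function(a, b) {
    d <- pos[[b]] - pos[[a]]
    d <- d - round(d)
    as.numeric(M %*% d)
  }
  ranked_neighbors <- function(lb) {
    nbs <- effective_neighbors(graph, structure, lb)
    if (!length(nbs)) return(character(0))
    nbs[order(-Z[el[nbs]], nbs)]
  }
  bank <- attr(assignment, "bank")
  frames <- stats::setNames(vector("list", nrow(at)), at$label)
  for (i in seq_len(nrow(at))) {
    lb <- at$label[i]
    tid <- assignment$type_id[i]
    axes <- if (tid == "UNMATCHED") NULL else bank$types[[tid]]$axes
    if (is.null(axes)) { frames[[lb]] <- identity_frame(); next }
    nbs <- ranked_neighbors(lb)
    resolve <- function(role) {
      switch(role,
        N1 = {
          if (!length(nbs)) stop("bind_axes: atom ", lb, " has no neighbour for role N1")
          dir_to(lb, nbs[1])
        },
        N2 = {
          if (length(nbs) >= 2) dir_to(lb, nbs[2]) else resolve("NN1")
        },
        NMEAN = {
          if (!length(nbs)) stop("bind_axes: atom ", lb, " has no neighbours for role NMEAN")
          vs <- vapply(nbs, function(nb) {
            v <- dir_to(lb, nb)
            v / sqrt(sum(v^2))   # unit directions so bond lengths do not bias
          }, numeric(3))
          if (is.null(dim(vs))) vs <- matrix(vs, nrow = 3)
          as.numeric(rowSums(vs))
        },
        NN1 = {
          if (!length(nbs)) stop("bind_axes: atom ", lb, " has no neighbour for role NN1")
          n1 <- nbs[1]
          cand <- setdiff(ranked_neighbors(n1), lb)
          if (!length(cand)) stop("bind_axes: atom ", lb, ": neighbour ", n1,
                                  " has no further neighbour for role NN1")
          dir_to(lb, cand[1])
        },
        stop("bind_axes: unknown role ", role))
    }
    frames[[lb]] <- tryCatch(
      local_frame_from_vectors(resolve(axes$Z), resolve(axes$X), label = lb),
      error = function(e) stop("bind_axes: ", conditionMessage(e)))
  }
  frames
}
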