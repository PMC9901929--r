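#' In-memory form-factor table
#'
#' The twin of a .tsc file: one complex scattering factor per (atom label,
#' hkl) pair.
#'
#' @param labels Character vector of scatterer labels (order preserved).
#' @param hkl Integer n x 3 matrix of Miller indices (no duplicates).
#' @param f Complex n_hkl x n_labels matrix.
#' @param title Header title.
#' @param symm Header symmetry note.
#' @param sources Named character vector label -> source model note.
#' @param extra_header Named character vector of verbatim extra header keys.
#' @return A `tsc_table`.
#' @export
tsc_table <- function(labels, hkl, f, title = "taamkit form factors",
                      symm = "expanded", sources = NULL, extra_header = NULL) {
  hkl <- to_hkl_matrix(hkl)
  storage.mode(hkl) <- "integer"
  f <- as.matrix(f)
  if (nrow(f) != nrow(hkl) || ncol(f) != length(labels)) {
    stop("tsc_table: f must be n_hkl x n_labels")
  }
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  if (anyDuplicated(key)) stop("tsc_table: duplicate hkl rows")
  colnames(f) <- labels
  if (is.null(sources)) sources <- stats::setNames(rep("unspecified", length(labels)), labels)
  structure(list(labels = labels, hkl = hkl, f = f,
                 header = list(title = title, symm = symm,
                               sources = sources, extra = extra_header)),
            class = "tsc_table")
}

#' @export
print.tsc_table <- function(x, ...) {
  cat(sprintf("<tsc_table> %d scatterer(s) x %d hkl\n", length(x$labels), nrow(x$hkl)))
  cat(" sources:", paste(unique(x$header$sources), collapse = ", "), "\n")
  invisible(x)
}

# row indices of requested hkl in the table (error when absent)
tsc_lookup <- function(table, hkl) {
  H <- to_hkl_matrix(hkl)
  key <- paste(table$hkl[, 1], table$hkl[, 2], table$hkl[, 3])
  want <- paste(H[, 1], H[, 2], H[, 3])
  idx <- match(want, key)
  if (anyNA(idx)) {
    stop("form-factor table lacks hkl ", want[which(is.na(idx))[1]])
  }
  idx
}

#' Write a .tsc document
#'
#' NoSpherA2-style text dialect: `TITLE:`, `SYMM:`, optional extra keys,
#' `SCATTERERS:` (space-separated labels), `DATA:`, then one row per hkl
#' `h k l re,im re,im ...` in scatterer order, 8 significant digits.
#'
#' @param table A [tsc_table()].
#' @return Character scalar.
#' @export
write_tsc <- function(table) {
  hdr <- c(paste0("TITLE: ", table$header$title),
           paste0("SYMM: ", table$header$symm))
  if (!is.null(table$header$sources)) {
    hdr <- c(hdr, paste0("SOURCES: ",
                         paste(paste0(names(table$header$sources), "=",
                                      table$header$sources), collapse = " ")))
  }
  for (k in names(table$header$extra)) {
    hdr <- c(hdr, paste0(k, ": ", table$header$extra[[k]]))
  }
  hdr <- c(hdr, paste0("SCATTERERS: ", paste(table$labels, collapse = " ")), "DATA:")
  fmt <- function(z) paste0(trimws(formatC(Re(z), format = "g", digits = 8)), ",",
                            trimws(formatC(Im(z), format = "g", digits = 8)))
  rows <- vapply(seq_len(nrow(table$hkl)), function(i) {
    paste(c(table$hkl[i, 1], table$hkl[i, 2], table$hkl[i, 3],
            fmt(table$f[i, ])), collapse = " ")
  }, "")
  paste(c(hdr, rows, ""), collapse = "\n")
}

#' Read a .tsc document
#'
#' Accepts the dialect written by [write_tsc()] leniently: required keys
#' are `SCATTERERS:` and `DATA:`; unknown header keys are preserved
#' verbatim. No hkl completeness is assumed beyond the declared rows.
#'
#' @param text .tsc document (single string or lines).
#' @return A [tsc_table()].
#' @export
read_tsc <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\r$", "", lines)
  idata <- which(trimws(toupper(lines)) == "DATA:")
  if (!length(idata)) stop("read_tsc: missing DATA: header line")
  idata <- idata[1]
  hdr <- lines[seq_len(idata - 1)]
  kv <- list()
  for (ln in hdr) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+):[[:space:]]*(.*)$", ln))[[1]]
    if (length(m) == 3) kv[[toupper(m[2])]] <- m[3]
  }
  if (is.null(kv$SCATTERERS)) stop("read_tsc: missing SCATTERERS: header line")
  labels <- strsplit(trimws(kv$SCATTERERS), "[[:space:]]+")[[1]]
  sources <- NULL
  if (!is.null(kv$SOURCES)) {
    toks <- strsplit(trimws(kv$SOURCES), "[[:space:]]+")[[1]]
    pv <- strsplit(toks, "=", fixed = TRUE)
    sources <- stats::setNames(vapply(pv, `[`, "", 2), vapply(pv, `[`, "", 1))
  }
  extra <- kv[setdiff(names(kv), c("TITLE", "SYMM", "SCATTERERS", "SOURCES"))]

  body <- trimws(lines[(idata + 1):length(lines)])
  body <- body[nzchar(body)]
  n <- length(body)
  hklm <- matrix(0L, n, 3)
  fm <- matrix(complex(1), n, length(labels))
  for (i in seq_len(n)) {
    fields <- strsplit(body[i], "[[:space:]]+")[[1]]
    if (length(fields) != 3 + length(labels)) {
      stop("read_tsc: data line ", i, " has ", length(fields),
           " fields, expected ", 3 + length(labels))
    }
    hklm[i, ] <- as.integer(fields[1:3])
    z <- strsplit(fields[-(1:3)], ",", fixed = TRUE)
    fm[i, ] <- complex(real = as.numeric(vapply(z, `[`, "", 1)),
                       imaginary = as.numeric(vapply(z, `[`, "", 2)))
  }
  key <- paste(hklm[, 1], hklm[, 2], hklm[, 3])
  if (anyDuplicated(key)) stop("read_tsc: duplicate hkl ", key[duplicated(key)][1])
  tsc_table(labels, hklm, fm,
            title = if (is.null(kv$TITLE)) "" else kv$TITLE,
            symm = if (is.null(kv$SYMM)) "" else kv$SYMM,
            sources = sources,
            extra_header = if (length(extra)) unlist(extra) else NULL)
}

#' Merge form-factor tables
#'
#' Column-wise union over scatterers; all tables must share an identical
#' hkl list (in any order). Duplicate labels either raise an error
#' (`conflict = "error"`) or are resolved by list priority
#' (`conflict = "priority"`, earlier tables win; the decision is recorded
#' in the header sources).
#'
#' @param tables List of [tsc_table()] objects.
#' @param conflict `"error"` or `"priority"`.
#' @return A merged [tsc_table()].
#' @export
merge_tsc <- function(tables, conflict = c("error", "priority")) {
  conflict <- match.arg(conflict)
  stopifnot(length(tables) >= 1)
  ref <- tables[[1]]
  ref_key <- paste(ref$hkl[, 1], ref$hkl[, 2], ref$hkl[, 3])
  labels <- character(0)
  fcols <- list()
  sources <- character(0)
  for (ti in seq_along(tables)) {
    tb <- tables[[ti]]
    key <- paste(tb$hkl[, 1], tb$hkl[, 2], tb$hkl[, 3])
    if (length(key) != length(ref_key) || !setequal(key, ref_key)) {
      diffh <- c(setdiff(key, ref_key), setdiff(ref_key, key))
      stop("merge_tsc: table ", ti, " hkl list differs (first difference: ", diffh[1], ")")
    }
    perm <- match(ref_key, key)
    for (j in seq_along(tb$labels)) {
      lb <- tb$labels[j]
      if (lb %in% labels) {
        if (conflict == "error") stop("merge_tsc: duplicate scatterer label ", lb)
        next  # priority: first table wins
      }
      labels <- c(labels, lb)
      fcols[[lb]] <- tb$f[perm, j]
      sources[lb] <- tb$header$sources[[lb]] %||% "unspecified"
    }
  }
  tsc_table(labels, ref$hkl, do.call(cbind, fcols),
            title = paste0("merged: ", paste(unique(sources), collapse = "+")),
            symm = ref$header$symm, sources = sources)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
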