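#' Parse a SHELX-style hkl reflection file
#'
#' Reads whitespace-separated (or fixed-width HKLF4) lines
#' `h k l F2 sigma`; a `0 0 0` record terminates the list. Duplicate
#' indices are merged by the inverse-variance weighted mean
#' (\eqn{F^2 = \sum F_i^2/\sigma_i^2 / \sum 1/\sigma_i^2},
#' \eqn{\sigma = 1/\sqrt{\sum 1/\sigma_i^2}}). Friedel mates are kept
#' separate.
#'
#' @param text hkl document as a single string or character vector of lines.
#' @param wavelength Wavelength metadata in Angstrom.
#' @return A `reflection_set`: tibble with columns `h`, `k`, `l`, `f2`,
#'   `sig` and attribute `wavelength`.
#' @export
parse_hkl <- function(text, wavelength = 0.71073) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\r$", "", lines)
  h <- k <- l <- f2 <- sig <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(f) < 5) {
      # fixed-width HKLF4: 3I4, 2F8
      raw <- lines[i]
      if (nchar(raw) >= 28) {
        f <- c(substr(raw, 1, 4), substr(raw, 5, 8), substr(raw, 9, 12),
               substr(raw, 13, 20), substr(raw, 21, 28))
        f <- trimws(f)
      } else stop("parse_hkl: line ", i, ": expected 'h k l F2 sigma'")
    }
    hv <- suppressWarnings(as.numeric(f[1:3]))
    if (any(is.na(hv)) || any(hv != round(hv))) {
      stop("parse_hkl: line ", i, ": non-integer Miller indices")
    }
    if (all(hv == 0)) break
    fv <- suppressWarnings(as.numeric(f[4:5]))
    if (any(is.na(fv))) stop("parse_hkl: line ", i, ": unreadable F2/sigma")
    if (fv[2] <= 0) stop("parse_hkl: line ", i, ": sigma must be positive")
    h <- c(h, hv[1]); k <- c(k, hv[2]); l <- c(l, hv[3])
    f2 <- c(f2, fv[1]); sig <- c(sig, fv[2])
  }
  if (length(h) == 0L) warning("parse_hkl: no reflections before terminator")
  refl <- tibble::tibble(h = as.integer(h), k = as.integer(k), l = as.integer(l),
                         f2 = f2, sig = sig)
  refl <- merge_reflections(refl)
  reflection_set(refl, wavelength = wavelength)
}

#' Construct a reflection set
#'
#' @param refl Data frame with columns `h`, `k`, `l`, `f2`, `sig`.
#' @param wavelength Wavelength metadata (Angstrom).
#' @return A `reflection_set` tibble.
#' @export
reflection_set <- function(refl, wavelength = 0.71073) {
  refl <- tibble::as_tibble(refl)
  stopifnot(all(c("h", "k", "l", "f2", "sig") %in% names(refl)))
  if (any(refl$sig <= 0)) stop("reflection_set: sigma must be positive for every reflection")
  key <- paste(refl$h, refl$k, refl$l)
  if (anyDuplicated(key)) stop("reflection_set: duplicate hkl present; merge first")
  attr(refl, "wavelength") <- wavelength
  class(refl) <- c("reflection_set", class(refl))
  refl
}

# inverse-variance weighted merge of duplicate hkl records
merge_reflections <- function(refl) {
  key <- paste(refl$h, refl$k, refl$l)
  if (!anyDuplicated(key)) return(refl)
  refl |>
    dplyr::mutate(w = 1 / .data$sig^2) |>
    dplyr::group_by(.data$h, .data$k, .data$l) |>
    dplyr::summarise(f2 = sum(.data$f2 * .data$w) / sum(.data$w),
                     sig = 1 / sqrt(sum(.data$w)), .groups = "drop")
}

#' Write a reflection set in SHELX HKLF4 layout
#'
#' @param refl A `reflection_set`.
#' @return Character scalar, fixed-format `3I4,2F8.2` lines plus the
#'   `0 0 0` terminator.
#' @export
write_hkl <- function(refl) {
  body <- sprintf("%4d%4d%4d%8.2f%8.2f", refl$h, refl$k, refl$l, refl$f2, refl$sig)
  paste(c(body, sprintf("%4d%4d%4d%8.2f%8.2f", 0L, 0L, 0L, 0, 0), ""), collapse = "\n")
}

#' Enumerate the full reflection sphere to a resolution limit
#'
#' All integer Miller indices (excluding the origin) with
#' \eqn{d \ge d_{min}}.
#'
#' @param cell A [unit_cell()].
#' @param d_min Resolution limit in Angstrom.
#' @return Integer matrix n x 3.
#' @export
hkl_sphere <- function(cell, d_min) {
  stopifnot(d_min > 0)
  smax <- 1 / d_min
  hmax <- ceiling(smax / cell$recip$a_star)
  kmax <- ceiling(smax / cell$recip$b_star)
  lmax <- ceiling(smax / cell$recip$c_star)
  grid <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
  grid <- grid[rowSums(grid != 0) > 0, , drop = FALSE]
  inv_d2 <- rowSums((grid %*% cell$metric_star) * grid)
  grid[inv_d2 <= smax^2 + 1e-12, , drop = FALSE]
}
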