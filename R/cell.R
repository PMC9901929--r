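#' Construct a unit cell
#'
#' Builds a validated unit cell from lengths (\eqn{\AA}) and angles (degrees)
#' and precomputes the direct and reciprocal metric tensors, the
#' fractional-to-Cartesian matrix and the cell volume.
#'
#' The Cartesian frame follows the standard crystallographic convention:
#' \eqn{a} along \eqn{x}, \eqn{b} in the \eqn{xy} plane.
#'
#' @param a,b,c Cell lengths in Angstrom, all positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell`: a list with the input parameters
#'   plus `volume` (\eqn{\AA^3}), `frac2cart` (3x3, Cartesian coordinates =
#'   `frac2cart %*% fractional`), `cart2frac`, `metric` (direct metric tensor
#'   G), `metric_star` (reciprocal metric tensor G*) and `recip` with the
#'   reciprocal cell lengths `a_star`, `b_star`, `c_star`.
#' @examples
#' cl <- unit_cell(10, 10, 10)
#' cl$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop("unit_cell: all cell lengths must be positive and finite")
  }
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180)) {
    stop("unit_cell: all cell angles must lie in (0, 180) degrees")
  }
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  sg <- sin(gamma * pi / 180)
  vol_arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vol_arg <= 0) stop("unit_cell: angles do not define a positive cell volume")
  volume <- a * b * c * sqrt(vol_arg)

  # frac -> cart, a along x, b in the xy plane
  M <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0,     volume / (a * b * sg)
  ), nrow = 3, byrow = TRUE)
  G <- t(M) %*% M
  Gstar <- solve(G)

  out <- list(
    a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
    volume = volume,
    frac2cart = M,
    cart2frac = solve(M),
    metric = G,
    metric_star = Gstar,
    recip = list(
      a_star = sqrt(Gstar[1, 1]),
      b_star = sqrt(Gstar[2, 2]),
      c_star = sqrt(Gstar[3, 3])
    )
  )
  class(out) <- "unit_cell"
  out
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf(
    "<unit_cell> a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f  V=%.3f A^3\n",
    x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume
  ))
  invisible(x)
}

#' Resolution of reflections
#'
#' Interplanar spacing \eqn{d = 1/|h^*|} and \eqn{\sin\theta/\lambda = 1/(2d)}
#' for one or more Miller indices.
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer vector of length 3, or an n x 3 matrix of indices.
#' @return A tibble with columns `h`, `k`, `l`, `d` (Angstrom) and `stol`
#'   (\eqn{\sin\theta/\lambda}, \eqn{\AA^{-1}}).
#' @examples
#' d_spacing(unit_cell(10, 10, 10), c(1, 0, 0))
#' @export
d_spacing <- function(cell, hkl) {
  stopifnot(inherits(cell, "unit_cell"))
  H <- to_hkl_matrix(hkl)
  if (any(rowSums(H != 0) == 0)) {
    stop("d_spacing: (0,0,0) has no associated lattice spacing")
  }
  inv_d2 <- rowSums((H %*% cell$metric_star) * H)
  d <- 1 / sqrt(inv_d2)
  tibble::tibble(h = H[, 1], k = H[, 2], l = H[, 3], d = d, stol = 1 / (2 * d))
}

# hkl input normalization: vector of 3 or n x 3 matrix/data frame
to_hkl_matrix <- function(hkl) {
  if (is.data.frame(hkl)) hkl <- as.matrix(hkl[, c("h", "k", "l")])
  if (is.null(dim(hkl))) {
    if (length(hkl) != 3) stop("hkl must have 3 components")
    hkl <- matrix(hkl, nrow = 1)
  }
  storage.mode(hkl) <- "double"
  hkl
}

# Reciprocal-space Cartesian vector(s) for Miller indices: rows of H %*% B^T
# where B = (M^-1)^T is the reciprocal basis; |h_cart| = 1/d.
hkl_to_cart <- function(cell, hkl) {
  H <- to_hkl_matrix(hkl)
  H %*% cell$cart2frac   # (n x 3) %*% M^-1 : row i = h_i^T M^-1 = (M^-T h)^T
}

# Cartesianization of a CIF U^ij tensor (reciprocal-basis convention):
# U_cart = M N U N M^T with N = diag(a*, b*, c*).
u_cif_to_cart <- function(cell, U) {
  N <- diag(c(cell$recip$a_star, cell$recip$b_star, cell$recip$c_star))
  cell$frac2cart %*% N %*% U %*% N %*% t(cell$frac2cart)
}

# Inverse of u_cif_to_cart
u_cart_to_cif <- function(cell, Ucart) {
  N <- diag(c(cell$recip$a_star, cell$recip$b_star, cell$recip$c_star))
  Minv <- cell$cart2frac
  Ninv <- diag(1 / diag(N))
  Ninv %*% Minv %*% Ucart %*% t(Minv) %*% Ninv
}
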