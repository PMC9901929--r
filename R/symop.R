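#' Parse a symmetry operator from an xyz string
#'
#' Converts operator strings such as `"-x,y+1/2,-z+1/2"` into a rotation
#' matrix and translation vector in the fractional basis. Serialization back
#' to the string form is lossless via [symop_to_xyz()].
#'
#' @param xyz A symmetry operator string, three comma-separated components in
#'   x, y, z with optional rational translations.
#' @return An object of class `symop`: list with `R` (3x3 matrix, det ±1)
#'   and `t` (length-3 translation, reduced mod 1 to [0, 1)).
#' @examples
#' parse_symop("-x,y+1/2,-z+1/2")
#' @export
parse_symop <- function(xyz) {
  parts <- strsplit(gsub("[[:space:]]", "", tolower(xyz)), ",", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("parse_symop: expected three comma-separated components in '", xyz, "'")
  R <- matrix(0, 3, 3)
  t <- numeric(3)
  for (i in 1:3) {
    comp <- parts[i]
    # tokenize into signed terms
    toks <- regmatches(comp, gregexpr("[+-]?[^+-]+", comp))[[1]]
    if (length(toks) == 0) stop("parse_symop: empty component in '", xyz, "'")
    for (tok in toks) {
      sign <- 1
      body <- tok
      if (startsWith(body, "+")) body <- substring(body, 2)
      if (startsWith(body, "-")) { sign <- -1; body <- substring(body, 2) }
      if (body %in% c("x", "y", "z")) {
        j <- match(body, c("x", "y", "z"))
        R[i, j] <- R[i, j] + sign
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        nd <- as.numeric(strsplit(body, "/", fixed = TRUE)[[1]])
        t[i] <- t[i] + sign * nd[1] / nd[2]
      } else if (grepl("^[0-9]*\\.?[0-9]+$", body)) {
        t[i] <- t[i] + sign * as.numeric(body)
      } else if (grepl("^[0-9]*\\.?[0-9]*\\*?[xyz]$", body)) {
        # forms like 2x or 0.5x
        ax <- substring(body, nchar(body))
        coef <- sub("\\*?[xyz]$", "", body)
        j <- match(ax, c("x", "y", "z"))
        R[i, j] <- R[i, j] + sign * as.numeric(coef)
      } else {
        stop("parse_symop: cannot parse term '", tok, "' in '", xyz, "'")
      }
    }
  }
  if (abs(abs(det(R)) - 1) > 1e-9) {
    stop("parse_symop: rotation part of '", xyz, "' has determinant ", det(R))
  }
  op <- list(R = R, t = t %% 1)
  class(op) <- "symop"
  op
}

#' Serialize a symmetry operator to its xyz string
#'
#' @param op A `symop` as returned by [parse_symop()].
#' @return Character scalar, e.g. `"-x,y+1/2,-z+1/2"`.
#' @export
symop_to_xyz <- function(op) {
  stopifnot(inherits(op, "symop"))
  axes <- c("x", "y", "z")
  comps <- character(3)
  for (i in 1:3) {
    s <- ""
    for (j in 1:3) {
      cij <- op$R[i, j]
      if (cij == 0) next
      term <- if (abs(cij) == 1) axes[j] else paste0(format_frac(abs(cij)), axes[j])
      s <- paste0(s, if (cij > 0 && nzchar(s)) "+" else if (cij < 0) "-" else "", term)
    }
    ti <- op$t[i] %% 1
    if (abs(ti) > 1e-9 && abs(ti - 1) > 1e-9) {
      s <- paste0(s, "+", format_frac(ti))
    }
    comps[i] <- s
  }
  paste(comps, collapse = ",")
}

# render a translation as n/d when close to a small rational, else decimal
format_frac <- function(x) {
  for (d in c(2L, 3L, 4L, 6L, 8L, 12L)) {
    n <- round(x * d)
    if (abs(x - n / d) < 1e-9 && n != 0) {
      g <- gcd2(abs(n), d)
      return(paste0(n / g, "/", d / g))
    }
  }
  format(x, digits = 10)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' @export
print.symop <- function(x, ...) {
  cat("<symop>", symop_to_xyz(x), "\n")
  invisible(x)
}

# op application to fractional coordinates (3-vector or 3 x n matrix)
apply_symop <- function(op, x) {
  if (is.null(dim(x))) as.vector(op$R %*% x + op$t) else op$R %*% x + op$t
}

symop_identity <- function() {
  op <- list(R = diag(3), t = c(0, 0, 0))
  class(op) <- "symop"
  op
}

symop_equal <- function(a, b, tol = 1e-9) {
  max(abs(a$R - b$R)) < tol && max(abs((a$t - b$t) %% 1)) < tol
}
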