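#' Crystallographic unit cell
#'
#' Constructs a unit cell from the six standard cell parameters and
#' precomputes the orthogonalization (fractional to Cartesian) and
#' deorthogonalization matrices in the PDB convention (a along x, b in the
#' x-y plane).
#'
#' @param a,b,c Cell edge lengths in Angstrom. Must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell`: a list with the cell parameters,
#'   the 3x3 orthogonalization matrix `orth`, its inverse `frac`, and the
#'   cell volume in cubic Angstrom.
#' @examples
#' cell <- unit_cell(30, 30, 40)
#' frac_to_cart(cell, c(0.5, 0.5, 0.5))
#' @export
unit_cell <- function(a, b = a, c = a, alpha = 90, beta = 90, gamma = 90) {
  if (!all(is.finite(c(a, b, c, alpha, beta, gamma)))) {
    stop("cell parameters must be finite numbers", call. = FALSE)
  }
  if (min(a, b, c) <= 0) stop("cell lengths must be positive", call. = FALSE)
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180)) {
    stop("cell angles must lie in (0, 180) degrees", call. = FALSE)
  }
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) stop("degenerate cell: volume is not positive", call. = FALSE)
  vol <- a * b * c * sqrt(v2)
  orth <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0,      c * sqrt(v2) / sg
  ), nrow = 3, byrow = TRUE)
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         orth = orth, frac = solve(orth), volume = vol),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Convert fractional coordinates to Cartesian
#'
#' @param cell A [unit_cell()].
#' @param x A numeric vector of length 3 or an n x 3 matrix of fractional
#'   coordinates.
#' @return Coordinates in Angstrom, same shape as the input.
#' @export
frac_to_cart <- function(cell, x) {
  x <- coord_matrix(x)
  out <- x %*% t(cell$orth)
  drop_coord(out)
}

#' Convert Cartesian coordinates to fractional
#'
#' @inheritParams frac_to_cart
#' @param x Cartesian coordinates in Angstrom (length-3 vector or n x 3
#'   matrix).
#' @export
cart_to_frac <- function(cell, x) {
  x <- coord_matrix(x)
  drop_coord(x %*% t(cell$frac))
}

# coerce a length-3 vector or n x 3 matrix to matrix form
coord_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3) stop("coordinate matrix must have 3 columns", call. = FALSE)
    x
  } else {
    if (length(x) != 3) stop("coordinates must have length 3", call. = FALSE)
    matrix(x, nrow = 1)
  }
}

drop_coord <- function(m) if (nrow(m) == 1) drop(m) else m

#' Minimum-image displacement and distance under lattice periodicity
#'
#' Computes the displacement from `from` to `to` (both Cartesian), reduced
#' by lattice translations so each fractional component lies in [-0.5, 0.5).
#'
#' @param cell A [unit_cell()].
#' @param from,to Cartesian coordinates (length-3 vectors or n x 3 matrices;
#'   recycled row-wise).
#' @return For `min_image_vec`, displacement vectors; for `min_image_dist`,
#'   distances in Angstrom.
#' @export
min_image_vec <- function(cell, from, to) {
  f1 <- coord_matrix(cart_to_frac(cell, from))
  f2 <- coord_matrix(cart_to_frac(cell, to))
  if (nrow(f1) == 1 && nrow(f2) > 1) f1 <- f1[rep(1, nrow(f2)), , drop = FALSE]
  if (nrow(f2) == 1 && nrow(f1) > 1) f2 <- f2[rep(1, nrow(f1)), , drop = FALSE]
  df <- f2 - f1
  df <- df - round(df)
  drop_coord(coord_matrix(frac_to_cart(cell, df)))
}

#' @rdname min_image_vec
#' @export
min_image_dist <- function(cell, from, to) {
  v <- coord_matrix(min_image_vec(cell, from, to))
  sqrt(rowSums(v^2))
}
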