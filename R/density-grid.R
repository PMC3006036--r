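#' Electron-density grid on a crystallographic unit cell
#'
#' A `density_grid` stores voxel values on a regular grid covering the whole
#' unit cell in P1. Voxel `[i, j, k]` (1-based) is centred at fractional
#' coordinate `((i - 1 + origin[1]) / nx, ...)`. Values are stored in an R
#' array whose first index varies fastest along the crystallographic a axis.
#'
#' @param values A 3-d numeric array of voxel values.
#' @param cell A [unit_cell()].
#' @param origin Integer grid offsets of the first voxel (CCP4 NCSTART
#'   words). Defaults to `c(0, 0, 0)`.
#' @param normalized Logical flag: has the map been scaled to unit standard
#'   deviation (see [normalize_density()])?
#' @return An object of class `density_grid`.
#' @seealso [read_map()], [normalize_density()], [modify_density()],
#'   [mask_region()]
#' @export
density_grid <- function(values, cell, origin = c(0L, 0L, 0L),
                         normalized = FALSE) {
  if (!is.array(values) || length(dim(values)) != 3) {
    stop("values must be a 3-d array", call. = FALSE)
  }
  if (!inherits(cell, "unit_cell")) stop("cell must be a unit_cell", call. = FALSE)
  storage.mode(values) <- "double"
  structure(
    list(values = values, dims = dim(values), cell = cell,
         origin = as.integer(origin), normalized = isTRUE(normalized)),
    class = "density_grid"
  )
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d x %d x %d voxels (%s)\n",
              x$dims[1], x$dims[2], x$dims[3],
              if (x$normalized) "normalized" else "raw"))
  print(x$cell)
  v <- x$values
  cat(sprintf("  values: min %.4g  mean %.4g  max %.4g  sd %.4g\n",
              min(v), mean(v), max(v), stats::sd(as.vector(v))))
  invisible(x)
}

#' Grid spacing along each cell axis
#' @param map A [density_grid()].
#' @return Numeric length-3 vector of voxel spacings in Angstrom.
#' @export
grid_spacing <- function(map) {
  c(map$cell$a, map$cell$b, map$cell$c) / map$dims
}

# continuous voxel coordinate (0-based: voxel i has coordinate i-1) of
# Cartesian points; rows of xyz
voxel_coord <- function(map, xyz) {
  x <- if (is.matrix(xyz)) xyz else matrix(xyz, 1, 3)
  f <- x %*% t(map$cell$frac)
  t(t(f) * map$dims - map$origin)
}

# Cartesian position of 0-based voxel coordinates (rows)
voxel_cart <- function(map, u) {
  f <- sweep(u + matrix(map$origin, nrow(u), 3, byrow = TRUE),
             2, map$dims, `/`)
  coord_matrix(frac_to_cart(map$cell, f))
}

# flat 1-based index from 0-based integer voxel triples, with periodic wrap
flat_index <- function(map, ijk) {
  n <- map$dims
  i <- ijk[, 1] %% n[1]; j <- ijk[, 2] %% n[2]; k <- ijk[, 3] %% n[3]
  1 + i + n[1] * (j + n[2] * k)
}

#' Normalize a density map to unit standard deviation
#'
#' Divides every voxel by the population standard deviation computed over
#' the full grid. The mean is not subtracted by default: normalization here
#' is a pure rescaling so that density values read directly in sigma units.
#'
#' @param map A [density_grid()].
#' @param center If `TRUE`, subtract the mean before dividing. Default
#'   `FALSE`.
#' @return A normalized `density_grid` (flag set).
#' @export
normalize_density <- function(map, center = FALSE) {
  stopifnot(inherits(map, "density_grid"))
  v <- map$values
  mu <- mean(v)
  sdv <- sqrt(mean((v - mu)^2))
  if (sdv == 0) stop("degenerate map: constant density has no scale", call. = FALSE)
  if (center) v <- v - mu
  map$values <- v / sdv
  map$normalized <- TRUE
  map
}

#' Damp super-strong density peaks
#'
#' Applies an upper clamp at `cap` sigma to a normalized map, yielding the
#' modified density used by all downstream search stages. Very strong peaks
#' (heavy atoms, e.g. brominated uracil) would otherwise dominate the
#' centre-of-gravity iteration and the fitting targets; the clamp damps them
#' while leaving ordinary density untouched. Idempotent.
#'
#' @param map A normalized [density_grid()].
#' @param cap Clamp level in sigma units, default 4.0. Must be positive.
#' @return The modified `density_grid`.
#' @export
modify_density <- function(map, cap = 4.0) {
  stopifnot(inherits(map, "density_grid"))
  if (!isTRUE(map$normalized)) {
    stop("modify_density() expects a normalized map; call normalize_density() first",
         call. = FALSE)
  }
  if (!is.numeric(cap) || length(cap) != 1 || !is.finite(cap) || cap <= 0) {
    stop("cap must be a positive number (sigma units)", call. = FALSE)
  }
  map$values[map$values > cap] <- cap
  map
}

#' Mask out a region around known atoms
#'
#' Sets every voxel within `radius` of any listed atom to a strongly
#' negative sentinel (default -10 sigma) so that masked regions can neither
#' seed nor attract blobs. Distances are minimum-image periodic on the cell,
#' so atoms near a cell face mask voxels on the opposite face too. Used to
#' exclude an already-built protein model when searching nucleic acid in a
#' complex.
#'
#' @param map A [density_grid()].
#' @param atoms Cartesian positions: an n x 3 matrix, a length-3 vector, or
#'   a data frame with columns `x`, `y`, `z`.
#' @param radius Masking radius in Angstrom (non-negative).
#' @param sentinel Value written into masked voxels. Default -10.
#' @return The masked `density_grid`.
#' @export
mask_region <- function(map, atoms, radius, sentinel = -10) {
  stopifnot(inherits(map, "density_grid"))
  if (!is.numeric(radius) || length(radius) != 1 || radius < 0) {
    stop("radius must be a single non-negative number", call. = FALSE)
  }
  if (is.data.frame(atoms)) atoms <- as.matrix(atoms[, c("x", "y", "z")])
  if (is.null(atoms) || (is.matrix(atoms) && nrow(atoms) == 0)) return(map)
  atoms <- coord_matrix(atoms)
  offs <- sphere_offsets(map, radius)
  v <- as.vector(map$values)
  for (r in seq_len(nrow(atoms))) {
    g <- gather_sphere(map, atoms[r, ], radius, offs)
    if (length(g$idx)) v[g$idx] <- sentinel
  }
  map$values <- array(v, dim = map$dims)
  map
}

# Precompute integer voxel offsets whose centres can fall within `radius` of
# an arbitrary continuous point, plus their Cartesian displacement for the
# zero-subvoxel case. Margin of one voxel diagonal covers sub-voxel shifts.
sphere_offsets <- function(map, radius) {
  sp <- grid_spacing(map)
  diag_len <- sqrt(sum(sp^2))
  rmax <- radius + diag_len / 2  # margin for sub-voxel centre shifts
  nmax <- pmin(ceiling(rmax / sp), floor((map$dims - 1) / 2))
  rng <- lapply(1:3, function(d) seq(-nmax[d], nmax[d]))
  ijk <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  cart <- coord_matrix(frac_to_cart(map$cell, sweep(ijk, 2, map$dims, `/`)))
  keep <- sqrt(rowSums(cart^2)) <= rmax
  list(ijk = ijk[keep, , drop = FALSE],
       cart = cart[keep, , drop = FALSE],
       radius = radius)
}

# Voxels whose centres lie within `radius` of the continuous Cartesian
# point `centre`. Returns flat indices, values, and Cartesian displacements
# voxel_centre - centre.
gather_sphere <- function(map, centre, radius, offs = NULL) {
  if (is.null(offs)) offs <- sphere_offsets(map, radius)
  u0 <- drop(round(voxel_coord(map, centre)))
  # displacement of nearest voxel centre from the query point
  d0 <- drop(voxel_cart(map, matrix(u0, 1, 3))) - centre
  oc <- offs$cart
  dx <- oc[, 1] + d0[1]; dy <- oc[, 2] + d0[2]; dz <- oc[, 3] + d0[3]
  dist2 <- dx * dx + dy * dy + dz * dz
  keep <- dist2 <= radius * radius
  oi <- offs$ijk
  n <- map$dims
  i <- (oi[keep, 1] + u0[1]) %% n[1]
  j <- (oi[keep, 2] + u0[2]) %% n[2]
  k <- (oi[keep, 3] + u0[3]) %% n[3]
  idx <- 1 + i + n[1] * (j + n[2] * k)
  list(idx = idx,
       values = map$values[idx],
       disp = cbind(dx[keep], dy[keep], dz[keep]),
       dist = sqrt(dist2[keep]))
}

#' Trilinear interpolation of map values (and gradient)
#'
#' Evaluates the density at arbitrary Cartesian points by periodic trilinear
#' interpolation; optionally returns the analytic Cartesian gradient of the
#' interpolant.
#'
#' @param map A [density_grid()].
#' @param xyz A length-3 vector or n x 3 matrix of Cartesian positions.
#' @param gradient If `TRUE`, also return the n x 3 gradient matrix
#'   (sigma / Angstrom).
#' @return A numeric vector of interpolated values, or if `gradient = TRUE`
#'   a list with elements `value` and `gradient`.
#' @export
interp_density <- function(map, xyz, gradient = FALSE) {
  u <- voxel_coord(map, xyz)
  i0 <- floor(u)
  v <- map$values   # flat single-index subsetting works on the 3-d array
  dims <- map$dims
  n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]
  fx <- u[, 1] - i0[, 1]; fy <- u[, 2] - i0[, 2]; fz <- u[, 3] - i0[, 3]
  if (min(i0) >= 0 && i0[1, 1] < n1 - 1 &&
      max(i0[, 1]) < n1 - 1 && max(i0[, 2]) < n2 - 1 && max(i0[, 3]) < n3 - 1) {
    # fast path: all corners in-bounds, no periodic wrap needed
    ia <- i0[, 1]; ib <- ia + 1
    ja <- i0[, 2] * n1; jb <- ja + n1
    ka <- i0[, 3] * (n1 * n2); kb <- ka + (n1 * n2)
  } else {
    ia <- i0[, 1] %% n1; ib <- (i0[, 1] + 1) %% n1
    ja <- (i0[, 2] %% n2) * n1; jb <- ((i0[, 2] + 1) %% n2) * n1
    ka <- (i0[, 3] %% n3) * (n1 * n2); kb <- ((i0[, 3] + 1) %% n3) * (n1 * n2)
  }
  c000 <- v[1 + ia + ja + ka]; c100 <- v[1 + ib + ja + ka]
  c010 <- v[1 + ia + jb + ka]; c110 <- v[1 + ib + jb + ka]
  c001 <- v[1 + ia + ja + kb]; c101 <- v[1 + ib + ja + kb]
  c011 <- v[1 + ia + jb + kb]; c111 <- v[1 + ib + jb + kb]
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  val <- c0 * (1 - fz) + c1 * fz
  if (!gradient) return(val)
  # partials with respect to the continuous voxel coordinate u
  dxu <- ((c100 - c000) * (1 - fy) + (c110 - c010) * fy) * (1 - fz) +
         ((c101 - c001) * (1 - fy) + (c111 - c011) * fy) * fz
  dyu <- (c10 - c00) * (1 - fz) + (c11 - c01) * fz
  dzu <- c1 - c0
  gu <- cbind(dxu, dyu, dzu)
  # du/dx = diag(dims) %*% frac matrix; gradient_x = t(J) %*% g_u
  jac <- diag(dims) %*% map$cell$frac
  grad <- gu %*% jac
  list(value = val, gradient = grad)
}
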