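#' Default blob-search parameters
#'
#' The centre-of-gravity blob search is controlled by a small set of
#' constants: the 2.5 A sphere over which the positive density is averaged,
#' a 0.11 A convergence cutoff on the centre shift, a maximum of 20
#' iterations, a 3.5 A limit on total drift from the seeding voxel, and a
#' 1.3 A masking radius around every accepted centre. `seed_min` sets the
#' lowest normalized density (sigma) a voxel needs to seed a search;
#' `max_blobs` caps the returned list.
#'
#' @param radius Sphere radius in Angstrom.
#' @param shift_tol Convergence cutoff on the per-iteration centre shift (A).
#' @param max_iter Maximum number of centre-of-gravity iterations.
#' @param max_drift Maximum allowed distance between seed and centre (A).
#' @param mask_radius Radius (A) around an accepted centre within which
#'   voxels are consumed and can no longer seed or host new blobs.
#' @param seed_min Minimum normalized density for a seeding voxel (sigma).
#' @param max_blobs Maximum number of blobs to return.
#' @return A named list of parameters.
#' @export
blob_params <- function(radius = 2.5, shift_tol = 0.11, max_iter = 20L,
                        max_drift = 3.5, mask_radius = 1.3,
                        seed_min = 1.0, max_blobs = 500L) {
  stopifnot(radius > 0, shift_tol > 0, max_iter >= 1, max_drift > 0,
            mask_radius > 0, max_blobs >= 1)
  list(radius = radius, shift_tol = shift_tol, max_iter = as.integer(max_iter),
       max_drift = max_drift, mask_radius = mask_radius,
       seed_min = seed_min, max_blobs = as.integer(max_blobs))
}

#' Iterate a blob centre of gravity to convergence
#'
#' Starting from a seed position, repeatedly computes the centroid of the
#' positive density inside a 2.5 A sphere about the current centre and moves
#' the centre there, until the shift drops below `shift_tol`. Negative
#' density carries no weight: a negative centroid weight could expel the
#' centre from the feature it is meant to find.
#'
#' @param map A normalized (and usually modified) [density_grid()].
#' @param seed Cartesian seed position (length-3).
#' @param params A [blob_params()] list.
#' @param consumed Optional logical vector (one entry per voxel, flat
#'   indexing) marking voxels already claimed by accepted blobs; a centre
#'   converging into a consumed voxel is rejected.
#' @param offs Precomputed [sphere_offsets()] (internal reuse).
#' @return A list with `status` (`"converged"`, `"max_iter"`, `"drift"`,
#'   `"masked"`, or `"empty"`), the final `centre`, and `n_iter`.
#' @export
converge_centre <- function(map, seed, params = blob_params(),
                            consumed = NULL, offs = NULL) {
  stopifnot(inherits(map, "density_grid"))
  seed <- as.numeric(seed)
  if (length(seed) != 3 || !all(is.finite(seed))) {
    stop("seed must be a finite Cartesian position of length 3", call. = FALSE)
  }
  if (is.null(offs)) offs <- sphere_offsets(map, params$radius)
  centre <- seed
  for (it in seq_len(params$max_iter)) {
    g <- gather_sphere(map, centre, params$radius, offs)
    w <- g$values
    pos <- w > 0
    if (!any(pos)) {
      return(list(status = "empty", centre = centre, n_iter = it))
    }
    step <- colSums(g$disp[pos, , drop = FALSE] * w[pos]) / sum(w[pos])
    centre <- centre + step
    if (sqrt(sum((centre - seed)^2)) > params$max_drift) {
      return(list(status = "drift", centre = centre, n_iter = it))
    }
    if (sqrt(sum(step^2)) < params$shift_tol) {
      if (!is.null(consumed)) {
        at <- flat_index(map, matrix(drop(round(voxel_coord(map, centre))), 1, 3))
        if (consumed[at]) {
          return(list(status = "masked", centre = centre, n_iter = it))
        }
      }
      return(list(status = "converged", centre = centre, n_iter = it))
    }
    # early abort: centre has wandered onto an already-claimed feature
    if (!is.null(consumed)) {
      at <- flat_index(map, matrix(drop(round(voxel_coord(map, centre))), 1, 3))
      if (consumed[at]) {
        return(list(status = "masked", centre = centre, n_iter = it))
      }
    }
  }
  list(status = "max_iter", centre = centre, n_iter = params$max_iter)
}

#' Moments-of-density shape analysis of a blob
#'
#' Builds the inertia-form moments matrix
#' `M_jk = sum_i rho_i (|r_i|^2 delta_jk - r_ij r_ik)` over all voxels with
#' positive density within `radius` of the centre (`r_i` measured from the
#' centre), and diagonalizes it. The eigenstructure encodes the blob shape:
#' one large eigenvalue with two smaller equal ones indicates a planar blob
#' whose large-eigenvalue eigenvector is the plane normal; three equal
#' eigenvalues indicate an isotropic (e.g. tetrahedral phosphate) blob.
#'
#' @inheritParams converge_centre
#' @param centre Cartesian blob centre.
#' @param radius Sphere radius in Angstrom (default 2.5).
#' @param offs Precomputed [sphere_offsets()] (internal reuse).
#' @return A list with `eigvals` (sorted decreasing), `eigvecs` (columns
#'   matching `eigvals`), `Q` (sum of positive density) and `n_pos`.
#' @export
compute_moments <- function(map, centre, radius = 2.5, offs = NULL) {
  g <- gather_sphere(map, centre, radius, offs)
  pos <- g$values > 0
  if (!any(pos)) {
    stop("degenerate blob: no positive density within the sphere", call. = FALSE)
  }
  w <- g$values[pos]
  r <- g$disp[pos, , drop = FALSE]
  r2 <- rowSums(r^2)
  tr <- sum(w * r2)
  # M = tr(I) - sum w r r^T
  rw <- r * w
  S <- crossprod(rw, r)          # sum w r r^T
  M <- diag(3) * tr - S
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  list(eigvals = e$values, eigvecs = e$vectors, Q = sum(w),
       n_pos = sum(pos), moments = M)
}

#' Planarity score of a blob
#'
#' `p = (2*l1 - l2 - l3) / (l1 + l2 + l3)` for eigenvalues
#' `l1 >= l2 >= l3 >= 0`. For any non-negative mass distribution the
#' perpendicular-axis inequality `l1 <= l2 + l3` bounds `p` to `[0, 0.5]`:
#' `p = 0.5` exactly for a perfectly planar blob (`l1 = l2 + l3`) and
#' `p = 0` for an isotropic one.
#'
#' @param eigvals Either a numeric length-3 vector of eigenvalues or a blob
#'   row / moments list carrying `lambda1..lambda3`.
#' @return Planarity score in `[0, 0.5]`.
#' @export
planarity <- function(eigvals) {
  if (is.list(eigvals)) {
    eigvals <- if (!is.null(eigvals$eigvals)) eigvals$eigvals
               else c(eigvals$lambda1, eigvals$lambda2, eigvals$lambda3)
  }
  l <- sort(as.numeric(eigvals), decreasing = TRUE)
  s <- sum(l)
  if (s <= 0) stop("degenerate blob: eigenvalue sum is not positive", call. = FALSE)
  (2 * l[1] - l[2] - l[3]) / s
}

#' Locate density blobs in a map
#'
#' Iterates over voxels in descending order of density, converging a centre
#' of gravity from each still-valid voxel (see [converge_centre()]). Every
#' accepted centre consumes the voxels within `mask_radius` (1.3 A) so that
#' each feature is reported once. Ties in seed density are broken by
#' ascending voxel index, making the acceptance order fully deterministic.
#'
#' @param map A normalized and modified [density_grid()].
#' @param params A [blob_params()] list.
#' @return A tibble, one row per accepted blob in acceptance order, with the
#'   converged `x, y, z`, the positive-density sum `Q`, eigenvalues
#'   `lambda1 >= lambda2 >= lambda3`, eigenvector matrix (list column
#'   `eigvecs`, columns matching the eigenvalues), `planarity`, iteration
#'   count and seed density.
#' @export
find_blobs <- function(map, params = blob_params()) {
  stopifnot(inherits(map, "density_grid"))
  if (!isTRUE(map$normalized)) {
    stop("find_blobs() expects a normalized map", call. = FALSE)
  }
  v <- as.vector(map$values)
  offs <- sphere_offsets(map, params$radius)
  offs_mask <- sphere_offsets(map, params$mask_radius)
  cand <- which(v >= max(params$seed_min, .Machine$double.eps))
  if (!length(cand)) return(empty_blob_tibble())
  cand <- cand[order(-v[cand], cand)]
  consumed <- rep(FALSE, length(v))
  rows <- list()
  n_acc <- 0L
  for (idx in cand) {
    if (consumed[idx]) next
    seed <- drop(voxel_cart(map, matrix(flat_to_ijk(map, idx), 1, 3)))
    res <- converge_centre(map, seed, params, consumed = consumed, offs = offs)
    if (res$status != "converged") next
    mom <- tryCatch(compute_moments(map, res$centre, params$radius, offs),
                    error = function(e) NULL)
    if (is.null(mom)) next
    n_acc <- n_acc + 1L
    rows[[n_acc]] <- tibble::tibble(
      id = n_acc,
      x = res$centre[1], y = res$centre[2], z = res$centre[3],
      Q = mom$Q,
      lambda1 = mom$eigvals[1], lambda2 = mom$eigvals[2],
      lambda3 = mom$eigvals[3],
      eigvecs = list(mom$eigvecs),
      planarity = planarity(mom$eigvals),
      n_iter = res$n_iter,
      seed_value = v[idx]
    )
    # consume the neighbourhood of the accepted centre
    g <- gather_sphere(map, res$centre, params$mask_radius, offs_mask)
    consumed[g$idx] <- TRUE
    consumed[idx] <- TRUE
    if (n_acc >= params$max_blobs) break
  }
  if (!n_acc) return(empty_blob_tibble())
  dplyr::bind_rows(rows)
}

empty_blob_tibble <- function() {
  tibble::tibble(id = integer(), x = double(), y = double(), z = double(),
                 Q = double(), lambda1 = double(), lambda2 = double(),
                 lambda3 = double(), eigvecs = list(), planarity = double(),
                 n_iter = integer(), seed_value = double())
}

# 0-based voxel triple from a flat 1-based index
flat_to_ijk <- function(map, idx) {
  n <- map$dims
  idx0 <- idx - 1
  i <- idx0 %% n[1]
  j <- (idx0 %/% n[1]) %% n[2]
  k <- idx0 %/% (n[1] * n[2])
  c(i, j, k)
}
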