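# Rigid-body pose utilities -------------------------------------------------

rot_z <- function(angle) {
  ca <- cos(angle); sa <- sin(angle)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

skew3 <- function(w) {
  matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
}

# exponential map so(3) -> SO(3)
rot_exp <- function(w) {
  th <- sqrt(sum(w^2))
  K <- skew3(w)
  if (th < 1e-12) return(diag(3) + K)
  diag(3) + sin(th) / th * K + (1 - cos(th)) / th^2 * (K %*% K)
}

# right Jacobian of the exponential map
rot_right_jacobian <- function(w) {
  th <- sqrt(sum(w^2))
  K <- skew3(w)
  if (th < 1e-6) return(diag(3) - K / 2)
  diag(3) - (1 - cos(th)) / th^2 * K + (th - sin(th)) / th^3 * (K %*% K)
}

apply_pose <- function(R, t, X) {
  sweep(X %*% t(R), 2, t, `+`)
}

# Template fitting -----------------------------------------------------------

#' Rank blobs by base likeness
#'
#' Base blobs are flat and dense: the sort quantity is `B = Q * planarity`,
#' descending. A blob with one dominant moments eigenvalue (eigenvector
#' perpendicular to the base plane) and a large positive-density sum ranks
#' first; isotropic or weak blobs rank last. Ties preserve input order.
#'
#' @param blobs A blob tibble from [find_blobs()].
#' @return The same tibble, ordered by the base score, with a `base_score`
#'   column added.
#' @export
rank_base_blobs <- function(blobs) {
  score <- blobs$Q * blobs$planarity
  blobs$base_score <- score
  blobs[order(-score), , drop = FALSE]
}

#' Initial template placements for a blob
#'
#' Aligns the template plane to the blob: the canonical plane normal (z) is
#' sent to the blob's largest-eigenvalue eigenvector and the template's
#' density centroid to the blob centre. Both faces (normal and anti-normal)
#' are emitted; the in-plane rotation is left to [simplex_fit()]'s 15-degree
#' scan. Blobs below the planarity floor yield no placements.
#'
#' @param template A [base_template()].
#' @param blob A single-row blob tibble (or list) with `x, y, z`,
#'   `eigvecs` and `planarity`.
#' @param planarity_floor Minimum blob planarity to attempt a base fit.
#' @return A list of poses, each `list(R = <3x3>, t = <length-3>)`; empty if
#'   the blob is not planar enough.
#' @export
align_template <- function(template, blob, planarity_floor = 0.25) {
  p <- if (!is.null(blob$planarity)) blob$planarity[[1]] else planarity(blob)
  if (p < planarity_floor) return(list())
  ev <- blob$eigvecs
  if (is.list(ev) && !is.matrix(ev)) ev <- ev[[1]]
  normal <- ev[, 1]
  centre <- c(blob$x[[1]], blob$y[[1]], blob$z[[1]])
  X <- template_coords(template)
  zc <- template$atoms$z
  centroid <- colSums(X * zc) / sum(zc)
  lapply(c(1, -1), function(s) {
    e3 <- s * normal
    ref <- if (abs(e3[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * e3) * e3
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- cross3(e3, e1)
    R <- cbind(e1, e2, e3)
    list(R = R, t = centre - drop(R %*% centroid))
  })
}

# correlation between template atomic numbers (dummies = -1) and the
# modified density interpolated at the posed atom positions
template_cc <- function(map, template, R, t) {
  X <- rbind(template_coords(template), template$dummies)
  zvec <- c(template$atoms$z, rep(-1, nrow(template$dummies)))
  rho <- interp_density(map, apply_pose(R, t, X))
  if (stats::sd(rho) == 0) return(0)
  stats::cor(zvec, rho)
}

template_S <- function(map, template, R, t) {
  X <- template_coords(template)
  sum(template$atoms$z * interp_density(map, apply_pose(R, t, X)))
}

#' Simplex search of a base template against the density
#'
#' Applies 24 in-plane rotations (15-degree steps) to the initial placement
#' and, from each, runs a derivative-free Nelder-Mead simplex over the six
#' rigid-body parameters (initial steps: 5 degrees rotation, 0.3 A
#' translation), minimizing the negative Pearson correlation between the
#' template atomic numbers (real atoms with their true Z, dummy positions
#' with Z = -1) and the modified density interpolated at the posed
#' positions.
#'
#' @param map A normalized, modified [density_grid()].
#' @param template A [base_template()].
#' @param init A pose `list(R, t)` from [align_template()].
#' @param rotations Number of in-plane rotation starts (default 24).
#' @param maxit Simplex evaluation budget per start (default 150).
#' @return A tibble of fits, one per rotation start, with columns `kind`,
#'   `cc`, `S`, `converged`, and list columns `R`, `t`, `coords` (posed
#'   real-atom coordinates, rows named).
#' @export
simplex_fit <- function(map, template, init, rotations = 24L, maxit = 150L) {
  angles <- 2 * pi * (seq_len(rotations) - 1) / rotations
  X <- template_coords(template)
  Xall <- rbind(X, template$dummies)
  zvec <- c(template$atoms$z, rep(-1, nrow(template$dummies)))
  zc <- zvec - mean(zvec)
  zss <- sqrt(sum(zc^2))
  parscale <- c(rep(5 * pi / 180, 3), rep(0.3, 3))
  rows <- lapply(angles, function(phi) {
    R0 <- init$R %*% rot_z(phi)
    t0 <- init$t
    fn <- function(p) {
      R <- rot_exp(p[1:3]) %*% R0
      Y <- Xall %*% t(R)
      tt <- t0 + p[4:6]
      Y[, 1] <- Y[, 1] + tt[1]; Y[, 2] <- Y[, 2] + tt[2]
      Y[, 3] <- Y[, 3] + tt[3]
      rho <- interp_density(map, Y)
      rc <- rho - mean(rho)
      den <- zss * sqrt(sum(rc^2))
      if (den == 0) return(0)
      -sum(zc * rc) / den
    }
    opt <- stats::optim(rep(0, 6), fn, method = "Nelder-Mead",
                        control = list(maxit = maxit, parscale = parscale,
                                       reltol = 1e-6))
    Rf <- rot_exp(opt$par[1:3]) %*% R0
    tf <- t0 + opt$par[4:6]
    Xf <- apply_pose(Rf, tf, X)
    tibble::tibble(
      kind = template$kind,
      cc = -opt$value,
      S = template_S(map, template, Rf, tf),
      converged = opt$convergence == 0L,
      R = list(Rf), t = list(tf),
      coords = list(Xf)
    )
  })
  dplyr::bind_rows(rows)
}

#' Gradient refinement of a base fit
#'
#' Maximizes `S = sum_i Z_i rho'(x_i)` over the six rigid-body parameters
#' with BFGS, using the analytic gradient of the trilinear interpolant.
#' Dummy atoms take no part in this stage.
#'
#' @param map A normalized, modified [density_grid()].
#' @param fit A single-row fit tibble from [simplex_fit()].
#' @param template The [base_template()] the fit came from (defaults to the
#'   template named by `fit$kind`).
#' @param maxit BFGS iteration budget.
#' @return The refined fit row with updated `S`, `cc`, pose and coordinates.
#' @export
refine_fit <- function(map, fit, template = NULL, maxit = 50L) {
  if (is.null(template)) template <- base_template(fit$kind[[1]])
  R0 <- fit$R[[1]]; t0 <- fit$t[[1]]
  X <- template_coords(template)
  zc <- template$atoms$z
  fn <- function(p) {
    y <- apply_pose(rot_exp(p[1:3]) %*% R0, t0 + p[4:6], X)
    -sum(zc * interp_density(map, y))
  }
  gr <- function(p) {
    E <- rot_exp(p[1:3])
    U <- X %*% t(R0)                     # u_i = R0 x_i
    y <- sweep(U %*% t(E), 2, t0 + p[4:6], `+`)
    ig <- interp_density(map, y, gradient = TRUE)
    gz <- ig$gradient * zc               # Z_i g_i rows
    gEt <- gz %*% E                      # rows: E^T (Z_i g_i)
    crossv <- cbind(U[, 2] * gEt[, 3] - U[, 3] * gEt[, 2],
                    U[, 3] * gEt[, 1] - U[, 1] * gEt[, 3],
                    U[, 1] * gEt[, 2] - U[, 2] * gEt[, 1])
    gw <- drop(t(rot_right_jacobian(p[1:3])) %*% colSums(crossv))
    -c(gw, colSums(gz))
  }
  opt <- stats::optim(rep(0, 6), fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-9))
  R <- rot_exp(opt$par[1:3]) %*% R0
  t <- t0 + opt$par[4:6]
  fit$R <- list(R); fit$t <- list(t)
  fit$coords <- list(apply_pose(R, t, X))
  fit$S <- -opt$value
  fit$cc <- template_cc(map, template, R, t)
  fit
}

#' Fit both base templates into one blob
#'
#' Runs the full per-blob base search: alignment to the blob plane (both
#' faces), the 24-rotation simplex scan for the purine and the pyrimidine
#' template, deduplication of near-identical poses (all-atom RMSD below
#' `dedup_rmsd`), retention of the top `cluster_size` solutions of each kind
#' by correlation, and gradient refinement of the survivors.
#'
#' @inheritParams simplex_fit
#' @param blob A single-row blob tibble from [find_blobs()].
#' @param templates List of the two [base_template()] objects.
#' @param planarity_floor Minimum blob planarity to attempt fitting.
#' @param cluster_size Number of solutions kept per kind (default 6).
#' @param dedup_rmsd RMSD (A) below which two poses count as the same.
#' @return A tibble of refined fits with a `blob_id` column; empty if the
#'   blob fails the planarity gate.
#' @export
fit_bases_at_blob <- function(map, blob,
                              templates = list(base_template("purine"),
                                               base_template("pyrimidine")),
                              planarity_floor = 0.25, cluster_size = 6L,
                              dedup_rmsd = 0.3, rotations = 24L,
                              maxit = 150L) {
  out <- lapply(templates, function(tm) {
    inits <- align_template(tm, blob, planarity_floor)
    if (!length(inits)) return(NULL)
    fits <- dplyr::bind_rows(lapply(inits, function(ini) {
      simplex_fit(map, tm, ini, rotations = rotations, maxit = maxit)
    }))
    fits <- fits[order(-fits$cc), , drop = FALSE]
    keep <- dedupe_fits(fits, dedup_rmsd)
    fits <- fits[keep, , drop = FALSE]
    fits <- utils::head(fits, cluster_size)
    dplyr::bind_rows(lapply(seq_len(nrow(fits)), function(i) {
      refine_fit(map, fits[i, , drop = FALSE], template = tm)
    }))
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out)) out$blob_id <- blob$id[[1]]
  out
}

# indices of fits to keep after greedy RMSD deduplication (fits pre-sorted
# by decreasing quality)
dedupe_fits <- function(fits, dedup_rmsd) {
  keep <- integer(0)
  for (i in seq_len(nrow(fits))) {
    ci <- fits$coords[[i]]
    dup <- FALSE
    for (j in keep) {
      d <- sqrt(mean(rowSums((ci - fits$coords[[j]])^2)))
      if (d < dedup_rmsd) { dup <- TRUE; break }
    }
    if (!dup) keep <- c(keep, i)
  }
  keep
}

# Watson-Crick scoring --------------------------------------------------------

#' Score a purine-pyrimidine combination as a Watson-Crick pair
#'
#' Constructs idealized in-plane hydrogens on the donor nitrogens (N-H
#' 1.01 A) and evaluates the three guanine-cytosine-type contacts:
#' purine N2-H...pyrimidine O2 (terminal, target 2.16 A), purine
#' N1-H...pyrimidine N3 (target 1.85 A), and pyrimidine N4-H...purine O6
#' (terminal, target 2.16 A). Each contact contributes
#' `cos(180 - theta) - |d - d0|`, where `theta` is the N-H...A angle at the
#' hydrogen and `d` the H...A distance, so a perfectly linear bond at its
#' target distance contributes +1 and the score maximum is 3. For amine
#' donors with two hydrogens the better-placed hydrogen is used.
#'
#' @param purine,pyrimidine Single-row fit tibbles (from [refine_fit()] or
#'   [fit_bases_at_blob()]), or lists with `coords` and `R`.
#' @return An object of class `base_pair`: a list with the two fits, a
#'   `bonds` tibble (donor, acceptor, `d`, `theta`, `d0`, contribution) and
#'   the total `wc_score`.
#' @export
wc_score <- function(purine, pyrimidine) {
  pu_coords <- fit_coords(purine); py_coords <- fit_coords(pyrimidine)
  pu_n <- fit_normal(purine); py_n <- fit_normal(pyrimidine)
  pu_t <- base_template("purine"); py_t <- base_template("pyrimidine")
  need <- function(coords, nm, what) {
    if (!all(nm %in% rownames(coords))) {
      stop("missing hydrogen-bond site atoms (", what, "): ",
           paste(setdiff(nm, rownames(coords)), collapse = ", "),
           call. = FALSE)
    }
  }
  need(pu_coords, c("N1", "N2", "O6", "C2", "C6"), "purine")
  need(py_coords, c("N3", "O2", "N4", "C4"), "pyrimidine")
  b <- wc_bonds(pu_coords, py_coords, pu_n, py_n, pu_t, py_t)
  bonds <- tibble::tibble(donor = c("N2", "N1", "N4"),
                          acceptor = c("O2", "N3", "O6"),
                          d = b$d, theta = b$theta, d0 = b$d0,
                          contribution = b$contribution)
  structure(list(purine = purine, pyrimidine = pyrimidine, bonds = bonds,
                 wc_score = sum(bonds$contribution)),
            class = "base_pair")
}

# numeric core of the Watson-Crick score (no tibbles; hot path for pruning)
wc_bonds <- function(pu_coords, py_coords, pu_n, py_n,
                     pu_t = base_template("purine"),
                     py_t = base_template("pyrimidine")) {
  contacts <- list(
    list(dc = pu_coords, ds = pu_t$hbond$donors$N2, dn = pu_n,
         acc = py_coords["O2", ], d0 = 2.16),
    list(dc = pu_coords, ds = pu_t$hbond$donors$N1, dn = pu_n,
         acc = py_coords["N3", ], d0 = 1.85),
    list(dc = py_coords, ds = py_t$hbond$donors$N4, dn = py_n,
         acc = pu_coords["O6", ], d0 = 2.16)
  )
  d <- theta <- contribution <- d0 <- numeric(3)
  for (k in 1:3) {
    ct <- contacts[[k]]
    H <- donor_hydrogens(ct$dc, ct$ds, ct$dn)
    N <- ct$dc[ct$ds$donor, ]
    best_c <- -Inf; best_d <- NA_real_; best_t <- NA_real_
    for (i in seq_len(nrow(H))) {
      h <- H[i, ]
      va <- ct$acc - h
      di <- sqrt(sum(va^2))
      vn <- N - h
      costh <- sum(vn * va) / (sqrt(sum(vn^2)) * di)
      costh <- max(-1, min(1, costh))
      ci <- -costh - abs(di - ct$d0)
      if (ci > best_c) {
        best_c <- ci; best_d <- di; best_t <- acos(costh) * 180 / pi
      }
    }
    d[k] <- best_d; theta[k] <- best_t
    contribution[k] <- best_c; d0[k] <- ct$d0
  }
  list(d = d, theta = theta, d0 = d0, contribution = contribution,
       score = sum(contribution))
}

fit_coords <- function(fit) {
  if (is.matrix(fit)) return(fit)
  cc <- fit$coords
  if (is.list(cc) && !is.matrix(cc)) cc <- cc[[1]]
  cc
}

fit_normal <- function(fit) {
  if (!is.matrix(fit) && !is.null(fit$R)) {
    R <- fit$R
    if (is.list(R)) R <- R[[1]]
    return(R[, 3])
  }
  # fall back to the least-squares plane of the coordinates
  X <- fit_coords(fit)
  Xc <- sweep(X, 2, colMeans(X))
  svd(Xc)$v[, 3]
}

#' @export
print.base_pair <- function(x, ...) {
  cat(sprintf("<base_pair> wc_score = %.3f\n", x$wc_score))
  print(as.data.frame(x$bonds), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Prune base fits by Watson-Crick pairing
#'
#' Scores every purine-pyrimidine combination drawn from distinct blobs and
#' greedily accepts the globally best pair whose score exceeds `threshold`,
#' consuming both blobs, until no acceptable pair remains. Blobs left
#' unpaired keep their single best fit by `S`, flagged `unpaired`; all other
#' cluster members are pruned as presumed false bases.
#'
#' @param fits Tibble of refined fits across blobs (rows from
#'   [fit_bases_at_blob()], must carry `blob_id`).
#' @param threshold Minimum acceptable pair score (default 1.5).
#' @param max_dist Centroid prefilter (A): combinations whose base
#'   centroids are farther apart are not scored. Default 12.
#' @return An object of class `base_pairing`: list with tibbles `pairs`
#'   (one row per accepted pair, with both fits and the bond table as list
#'   columns), `singles`, and `pruned`.
#' @export
prune_by_pairing <- function(fits, threshold = 1.5, max_dist = 12) {
  if (!nrow(fits)) {
    return(structure(list(pairs = tibble::tibble(), singles = fits,
                          pruned = fits), class = "base_pairing"))
  }
  cent <- t(vapply(fits$coords, colMeans, numeric(3)))
  ipu <- which(fits$kind == "purine")
  ipy <- which(fits$kind == "pyrimidine")
  pu_t <- base_template("purine"); py_t <- base_template("pyrimidine")
  normals <- lapply(seq_len(nrow(fits)), function(i) fits$R[[i]][, 3])
  cand <- NULL
  if (length(ipu) && length(ipy)) {
    grid <- expand.grid(a = ipu, b = ipy)
    keep <- fits$blob_id[grid$a] != fits$blob_id[grid$b] &
      sqrt(rowSums((cent[grid$a, , drop = FALSE] -
                    cent[grid$b, , drop = FALSE])^2)) <= max_dist
    grid <- grid[keep, , drop = FALSE]
    if (nrow(grid)) {
      score <- vapply(seq_len(nrow(grid)), function(r) {
        wc_bonds(fits$coords[[grid$a[r]]], fits$coords[[grid$b[r]]],
                 normals[[grid$a[r]]], normals[[grid$b[r]]],
                 pu_t, py_t)$score
      }, numeric(1))
      cand <- data.frame(a = grid$a, b = grid$b, score = score)
    }
  }
  pairs <- list(); used_blobs <- integer(0); used_rows <- integer(0)
  if (!is.null(cand)) {
    cand <- cand[order(-cand$score), , drop = FALSE]
    while (nrow(cand) && cand$score[1] > threshold) {
      a <- cand$a[1]; b <- cand$b[1]
      pr <- wc_score(fits[a, , drop = FALSE], fits[b, , drop = FALSE])
      pairs[[length(pairs) + 1]] <- tibble::tibble(
        blob_purine = fits$blob_id[a], blob_pyrimidine = fits$blob_id[b],
        wc_score = pr$wc_score,
        purine = list(fits[a, , drop = FALSE]),
        pyrimidine = list(fits[b, , drop = FALSE]),
        bonds = list(pr$bonds))
      used_blobs <- c(used_blobs, fits$blob_id[a], fits$blob_id[b])
      used_rows <- c(used_rows, a, b)
      keepc <- !(fits$blob_id[cand$a] %in% used_blobs |
                 fits$blob_id[cand$b] %in% used_blobs)
      cand <- cand[keepc, , drop = FALSE]
    }
  }
  pairs <- if (length(pairs)) dplyr::bind_rows(pairs) else tibble::tibble()
  rest <- fits[!(fits$blob_id %in% used_blobs), , drop = FALSE]
  singles <- rest |>
    dplyr::group_by(.data$blob_id) |>
    dplyr::slice_max(.data$S, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  if (nrow(singles)) singles$unpaired <- TRUE
  pruned_idx <- setdiff(seq_len(nrow(fits)), used_rows)
  pruned <- fits[pruned_idx, , drop = FALSE]
  if (nrow(singles)) {
    # singles are kept, not pruned
    key <- paste(pruned$blob_id, pruned$kind, pruned$S)
    skey <- paste(singles$blob_id, singles$kind, singles$S)
    pruned <- pruned[!(key %in% skey), , drop = FALSE]
  }
  structure(list(pairs = pairs, singles = singles, pruned = pruned),
            class = "base_pairing")
}

#' @export
print.base_pairing <- function(x, ...) {
  cat(sprintf("<base_pairing> %d pairs, %d unpaired singles, %d pruned fits\n",
              nrow(x$pairs), nrow(x$singles), nrow(x$pruned)))
  invisible(x)
}

# Evaluation ------------------------------------------------------------------

#' Evaluate placed bases against a reference structure
#'
#' A placed base counts as correct when its C1' lies within `c1p_max`
#' (default 1 A) of the best-matching reference residue's C1' and the RMSD
#' over the atoms common to all bases of its kind is below `rmsd_max`
#' (default 1.0 A). Distances honour lattice periodicity when a cell is
#' supplied.
#'
#' @param fits Tibble of placed base fits (with `kind` and `coords`).
#' @param reference A reference structure: path to a PDB file, or the atom
#'   tibble produced by [build_duplex()].
#' @param cell Optional [unit_cell()] for periodic-aware distances.
#' @param c1p_max,rmsd_max Correctness radii in Angstrom.
#' @return A tibble of per-fit verdicts (`kind`, matched residue, `c1p_err`,
#'   `rmsd`, `correct`) with a summary attribute (`n_tp` distinct reference
#'   residues recovered, `n_fp` fits matching no residue, per-kind totals)
#'   retrievable with `attr(x, "summary")`.
#' @export
evaluate_bases <- function(fits, reference, cell = NULL,
                           c1p_max = 1.0, rmsd_max = 1.0) {
  res <- reference_residues(reference)
  if (!nrow(fits)) {
    out <- tibble::tibble(kind = character(), residue = character(),
                          c1p_err = double(), rmsd = double(),
                          correct = logical())
    attr(out, "summary") <- list(n_tp = 0L, n_fp = 0L)
    return(out)
  }
  dist_fun <- function(a, b) {
    if (is.null(cell)) sqrt(sum((a - b)^2)) else min_image_dist(cell, a, b)
  }
  rows <- lapply(seq_len(nrow(fits)), function(i) {
    kind <- fits$kind[i]
    coords <- fits$coords[[i]]
    tmpl <- base_template(kind)
    cands <- Filter(function(r) r$kind == kind, res)
    best <- NULL
    for (r in cands) {
      if (!("C1'" %in% rownames(r$xyz))) next
      c1e <- dist_fun(coords["C1'", ], r$xyz["C1'", ])
      if (is.null(best) || c1e < best$c1e) best <- list(r = r, c1e = c1e)
    }
    if (is.null(best)) {
      return(tibble::tibble(kind = kind, residue = NA_character_,
                            c1p_err = NA_real_, rmsd = NA_real_,
                            correct = FALSE))
    }
    com <- intersect(tmpl$common_atoms, rownames(best$r$xyz))
    dv <- coords[com, , drop = FALSE] - best$r$xyz[com, , drop = FALSE]
    if (!is.null(cell)) {
      df <- coord_matrix(cart_to_frac(cell, dv))
      df <- df - round(df)
      dv <- coord_matrix(frac_to_cart(cell, df))
    }
    rmsd <- sqrt(mean(rowSums(dv^2)))
    tibble::tibble(kind = kind, residue = best$r$label,
                   c1p_err = best$c1e, rmsd = rmsd,
                   correct = best$c1e < c1p_max && rmsd < rmsd_max)
  })
  out <- dplyr::bind_rows(rows)
  tp_res <- unique(out$residue[out$correct])
  attr(out, "summary") <- list(
    n_tp = length(tp_res),
    n_fp = sum(!out$correct),
    by_kind = table(out$kind[out$correct])
  )
  out
}

# Normalize a reference structure into a list of residues, each with a
# named coordinate matrix, a purine/pyrimidine kind and a label.
reference_residues <- function(reference) {
  at <- reference_atoms(reference)
  split_keys <- paste(at$chain, at$resno)
  lapply(split(at, factor(split_keys, unique(split_keys))), function(d) {
    xyz <- as.matrix(d[, c("x", "y", "z")])
    rownames(xyz) <- d$name
    kind <- if ("N9" %in% d$name) "purine" else "pyrimidine"
    list(xyz = xyz, kind = kind,
         label = paste0(d$chain[1], d$resno[1]))
  })
}

# atoms tibble (chain, resno, name, x, y, z) from a path or tibble
reference_atoms <- function(reference) {
  if (is.character(reference) && length(reference) == 1) {
    pdb <- bio3d::read.pdb(reference)
    a <- pdb$atom
    tibble::tibble(chain = a$chain, resno = a$resno, name = a$elety,
                   x = a$x, y = a$y, z = a$z)
  } else if (is.data.frame(reference)) {
    tibble::as_tibble(reference[, c("chain", "resno", "name", "x", "y", "z")])
  } else {
    stop("reference must be a PDB path or an atom data frame", call. = FALSE)
  }
}
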