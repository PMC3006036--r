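# package-level cache for deterministic, lazily built geometry
.nucleo_env <- new.env(parent = emptyenv())

#' Ideal Watson-Crick pair geometry
#'
#' Builds the canonical G:C-type pair used by the duplex generator: the
#' purine template stays in its canonical frame and the pyrimidine is posed
#' by a deterministic geometric construction (N3 placed along the purine
#' N1-H direction at the target hydrogen-bond distance, lone-pair
#' anti-aligned) followed by a rigid-body polish that maximizes the
#' Watson-Crick score while penalising steric clashes. The result is
#' expressed in a pair frame with the C1'-C1' midpoint at the origin and
#' the C1'-C1' line along y (purine on the -y side), base plane z = 0.
#'
#' @return A list with named coordinate matrices `purine` and `pyrimidine`,
#'   the pair `wc_score`, and `c1c1` (the C1'-C1' distance).
#' @export
ideal_pair <- function() {
  if (!is.null(.nucleo_env$ideal_pair)) return(.nucleo_env$ideal_pair)
  pu <- template_coords(base_template("purine"))
  py0 <- template_coords(base_template("pyrimidine"))
  # geometric init: N3 of the pyrimidine along the purine N1-H direction
  hdir <- drop(donor_hydrogens(pu, base_template("purine")$hbond$donors$N1,
                               c(0, 0, 1))) - pu["N1", ]
  hdir <- hdir / sqrt(sum(hdir^2))
  n3_target <- pu["N1", ] + 2.90 * hdir
  lp <- py0["N3", ] - colMeans(py0[c("C2", "C4"), ])
  lp <- lp / sqrt(sum(lp^2))
  variants <- lapply(c(FALSE, TRUE), function(flip) {
    X <- py0
    if (flip) {
      # rotate 180 degrees about the in-plane lone-pair axis through N3
      ax <- lp
      Xc <- sweep(X, 2, py0["N3", ])
      X <- t(apply(Xc, 1, function(v) {
        2 * sum(v * ax) * ax - v
      }))
      dimnames(X) <- dimnames(py0)
      X <- sweep(X, 2, py0["N3", ], `+`)
    }
    lp2 <- X["N3", ] - colMeans(X[c("C2", "C4"), ])
    ang <- atan2(-hdir[2], -hdir[1]) - atan2(lp2[2], lp2[1])
    R <- rot_z(ang)
    X <- sweep(X, 2, X["N3", ]) %*% t(R)
    X <- sweep(X, 2, n3_target, `+`)
    dimnames(X) <- dimnames(py0)
    X
  })
  # the polish is restricted to in-plane motion (rotation about z plus x/y
  # translation) so both bases stay exactly coplanar: the fixture helix is
  # built from flat pairs (no propeller twist)
  polish <- function(X0) {
    ctr <- colMeans(X0)
    place <- function(p) {
      X <- sweep(sweep(X0, 2, ctr) %*% t(rot_z(p[1])), 2,
                 ctr + c(p[2], p[3], 0), `+`)
      dimnames(X) <- dimnames(X0)
      X
    }
    obj <- function(p) {
      X <- place(p)
      sc <- wc_score(pu, X)$wc_score
      # steric penalty: non-bonded heavy atoms should stay apart
      dmat <- as.matrix(stats::dist(rbind(pu, X)))
      cross <- dmat[seq_len(nrow(pu)), nrow(pu) + seq_len(nrow(X))]
      clash <- sum(pmax(0, 2.6 - cross)^2)
      -sc + 10 * clash
    }
    opt <- stats::optim(rep(0, 3), obj, method = "Nelder-Mead",
                        control = list(maxit = 600, reltol = 1e-10))
    list(X = place(opt$par), value = opt$value)
  }
  fits <- lapply(variants, polish)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  py <- best$X
  # move into the pair frame: C1'-C1' midpoint at origin, line along +y
  # (purine at -y), plane z = 0
  mid <- (pu["C1'", ] + py["C1'", ]) / 2
  yax <- py["C1'", ] - pu["C1'", ]
  yax <- yax / sqrt(sum(yax^2))
  zax <- c(0, 0, 1)
  xax <- cross3(yax, zax); xax <- xax / sqrt(sum(xax^2))
  zax <- cross3(xax, yax)
  B <- rbind(xax, yax, zax)
  tr <- function(X) {
    out <- sweep(X, 2, mid) %*% t(B)
    dimnames(out) <- dimnames(X)
    out
  }
  pu2 <- tr(pu); py2 <- tr(py)
  res <- list(purine = pu2, pyrimidine = py2,
              wc_score = wc_score(pu2, py2)$wc_score,
              c1c1 = sqrt(sum((pu2["C1'", ] - py2["C1'", ])^2)))
  .nucleo_env$ideal_pair <- res
  res
}

# one-step helix operator: rotation by twist about z plus rise along z
helix_step <- function(p, twist_deg, rise, j = 1) {
  ang <- j * twist_deg * pi / 180
  drop(rot_z(ang) %*% p) + c(0, 0, j * rise)
}

# dyad: 180-degree rotation about the pair-frame x axis
dyad_flip <- function(p) c(p[1], -p[2], -p[3])

# Solve the phosphate position (residue frame) so the two step distances
# hit their targets and the glycosidic-N distances are symmetric; weak
# pulls toward the reference step angles select the physical branch.
solve_backbone_p <- function(twist_deg, rise, t3, t5, ang1, ang2, n0) {
  key <- paste0("p_", twist_deg, "_", rise, "_", t3, "_", t5)
  if (!is.null(.nucleo_env[[key]])) return(.nucleo_env[[key]])
  pair <- ideal_pair()
  c0 <- pair$purine["C1'", ]                      # strand-1 C1' in frame
  obj <- function(p) {
    hp <- helix_step(p, twist_deg, rise)
    d5 <- sqrt(sum((p - c0)^2))
    d3 <- sqrt(sum((hp - c0)^2))
    dn5 <- sqrt(sum((p - n0)^2))
    dn3 <- sqrt(sum((hp - n0)^2))
    # angle (C1'_{i-1}, P_i, C1'_i) at P and (P_i, C1'_i, P_{i+1}) at C1'
    cm1 <- helix_step(c0, twist_deg, rise, -1)
    a1 <- vangle(cm1 - p, c0 - p)
    pp1 <- helix_step(p, twist_deg, rise)
    a2 <- vangle(p - c0, pp1 - c0)
    10 * ((d5 - t5)^2 + (d3 - t3)^2) + 0.5 * (dn5 - dn3)^2 +
      0.002 * ((a1 - ang1)^2 + (a2 - ang2)^2)
  }
  init <- helix_step(c0 * (8.8 / sqrt(sum(c0[1:2]^2) + 1e-9)),
                     -twist_deg / 2, rise, 1) - c(0, 0, 1.5 * rise)
  opt <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  opt <- stats::optim(opt$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  .nucleo_env[[key]] <- opt$par
  opt$par
}

#' Build an ideal double-helical duplex
#'
#' Places generic purine/pyrimidine bases (guanine and cytosine skeletons,
#' including C1') as ideal Watson-Crick pairs on a regular helix, with an
#' antiparallel complementary strand, full phosphate groups (P plus four
#' oxygens at 1.56 A in tetrahedral directions) and a minimal two-atom
#' pseudo-sugar bridge between each C1' and its 5' phosphate. The phosphate
#' position is solved so the per-step C1'-anchored distances reproduce the
#' reference geometry of the requested helical family (B: 4.29 / 5.14 A;
#' A: 4.77 / 5.34 A) with symmetric glycosidic-N distances. Purines stand
#' in for A/G and pyrimidines for C/T/U: base identity beyond the
#' purine/pyrimidine kind is not modelled.
#'
#' @param sequence Character string over A, C, G, T, U: the 5' to 3'
#'   sequence of strand 1.
#' @param conformation `"B"` (default) or `"A"`.
#' @param rise,twist Helical rise (A) and twist (degrees) per residue;
#'   defaults 3.38 / 36 for B, 2.56 / 32.7 for A.
#' @return An object of class `duplex_scene`: a list with `atoms` (tibble:
#'   `chain`, `resno`, `resid`, `name`, `element`, `Z`, `x`, `y`, `z`,
#'   `b`), the `sequence`, helix parameters, and `n_res`.
#' @export
build_duplex <- function(sequence, conformation = c("B", "A"),
                         rise = NULL, twist = NULL) {
  conformation <- match.arg(conformation)
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  if (!length(seq_chars) || !all(seq_chars %in% c("A", "C", "G", "T", "U"))) {
    stop("sequence must be a nonempty string over A, C, G, T, U", call. = FALSE)
  }
  if (is.null(rise)) rise <- if (conformation == "B") 3.38 else 2.56
  if (is.null(twist)) twist <- if (conformation == "B") 36 else 32.7
  if (rise <= 0) stop("rise must be positive", call. = FALSE)
  if (twist <= 0 || twist >= 360) stop("twist must be in (0, 360)", call. = FALSE)
  ref <- reference_table(if (conformation == "B") "B" else "A")
  t3 <- ref$mean[ref$quantity == "d_c1_3p"][1]
  t5 <- ref$mean[ref$quantity == "d_5p_c1"][1]
  ang1 <- ref$mean[ref$quantity == "ang_c1_p_c1"][1]
  ang2 <- ref$mean[ref$quantity == "ang_p_c1_p"][1]
  pair <- ideal_pair()
  n <- length(seq_chars)
  purine1 <- seq_chars %in% c("A", "G")
  n0 <- pair$purine["N9", ]
  p0 <- solve_backbone_p(twist, rise, t3, t5, ang1, ang2, n0)
  c0_1 <- pair$purine["C1'", ]          # strand-1 C1' (identical both kinds)
  base_coords <- function(j, strand) {
    pu_here <- if (strand == 1) purine1[j + 1] else !purine1[j + 1]
    X <- if (pu_here) pair$purine else pair$pyrimidine
    # the pair frame holds the purine on the -y side, which is strand 1's
    # side; when the step's purine belongs to strand 2 the whole pair is
    # flipped about the dyad (x) axis
    if (!purine1[j + 1]) X <- t(apply(X, 1, dyad_flip))
    dimnames(X) <- if (pu_here) dimnames(pair$purine) else dimnames(pair$pyrimidine)
    out <- t(apply(X, 1, helix_step, twist_deg = twist, rise = rise, j = j))
    dimnames(out) <- dimnames(X)
    out
  }
  rows <- list()
  add_atoms <- function(chain, resno, resid, X, bfac = 15) {
    nm <- rownames(X)
    el <- vapply(nm, atom_element, character(1))
    rows[[length(rows) + 1]] <<- tibble::tibble(
      chain = chain, resno = resno, resid = resid, name = nm,
      element = el, Z = unname(.element_z[el]),
      x = X[, 1], y = X[, 2], z = X[, 3], b = bfac)
  }
  resid_of <- function(ch) paste0("D", ch)
  comp <- c(A = "T", T = "A", G = "C", C = "G", U = "A")
  # strand 1: residues j = 0..n-1 read 5'->3'
  c1_1 <- t(vapply(0:(n - 1), function(j)
    helix_step(c0_1, twist, rise, j), numeric(3)))
  p_1 <- t(vapply(0:(n - 1), function(j)
    helix_step(p0, twist, rise, j), numeric(3)))
  # strand 2 (antiparallel): residue at step j, 5'->3' runs j = n-1 .. 0
  c0_2 <- dyad_flip(c0_1)
  p0_2 <- dyad_flip(p0)
  c1_2 <- t(vapply(0:(n - 1), function(j)
    helix_step(c0_2, twist, rise, j), numeric(3)))
  p_2 <- t(vapply(0:(n - 1), function(j)
    helix_step(p0_2, twist, rise, j), numeric(3)))
  phosphate_atoms <- function(P, c1_own, c1_prev) {
    e1 <- c1_own - P; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c1_prev - P; e2 <- e2 / sqrt(sum(e2^2))
    a <- e1 + e2; a <- a / sqrt(sum(a^2))
    b <- e1 - e2; b <- b / sqrt(sum(b^2))
    cc <- cross3(a, b)
    ct <- cos(54.735 * pi / 180); st <- sin(54.735 * pi / 180)
    dirs <- rbind("O5'" = ct * a + st * b,
                  "O3'" = ct * a - st * b,
                  OP1 = -ct * a + st * cc,
                  OP2 = -ct * a - st * cc)
    X <- sweep(1.56 * dirs, 2, P, `+`)
    rbind(P = P, X)
  }
  # two pseudo-sugar carbons bridging C1' to its 5' phosphate, displaced
  # radially outward (away from the helix axis, like a real sugar ring)
  # so they stay clear of the base-ring blob spheres
  bridge_atoms <- function(P, C1) {
    d <- P - C1
    mid1 <- C1 + 0.45 * d
    mid2 <- C1 + 0.75 * d
    radial <- function(p) {
      r <- c(p[1], p[2], 0)
      n <- sqrt(sum(r^2))
      if (n < 1e-9) c(0, 0, 0) else r / n
    }
    rbind("C4'" = mid1 + 0.8 * radial(mid1),
          "C5'" = mid2 + 0.8 * radial(mid2))
  }
  # atoms are emitted in 5'->3' order for each chain
  for (j in 0:(n - 1)) {
    ch1_res <- j + 1                     # strand 1 residue number 5'->3'
    add_atoms("A", ch1_res, resid_of(seq_chars[j + 1]),
              base_coords(j, 1))
    if (j >= 1) {
      add_atoms("A", ch1_res, resid_of(seq_chars[j + 1]),
                phosphate_atoms(p_1[j + 1, ], c1_1[j + 1, ], c1_1[j, ]))
      add_atoms("A", ch1_res, resid_of(seq_chars[j + 1]),
                bridge_atoms(p_1[j + 1, ], c1_1[j + 1, ]))
    }
  }
  for (j in (n - 1):0) {
    ch2_res <- n - j                     # strand 2 numbering runs 5'->3'
    add_atoms("B", ch2_res, resid_of(comp[seq_chars[j + 1]]),
              base_coords(j, 2))
    if (j <= n - 2) {
      add_atoms("B", ch2_res, resid_of(comp[seq_chars[j + 1]]),
                phosphate_atoms(p_2[j + 1, ], c1_2[j + 1, ], c1_2[j + 2, ]))
      add_atoms("B", ch2_res, resid_of(comp[seq_chars[j + 1]]),
                bridge_atoms(p_2[j + 1, ], c1_2[j + 1, ]))
    }
  }
  atoms <- dplyr::bind_rows(rows)
  structure(list(atoms = atoms, sequence = sequence,
                 conformation = conformation, rise = rise, twist = twist,
                 n_res = 2L * n),
            class = "duplex_scene")
}

#' @export
print.duplex_scene <- function(x, ...) {
  cat(sprintf("<duplex_scene> %s-form, %d nt duplex (%d atoms)\n",
              x$conformation, x$n_res, nrow(x$atoms)))
  invisible(x)
}

#' Write a scene as a PDB file
#'
#' @param scene A `duplex_scene` or an atom tibble with `chain`, `resno`,
#'   `resid`, `name`, `element`, `x`, `y`, `z` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scene_pdb <- function(scene, path) {
  at <- if (inherits(scene, "duplex_scene")) scene$atoms else scene
  n <- nrow(at)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = rep("ATOM", n),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   elety = at$name, eleno = seq_len(n),
                   o = rep(1, n), b = if (!is.null(at$b)) at$b else rep(15, n),
                   elesy = at$element)
  invisible(path)
}

#' Translate a scene into a padded orthorhombic cell
#'
#' Shifts the atom coordinates so the scene sits `padding` Angstrom away
#' from every cell face and returns the matching [unit_cell()].
#'
#' @param scene A `duplex_scene` or atom tibble.
#' @param padding Clearance to each cell face in Angstrom (default 5).
#' @return A list with the shifted `atoms` tibble, the `cell`, and the
#'   applied `shift`.
#' @export
place_scene <- function(scene, padding = 5) {
  at <- if (inherits(scene, "duplex_scene")) scene$atoms else tibble::as_tibble(scene)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  lo <- apply(xyz, 2, min); hi <- apply(xyz, 2, max)
  shift <- padding - lo
  ext <- hi - lo + 2 * padding
  at$x <- at$x + shift[1]; at$y <- at$y + shift[2]; at$z <- at$z + shift[3]
  list(atoms = at, cell = unit_cell(ext[1], ext[2], ext[3]), shift = shift)
}

#' Render a synthetic electron-density map from atoms
#'
#' Each atom contributes `Z * exp(-r^2 / (2 w^2))` with `w = k * resolution`
#' (default k = 0.425, chosen so that adjacent ring atoms merge into a
#' connected ring at 2.5 A resolution while staying resolved near 1 A).
#' Contributions are summed with periodic wrapping on the cell and the map
#' is then normalized to unit standard deviation.
#'
#' @param atoms An atom tibble with `Z`, `x`, `y`, `z` (e.g. from
#'   [build_duplex()] after [place_scene()]), or a `duplex_scene`.
#' @param cell A [unit_cell()]. If `NULL` the scene is translated into a
#'   padded box (see [place_scene()]) and the shift is stored in the
#'   `"scene_shift"` attribute of the result.
#' @param resolution Nominal resolution in Angstrom.
#' @param spacing Target grid spacing in Angstrom (must satisfy
#'   `resolution >= 2 * spacing`).
#' @param padding Cell padding used when `cell` is `NULL`.
#' @param k Gaussian width constant: `w = k * resolution`.
#' @param normalize Normalization of the summed map: `"sd"` divides by the
#'   standard deviation over the grid (the definition used for real maps),
#'   `"atomic"` scales so that an isolated carbon atom peaks at
#'   `carbon_peak` sigma, and `"none"` leaves raw sums. A synthetic cell is
#'   mostly empty, so `"sd"` scaling would give atomic peaks of tens of
#'   sigma, unlike experimental maps whose solvent and noise keep atomic
#'   peaks at a few sigma; `"atomic"` reproduces that experimental contrast
#'   and is what the shipped fixtures use.
#' @param carbon_peak Peak height (sigma) of an isolated carbon under
#'   `"atomic"` scaling. Default 3.
#' @return A [density_grid()].
#' @export
render_map <- function(atoms, cell = NULL, resolution = 1.5, spacing = 0.4,
                       padding = 5, k = 0.425,
                       normalize = c("sd", "atomic", "none"),
                       carbon_peak = 3) {
  normalize <- if (is.logical(normalize)) {
    if (normalize) "sd" else "none"
  } else match.arg(normalize)
  if (inherits(atoms, "duplex_scene")) atoms <- atoms$atoms
  if (resolution < 2 * spacing) {
    stop("resolution must be at least twice the grid spacing", call. = FALSE)
  }
  shift <- c(0, 0, 0)
  if (is.null(cell)) {
    pl <- place_scene(atoms, padding)
    atoms <- pl$atoms; cell <- pl$cell; shift <- pl$shift
  }
  dims <- pmax(8L, as.integer(ceiling(c(cell$a, cell$b, cell$c) / spacing)))
  map <- density_grid(array(0, dims), cell)
  w <- k * resolution
  rcut <- 4 * w
  offs <- sphere_offsets(map, rcut)
  v <- numeric(prod(dims))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  for (i in seq_len(nrow(atoms))) {
    g <- gather_sphere(map, xyz[i, ], rcut, offs)
    v[g$idx] <- v[g$idx] + atoms$Z[i] * exp(-g$dist^2 / (2 * w^2))
  }
  map$values <- array(v, dims)
  if (normalize == "sd") {
    map <- normalize_density(map)
  } else if (normalize == "atomic") {
    map$values <- map$values * (carbon_peak / 6)
    map$normalized <- TRUE
  }
  attr(map, "scene_shift") <- shift
  map
}

#' Add seeded Gaussian noise to a normalized map
#'
#' @param map A normalized [density_grid()].
#' @param noise_sd Noise standard deviation in sigma units of the input
#'   map. Zero returns the map unchanged.
#' @param seed Integer seed; the same seed always produces the same map.
#' @return The noisy map, renormalized to unit standard deviation.
#' @export
add_noise <- function(map, noise_sd, seed = 1L) {
  stopifnot(inherits(map, "density_grid"), noise_sd >= 0)
  if (noise_sd == 0) return(map)
  if (!isTRUE(map$normalized)) stop("add_noise() expects a normalized map",
                                    call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  map$values <- map$values + array(stats::rnorm(prod(map$dims), 0, noise_sd),
                                   map$dims)
  normalize_density(map)
}

#' Named test fixtures
#'
#' Deterministic scenes with rendered maps used across the test-suite and
#' the worked examples:
#' `"one_base"` (a single purine), `"gc_pair"` (one ideal Watson-Crick
#' pair), `"b8mer"` / `"a8mer"` (GCGCGCGC duplexes, 16 nt, B- and A-form),
#' and `"phos_field"` (five tetrahedral phosphate groups plus five lone
#' carbon atoms, all at least 6 A apart).
#'
#' @param name Fixture name.
#' @param resolution,spacing Rendering parameters (A); defaults 1.5 / 0.4.
#' @param noise Optional noise level in sigma units (default 0).
#' @param seed Seed for the noise.
#' @return A list with `name`, `atoms` (cell-placed), `cell`, `map`
#'   (normalized, and modified at the default 4 sigma cap), and for
#'   structure-backed fixtures `ref` (the reference atom tibble, same frame
#'   as the map).
#' @export
make_fixture <- function(name = c("one_base", "gc_pair", "b8mer", "a8mer",
                                  "phos_field"),
                         resolution = 1.5, spacing = 0.4, noise = 0,
                         seed = 1L) {
  name <- match.arg(name)
  scene <- switch(
    name,
    one_base = {
      X <- template_coords(base_template("purine"))
      nm <- rownames(X)
      el <- vapply(nm, atom_element, character(1))
      tibble::tibble(chain = "A", resno = 1L, resid = "DG", name = nm,
                     element = el, Z = unname(.element_z[el]),
                     x = X[, 1], y = X[, 2], z = X[, 3], b = 15)
    },
    gc_pair = {
      pr <- ideal_pair()
      X <- rbind(pr$purine, pr$pyrimidine)
      nm <- c(rownames(pr$purine), rownames(pr$pyrimidine))
      el <- vapply(nm, atom_element, character(1))
      tibble::tibble(chain = c(rep("A", nrow(pr$purine)),
                               rep("B", nrow(pr$pyrimidine))),
                     resno = 1L,
                     resid = rep(c("DG", "DC"),
                                 c(nrow(pr$purine), nrow(pr$pyrimidine))),
                     name = nm, element = el, Z = unname(.element_z[el]),
                     x = X[, 1], y = X[, 2], z = X[, 3], b = 15)
    },
    b8mer = build_duplex("GCGCGCGC", "B")$atoms,
    a8mer = build_duplex("GCGCGCGC", "A")$atoms,
    phos_field = phos_field_atoms()
  )
  pl <- place_scene(scene, padding = 5)
  map <- render_map(pl$atoms, cell = pl$cell, resolution = resolution,
                    spacing = spacing, normalize = "atomic")
  if (noise > 0) map <- add_noise(map, noise, seed)
  map <- modify_density(map)
  list(name = name, atoms = pl$atoms, cell = pl$cell, map = map,
       ref = pl$atoms)
}

# five PO4 groups (varied orientations) + five lone carbons, >= 6 A apart
phos_field_atoms <- function() {
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  pos_p <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0), c(0, 0, 8), c(8, 8, 8))
  pos_c <- rbind(c(8, 8, 0), c(8, 0, 8), c(0, 8, 8), c(16, 8, 8), c(8, 16, 8))
  rows <- list()
  for (i in seq_len(nrow(pos_p))) {
    R <- rot_exp(c(0.5, 0.9, 1.3) * i)
    X <- rbind(P = c(0, 0, 0), 1.56 * tet %*% t(R))
    rownames(X) <- c("P", "OP1", "OP2", "O5'", "O3'")
    X <- sweep(X, 2, pos_p[i, ], `+`)
    nm <- rownames(X)
    el <- vapply(nm, atom_element, character(1))
    rows[[length(rows) + 1]] <- tibble::tibble(
      chain = "A", resno = i, resid = "DG", name = nm, element = el,
      Z = unname(.element_z[el]), x = X[, 1], y = X[, 2], z = X[, 3], b = 15)
  }
  for (i in seq_len(nrow(pos_c))) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      chain = "C", resno = i, resid = "LIG", name = "C1", element = "C",
      Z = 6, x = pos_c[i, 1], y = pos_c[i, 2], z = pos_c[i, 3], b = 15)
  }
  dplyr::bind_rows(rows)
}
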