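# Idealized heavy-atom geometry of the two search templates, in a canonical
# frame: ring least-squares plane = z = 0, ring centroid at the origin,
# +x pointing toward C1'. Coordinates are frozen from an MMFF-optimized,
# plane-projected N9-methylguanine / N1-methylcytosine model; bond lengths
# agree with standard base geometry to ~0.01-0.02 A, which is far below the
# placement tolerances used anywhere downstream.

.guanine_xyz <- matrix(c(
  #  x        y        z
   3.1383,  0.0000, 0,   # C1'
   1.7906, -0.5029, 0,   # N9
   1.4126, -1.8202, 0,   # C8
   0.1010, -1.9576, 0,   # N7
  -0.3746, -0.6699, 0,   # C5
   0.6518,  0.2478, 0,   # C4
   0.5730,  1.6000, 0,   # N3
  -0.6560,  2.0415, 0,   # C2
  -0.8947,  3.3775, 0,   # N2
  -1.7692,  1.2248, 0,   # N1
  -1.7293, -0.1634, 0,   # C6
  -2.7523, -0.8408, 0    # O6
), ncol = 3, byrow = TRUE,
  dimnames = list(c("C1'", "N9", "C8", "N7", "C5", "C4", "N3", "C2", "N2",
                    "N1", "C6", "O6"), c("x", "y", "z")))

.cytosine_xyz <- matrix(c(
   2.8017,  0.0000, 0,   # C1'
   1.3490,  0.0026, 0,   # N1
   0.6830,  1.2052, 0,   # C6
  -0.6475,  1.2524, 0,   # C5
  -1.3351, -0.0534, 0,   # C4
  -2.7022, -0.0971, 0,   # N4
  -0.7124, -1.1893, 0,   # N3
   0.6630, -1.2175, 0,   # C2
   1.2665, -2.2879, 0    # O2
), ncol = 3, byrow = TRUE,
  dimnames = list(c("C1'", "N1", "C6", "C5", "C4", "N4", "N3", "C2", "O2"),
                  c("x", "y", "z")))

.element_z <- c(C = 6, N = 7, O = 8, P = 15, H = 1)

atom_element <- function(name) substr(gsub("[^A-Za-z].*$", "", name), 1, 1)

#' Standard base search templates
#'
#' Returns the rigid search template for a generic purine (guanine heavy
#' atoms) or pyrimidine (cytosine heavy atoms), each including the C1'
#' anchor. The template carries, besides the real atoms, a set of dummy
#' positions where *no* density is expected; dummies enter the
#' template-vs-density correlation with an atomic number of -1 and serve two
#' purposes: they stabilise the fitted plane (one dummy 2 A above and below
#' each ring centroid) and they sharpen the purine/pyrimidine contrast (the
#' pyrimidine template additionally carries two in-plane dummies placed
#' where a purine's second ring would sit, so pyrimidine fits into purine
#' density are penalised).
#'
#' @param kind `"purine"` or `"pyrimidine"`.
#' @param dummy_height Height (A) of the out-of-plane dummies above/below
#'   each ring centroid. Default 2.0.
#' @return An object of class `base_template`: a list with `kind`, the atom
#'   tibble (`name`, `element`, `z`, `x`, `y`, `zc`), a dummy-position
#'   matrix, ring-atom names, hydrogen-bond site definitions and the names
#'   of the atoms shared by all bases of the kind (used for RMSD
#'   evaluation).
#' @export
base_template <- function(kind = c("purine", "pyrimidine"),
                          dummy_height = 2.0) {
  kind <- match.arg(kind)
  if (kind == "purine") {
    xyz <- .guanine_xyz
    rings <- list(five = c("N9", "C8", "N7", "C5", "C4"),
                  six = c("C4", "N3", "C2", "N1", "C6", "C5"))
    hbond <- list(
      donors = list(
        N1 = list(donor = "N1", frame = c("C2", "C6"), type = "ring"),
        N2 = list(donor = "N2", frame = "C2", type = "amine")
      ),
      acceptors = "O6"
    )
    common <- c("C1'", "N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  } else {
    xyz <- .cytosine_xyz
    rings <- list(six = c("N1", "C6", "C5", "C4", "N3", "C2"))
    hbond <- list(
      donors = list(
        N4 = list(donor = "N4", frame = "C4", type = "amine")
      ),
      acceptors = c("O2", "N3")
    )
    common <- c("C1'", "N1", "C2", "O2", "N3", "C4", "C5", "C6")
  }
  nm <- rownames(xyz)
  el <- vapply(nm, atom_element, character(1))
  atoms <- tibble::tibble(name = nm, element = el,
                          z = unname(.element_z[el]),
                          x = xyz[, 1], y = xyz[, 2], zc = xyz[, 3])
  dummies <- do.call(rbind, lapply(rings, function(rn) {
    ctr <- colMeans(xyz[rn, , drop = FALSE])
    rbind(ctr + c(0, 0, dummy_height), ctr - c(0, 0, dummy_height))
  }))
  if (kind == "pyrimidine") {
    dummies <- rbind(dummies, purine_contrast_dummies())
  }
  rownames(dummies) <- NULL
  structure(list(kind = kind, atoms = atoms, dummies = dummies,
                 rings = rings, hbond = hbond, common_atoms = common,
                 c1p = "C1'"),
            class = "base_template")
}

# In-plane dummy positions for the pyrimidine template: centroid and far
# vertex of the region a purine's five-membered ring would NOT occupy --
# i.e. where the purine six-ring extends beyond the pyrimidine ring when
# both templates share the glycosidic geometry. Computed by mapping the
# purine frame onto the pyrimidine frame via the C1' position and the
# C1'->N(glycosidic) direction.
purine_contrast_dummies <- function() {
  g <- .guanine_xyz
  cx <- .cytosine_xyz
  # 2-d rigid map: purine C1' -> pyrimidine C1', direction C1'->N9 -> C1'->N1
  vg <- g["N9", 1:2] - g["C1'", 1:2]
  vc <- cx["N1", 1:2] - cx["C1'", 1:2]
  ang <- atan2(vc[2], vc[1]) - atan2(vg[2], vg[1])
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  mapg <- function(p) as.numeric(R %*% (p - g["C1'", 1:2]) + cx["C1'", 1:2])
  six <- c("C4", "N3", "C2", "N1", "C6", "C5")
  ctr6 <- mapg(colMeans(g[six, 1:2, drop = FALSE]))
  far <- mapg(g["O6", 1:2])
  rbind(c(ctr6, 0), c(far, 0))
}

#' @export
print.base_template <- function(x, ...) {
  cat(sprintf("<base_template> %s: %d atoms + C1', %d dummies\n",
              x$kind, nrow(x$atoms) - 1L, nrow(x$dummies)))
  invisible(x)
}

# Canonical-frame coordinates of the real atoms (rows named), Nx3
template_coords <- function(template) {
  m <- as.matrix(template$atoms[, c("x", "y", "zc")])
  rownames(m) <- template$atoms$name
  colnames(m) <- c("x", "y", "z")
  m
}

# Idealized in-plane hydrogen positions for a donor site, given coordinates
# of the (already transformed) template atoms. N-H = 1.01 A; ring N-H along
# the external bisector, sp2 amine H at +-120 degrees from the C-N bond.
donor_hydrogens <- function(coords, donor_spec, normal) {
  N <- coords[donor_spec$donor, ]
  if (donor_spec$type == "ring") {
    mid <- colMeans(coords[donor_spec$frame, , drop = FALSE])
    dir <- N - mid
    dir <- dir - sum(dir * normal) * normal
    dir <- dir / sqrt(sum(dir^2))
    matrix(N + 1.01 * dir, 1, 3)
  } else {
    C <- coords[donor_spec$frame, ]
    axis <- N - C
    axis <- axis - sum(axis * normal) * normal
    axis <- axis / sqrt(sum(axis^2))
    side <- cross3(normal, axis)
    h <- t(vapply(c(1, -1), function(s) {
      dir <- cos(pi / 3) * axis + s * sin(pi / 3) * side
      N + 1.01 * dir / sqrt(sum(dir^2))
    }, numeric(3)))
    h
  }
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
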