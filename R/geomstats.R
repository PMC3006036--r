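#' Extract per-nucleotide P/C1' frames from a structure
#'
#' Reads the nucleic-acid chains of a coordinate file and returns, per
#' residue in deposited (5' to 3') order, the phosphorus position, the C1'
#' anchor, and the glycosidic nitrogen (N9 for purines, N1 for
#' pyrimidines). Residues without a C1' atom are skipped with a warning;
#' alternate locations are resolved to the highest occupancy.
#'
#' @param structure Path to a PDB file, a `bio3d` pdb object, or an atom
#'   data frame with columns `chain, resno, name, x, y, z` (and optionally
#'   `occ`, `insert`).
#' @return A tibble with one row per nucleotide: `chain`, `resno`,
#'   `Px, Py, Pz` (NA when the residue has no phosphate), `C1x..C1z`, and
#'   `Nx..Nz` (glycosidic nitrogen, NA if absent).
#' @export
extract_frames <- function(structure) {
  at <- frames_atoms(structure)
  if (!nrow(at)) return(empty_frames())
  keys <- paste(at$chain, at$resno, at$insert)
  at$key <- factor(keys, levels = unique(keys))
  res <- split(at, at$key)
  rows <- lapply(res, function(d) {
    pick <- function(nm) {
      m <- d[d$name == nm, , drop = FALSE]
      if (!nrow(m)) return(c(NA_real_, NA_real_, NA_real_))
      m <- m[order(-m$occ), , drop = FALSE]
      unname(c(m$x[1], m$y[1], m$z[1]))
    }
    c1 <- pick("C1'")
    if (any(is.na(c1))) return(NULL)
    n9 <- pick("N9")
    nref <- if (!any(is.na(n9))) n9 else pick("N1")
    p <- pick("P")
    tibble::tibble(chain = d$chain[1], resno = d$resno[1],
                   Px = p[1], Py = p[2], Pz = p[3],
                   C1x = c1[1], C1y = c1[2], C1z = c1[3],
                   Nx = nref[1], Ny = nref[2], Nz = nref[3])
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    warning("no nucleic-acid residues with C1' atoms found")
    return(empty_frames())
  }
  if (dropped > 0) {
    warning(dropped, " residue(s) without a C1' atom skipped")
  }
  out
}

empty_frames <- function() {
  tibble::tibble(chain = character(), resno = integer(),
                 Px = double(), Py = double(), Pz = double(),
                 C1x = double(), C1y = double(), C1z = double(),
                 Nx = double(), Ny = double(), Nz = double())
}

frames_atoms <- function(structure) {
  if (is.character(structure) && length(structure) == 1) {
    structure <- bio3d::read.pdb(structure)
  }
  if (inherits(structure, "pdb")) {
    a <- structure$atom
    out <- tibble::tibble(chain = a$chain, resno = a$resno,
                          insert = ifelse(is.na(a$insert), "", a$insert),
                          name = a$elety, x = a$x, y = a$y, z = a$z,
                          occ = ifelse(is.na(a$o), 1, a$o))
  } else if (is.data.frame(structure)) {
    out <- tibble::as_tibble(structure)
    if (!"insert" %in% names(out)) out$insert <- ""
    if (!"occ" %in% names(out)) out$occ <- 1
    out <- out[, c("chain", "resno", "insert", "name", "x", "y", "z", "occ")]
  } else {
    stop("structure must be a PDB path, bio3d pdb object or atom data frame",
         call. = FALSE)
  }
  out$chain[is.na(out$chain)] <- ""
  out
}

vangle <- function(a, b) {
  ct <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Torsion (dihedral) angle of four points
#'
#' IUPAC sign convention: looking from atom 2 to atom 3, the angle is
#' positive when the far bond (3-4) is rotated clockwise from the near bond
#' (2-1). Returns NA when any three consecutive points are collinear (the
#' torsion is then undefined).
#'
#' @param p1,p2,p3,p4 Cartesian positions (length-3 vectors).
#' @return The torsion in degrees in (-180, 180], or NA if degenerate.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16) return(NA_real_)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  res <- -atan2(y, x) * 180 / pi
  if (res <= -180) res + 360 else res
}

#' Per-step backbone geometry of a P/C1' chain
#'
#' For every nucleotide i (per chain, read 5' to 3' as deposited) computes
#' the distances `d(C1'_i -> P_{i+1})` (to the 3' phosphate) and
#' `d(P_i -> C1'_i)` (from the 5' phosphate), the angles at P
#' (`C1'_{i-1}, P_i, C1'_i`) and at C1' (`P_i, C1'_i, P_{i+1}`), and the
#' pseudo-torsions `eta' = torsion(C1'_{i-1}, P_i, C1'_i, P_{i+1})` and
#' `theta' = torsion(P_i, C1'_i, P_{i+1}, C1'_{i+1})`. These are the
#' classical eta/theta pseudo-torsions with C1' taking the place of C4':
#' the C1' is rigidly tied to the fitted base while the sugar ring (and so
#' C4') is flexible and often poorly resolved.
#'
#' @param frames Frame tibble from [extract_frames()].
#' @return A tibble with one row per nucleotide: `chain`, `resno`,
#'   `d_c1_3p`, `d_5p_c1`, `ang_c1_p_c1`, `ang_p_c1_p`, `eta`, `theta`,
#'   plus the N-anchored distances `d_n_3p` and `d_5p_n` used for the
#'   direction-asymmetry comparison. Quantities whose defining atoms are
#'   missing are NA.
#' @export
backbone_geometry <- function(frames) {
  dplyr::bind_rows(lapply(split(frames, factor(frames$chain,
                                               unique(frames$chain))),
                          chain_geometry))
}

chain_geometry <- function(fr) {
  n <- nrow(fr)
  P <- as.matrix(fr[, c("Px", "Py", "Pz")])
  C1 <- as.matrix(fr[, c("C1x", "C1y", "C1z")])
  Nr <- as.matrix(fr[, c("Nx", "Ny", "Nz")])
  get <- function(M, i) if (i >= 1 && i <= n) M[i, ] else rep(NA_real_, 3)
  dd <- function(a, b) if (any(is.na(a)) || any(is.na(b))) NA_real_
                       else sqrt(sum((a - b)^2))
  aa <- function(a, b, c) {
    if (any(is.na(c(a, b, c)))) return(NA_real_)
    vangle(a - b, c - b)
  }
  tt <- function(a, b, c, d) {
    if (any(is.na(c(a, b, c, d)))) return(NA_real_)
    torsion_angle(a, b, c, d)
  }
  rows <- lapply(seq_len(n), function(i) {
    tibble::tibble(
      chain = fr$chain[i], resno = fr$resno[i],
      d_c1_3p = dd(get(C1, i), get(P, i + 1)),
      d_5p_c1 = dd(get(P, i), get(C1, i)),
      d_n_3p = dd(get(Nr, i), get(P, i + 1)),
      d_5p_n = dd(get(P, i), get(Nr, i)),
      ang_c1_p_c1 = aa(get(C1, i - 1), get(P, i), get(C1, i)),
      ang_p_c1_p = aa(get(P, i), get(C1, i), get(P, i + 1)),
      eta = tt(get(C1, i - 1), get(P, i), get(C1, i), get(P, i + 1)),
      theta = tt(get(P, i), get(C1, i), get(P, i + 1), get(C1, i + 1))
    )
  })
  dplyr::bind_rows(rows)
}

#' Eta'/theta' pseudo-torsions
#'
#' Convenience accessor returning just the pseudo-torsion pairs from
#' [backbone_geometry()].
#'
#' @inheritParams backbone_geometry
#' @return A tibble with `chain`, `resno`, `eta`, `theta` (degrees; NA
#'   where undefined).
#' @export
eta_theta_prime <- function(frames) {
  g <- backbone_geometry(frames)
  g[, c("chain", "resno", "eta", "theta")]
}

#' Assign the backbone direction of a chain
#'
#' The two C1'-anchored distance populations of a nucleic-acid chain are
#' asymmetric: in the 5' to 3' reading the distance from the 5' phosphate
#' to C1' is systematically longer than from C1' to the 3' phosphate (B-DNA
#' reference means 5.14 vs 4.29 A). Reading the chain backwards swaps the
#' two populations, so comparing both hypotheses against the reference
#' means decides the direction.
#'
#' @param geometry A per-step geometry tibble from [backbone_geometry()]
#'   (one chain).
#' @param reference_kind `"A"`, `"B"`, `"Z"` or `"RNA"`.
#' @return A list with `verdict` (`"forward"`, `"reversed"` or
#'   `"indeterminate"`), `margin` (mean squared z-score advantage of the
#'   chosen hypothesis; positive when decided) and the two hypothesis
#'   scores.
#' @export
assign_direction <- function(geometry, reference_kind = c("B", "A", "Z", "RNA")) {
  reference_kind <- match.arg(reference_kind)
  ref <- reference_table(reference_kind)
  dists <- ref[ref$quantity %in% c("d_c1_3p", "d_5p_c1"), , drop = FALSE]
  a <- geometry$d_c1_3p
  b <- geometry$d_5p_c1
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) {
    return(list(verdict = "indeterminate", margin = NA_real_,
                score_forward = NA_real_, score_reversed = NA_real_))
  }
  a <- a[ok]; b <- b[ok]
  zsq <- function(x, quantity) {
    comp <- dists[dists$quantity == quantity, , drop = FALSE]
    # multi-component references (Z-DNA): best-matching component per value
    z2 <- sapply(seq_len(nrow(comp)), function(k) {
      ((x - comp$mean[k]) / comp$sd[k])^2
    })
    if (is.null(dim(z2))) z2 <- matrix(z2, nrow = 1)
    sum(apply(z2, 1, min))
  }
  nsteps <- length(a) + length(b)
  sf <- (zsq(a, "d_c1_3p") + zsq(b, "d_5p_c1")) / nsteps
  sr <- (zsq(a, "d_5p_c1") + zsq(b, "d_c1_3p")) / nsteps
  verdict <- if (sf < sr) "forward" else "reversed"
  list(verdict = verdict, margin = abs(sf - sr),
       score_forward = sf, score_reversed = sr)
}
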