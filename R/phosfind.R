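#' Inversion correlation on a sphere
#'
#' Pearson correlation between the density values at diametrically opposite
#' points on a sphere about a putative phosphorus position. Tetrahedral PO4
#' density has an oxygen peak on one side of the P and a gap on the other
#' for every direction, so the correlation is strongly negative; spherically
#' symmetric density gives +1. Directions are a deterministic spherical
#' Fibonacci lattice; values come from trilinear interpolation of the
#' modified map.
#'
#' @param map A normalized, modified [density_grid()].
#' @param centre Cartesian centre (putative P position).
#' @param radius Sphere radius in Angstrom; default 1.56, the P-O bond
#'   length, so the sampled shell runs through the oxygen peaks.
#' @param n_pairs Number of antipodal direction pairs (default 64).
#' @return Correlation in `[-1, 1]`. If either value list is constant the
#'   correlation is defined as 0 and the result carries
#'   `attr(, "degenerate") = TRUE`.
#' @export
inversion_cc <- function(map, centre, radius = 1.56, n_pairs = 64L) {
  u <- fibonacci_sphere(n_pairs)
  p1 <- sweep(radius * u, 2, centre, `+`)
  p2 <- sweep(-radius * u, 2, centre, `+`)
  v1 <- interp_density(map, p1)
  v2 <- interp_density(map, p2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  stats::cor(v1, v2)
}

# deterministic spherical Fibonacci lattice (n points on the unit sphere)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Tetrahedral phosphate score
#'
#' `P = exp(-k1 * (1 + cc_inv) / sqrt(Q)) + exp(-k2 * (l1 - l3) / l1)`.
#' The first factor rewards inversion anti-correlation, damped by the
#' square root of the blob density sum Q (the square root keeps single
#' heavy atoms, which are strong but not tetrahedral, from scoring high);
#' the second rewards isotropy of the moments eigenvalues. Each term is at
#' most 1, the first reaching it only as `cc_inv = -1` (for finite Q) and
#' the second exactly when `l1 = l3`, so the supremum of P is 2 regardless
#' of the input map.
#'
#' @param Q Positive-density sum of the blob (must be > 0).
#' @param cc_inv Inversion correlation in `[-1, 1]`.
#' @param eigvals Moments eigenvalues (length 3, `l1 >= l2 >= l3`), or the
#'   blob row columns `lambda1..lambda3`.
#' @param k1,k2 Positive shape constants; defaults 12 and 2 (see Details).
#' @return The score P in (0, 2].
#' @export
phosphate_score <- function(Q, cc_inv, eigvals, k1 = 12, k2 = 2) {
  l <- sort(as.numeric(eigvals), decreasing = TRUE)
  if (any(Q <= 0)) stop("degenerate candidate: Q must be positive", call. = FALSE)
  if (l[1] <= 0) stop("degenerate candidate: lambda1 must be positive", call. = FALSE)
  exp(-k1 * (1 + cc_inv) / sqrt(Q)) + exp(-k2 * (l[1] - l[3]) / l[1])
}

#' Rank blobs as phosphate candidates
#'
#' Computes the inversion correlation and the tetrahedral score P for every
#' blob and returns the list in descending order of P (ties broken by blob
#' acceptance order).
#'
#' @param blobs Blob tibble from [find_blobs()].
#' @param map The normalized, modified [density_grid()] the blobs came from.
#' @param k1,k2 Constants of [phosphate_score()].
#' @param radius Inversion-sphere radius (default 1.56 A).
#' @param n_pairs Antipodal pairs for [inversion_cc()].
#' @return A tibble of candidates ordered by decreasing `P`, with `rank`,
#'   `cc_inv` and `P` columns added to the blob columns.
#' @export
rank_phosphates <- function(blobs, map, k1 = 12, k2 = 2,
                            radius = 1.56, n_pairs = 64L) {
  if (!nrow(blobs)) {
    out <- blobs
    out$cc_inv <- double(); out$P <- double(); out$rank <- integer()
    return(out)
  }
  cc <- vapply(seq_len(nrow(blobs)), function(i) {
    as.numeric(inversion_cc(map, c(blobs$x[i], blobs$y[i], blobs$z[i]),
                            radius, n_pairs))
  }, numeric(1))
  P <- vapply(seq_len(nrow(blobs)), function(i) {
    phosphate_score(blobs$Q[i], cc[i],
                    c(blobs$lambda1[i], blobs$lambda2[i], blobs$lambda3[i]),
                    k1, k2)
  }, numeric(1))
  blobs$cc_inv <- cc
  blobs$P <- P
  ord <- order(-P, seq_len(nrow(blobs)))
  out <- blobs[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' Evaluate a ranked phosphate list against reference P atoms
#'
#' A candidate is correct when it lies within `dist_max` (1.5 A,
#' periodic-aware when a cell is given) of a reference P atom not yet
#' claimed by a higher-ranked candidate. For each requested coverage
#' fraction f the relative-number indicator is
#' `r.n.(f) = rank at which ceil(f * N_P) correct candidates have appeared
#' / ceil(f * N_P)`; it equals 1 exactly when no false positive precedes
#' the last counted true positive.
#'
#' @param ranked Ranked candidate tibble from [rank_phosphates()] (or any
#'   tibble with `x, y, z` in rank order; a `P` column is used for the
#'   score summaries when present).
#' @param reference PDB path or atom data frame containing P atoms
#'   (`name == "P"`).
#' @param fractions Coverage percentages, default `c(80, 90, 100)`.
#' @param dist_max Correctness radius in Angstrom (default 1.5).
#' @param cell Optional [unit_cell()] for periodic distances.
#' @return A tibble with one row per fraction (`fraction`, `n_required`,
#'   `rank_needed`, `rn`) plus a `verdicts` attribute (per-candidate
#'   logical) and a `scores` attribute with Table-3-style summaries: top
#'   score, score of the first false positive, mean true-positive score and
#'   mean false-positive score up to the last true positive.
#' @export
evaluate_phosphates <- function(ranked, reference,
                                fractions = c(80, 90, 100),
                                dist_max = 1.5, cell = NULL) {
  if (!nrow(ranked)) stop("ranked candidate list is empty", call. = FALSE)
  at <- reference_atoms(reference)
  pref <- as.matrix(at[at$name == "P", c("x", "y", "z")])
  np <- nrow(pref)
  if (!np) stop("reference contains no P atoms", call. = FALSE)
  claimed <- rep(FALSE, np)
  correct <- logical(nrow(ranked))
  for (i in seq_len(nrow(ranked))) {
    p <- c(ranked$x[i], ranked$y[i], ranked$z[i])
    d <- if (is.null(cell)) sqrt(colSums((t(pref) - p)^2))
         else min_image_dist(cell, matrix(p, nrow(pref), 3, byrow = TRUE), pref)
    d[claimed] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= dist_max) {
      claimed[j] <- TRUE
      correct[i] <- TRUE
    }
  }
  cum_tp <- cumsum(correct)
  rows <- lapply(fractions, function(f) {
    m <- ceiling(f / 100 * np)
    rk <- if (any(cum_tp >= m)) which(cum_tp >= m)[1] else NA_integer_
    tibble::tibble(fraction = f, n_required = m, rank_needed = rk,
                   rn = rk / m)
  })
  out <- dplyr::bind_rows(rows)
  scores <- if ("P" %in% names(ranked)) {
    last_tp <- if (any(correct)) max(which(correct)) else 0L
    first_fp <- which(!correct)[1]
    fp_head <- !correct[seq_len(last_tp)]
    list(
      score_top = ranked$P[1],
      score_first_fp = if (is.na(first_fp)) NA_real_ else ranked$P[first_fp],
      mean_tp = mean(ranked$P[correct]),
      mean_fp = if (any(fp_head)) mean(ranked$P[seq_len(last_tp)][fp_head])
                else NA_real_
    )
  } else NULL
  attr(out, "verdicts") <- correct
  attr(out, "scores") <- scores
  out
}
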