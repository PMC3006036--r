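test_that("base blobs rank by density-sum times planarity", {
  blobs <- tibble::tibble(id = 1:3, Q = c(100, 150, 120),
                          planarity = c(0.5, 0.1, 0))
  r <- rank_base_blobs(blobs)
  expect_equal(r$id[1], 1)                 # 50 beats 15
  expect_equal(r$id[3], 3)                 # isotropic blob last
  # ties keep input order
  b2 <- tibble::tibble(id = 1:2, Q = c(10, 20), planarity = c(0.4, 0.2))
  expect_equal(rank_base_blobs(b2)$id, c(1, 2))
})

test_that("template alignment puts the plane normal on the blob eigenvector", {
  fx <- get_fixture("one_base")
  blobs <- find_blobs(fx$map)
  tm <- base_template("purine")
  inits <- align_template(tm, blobs[1, ])
  expect_length(inits, 2)                  # both faces
  normal_true <- c(0, 0, 1)                # fixture base lies in z = const
  errs <- vapply(inits, function(ini) {
    acos(min(1, abs(sum(ini$R[, 3] * normal_true)))) * 180 / pi
  }, numeric(1))
  expect_lt(min(errs), 10)
  # isotropic blob fails the planarity gate
  iso <- tibble::tibble(x = 1, y = 1, z = 1, planarity = 0.05,
                        eigvecs = list(diag(3)))
  expect_length(align_template(tm, iso), 0)
})

test_that("simplex fitting recovers a clean single base", {
  fx <- get_fixture("one_base")
  blobs <- find_blobs(fx$map)
  fits <- cached("one_base_fits", fit_bases_at_blob(fx$map, blobs[1, ]))
  expect_lte(sum(fits$kind == "purine"), 6)
  expect_lte(sum(fits$kind == "pyrimidine"), 6)
  truth <- as.matrix(fx$atoms[, c("x", "y", "z")])
  rownames(truth) <- fx$atoms$name
  pu <- fits[fits$kind == "purine", ]
  best <- pu$coords[[which.max(pu$S)]]
  rmsd <- sqrt(mean(rowSums((best[rownames(truth), ] - truth)^2)))
  expect_lt(rmsd, 0.4)
  # correct kind wins on S
  expect_gt(max(fits$S[fits$kind == "purine"]),
            max(fits$S[fits$kind == "pyrimidine"]))
})

test_that("correlation is invariant under affine rescaling of the map", {
  fx <- get_fixture("one_base")
  blobs <- find_blobs(fx$map)
  fits <- cached("one_base_fits", fit_bases_at_blob(fx$map, blobs[1, ]))
  f <- fits[which.max(fits$cc), ]
  tm <- base_template(f$kind)
  m2 <- fx$map
  m2$values <- 3.7 * m2$values + 1.2
  cc1 <- nucleoblob:::template_cc(fx$map, tm, f$R[[1]], f$t[[1]])
  cc2 <- nucleoblob:::template_cc(m2, tm, f$R[[1]], f$t[[1]])
  expect_equal(cc1, cc2, tolerance = 1e-9)
})

test_that("fits into pure noise never reach real-base correlation", {
  # fixed-seed noise map; the best of the 24 rotational starts stays well
  # below the correlation of a genuine base fit (recorded oracle: 0.86
  # noise vs > 0.97 real)
  set.seed(123)
  cell <- unit_cell(14)
  m <- modify_density(density_grid(array(stats::rnorm(35^3), c(35, 35, 35)),
                                   cell, normalized = TRUE))
  f <- simplex_fit(m, base_template("purine"),
                   list(R = diag(3), t = c(7, 7, 7)))
  expect_lt(max(f$cc), 0.9)
  fits <- .fixture_cache$one_base_fits
  expect_gt(max(fits$cc), 0.97)
})

test_that("gradient refinement improves a displaced pose and never degrades S", {
  fx <- get_fixture("one_base")
  truth <- as.matrix(fx$atoms[, c("x", "y", "z")])
  rownames(truth) <- fx$atoms$name
  tm <- base_template("purine")
  X <- nucleoblob:::template_coords(tm)
  # true pose: fixture base is the canonical template translated into the box
  shift <- truth["N9", ] - X["N9", ]
  start <- tibble::tibble(kind = "purine", cc = NA, S = NA, converged = TRUE,
                          R = list(diag(3)),
                          t = list(shift + c(0.4, -0.25, 0.15)),
                          coords = list(X))
  ref <- refine_fit(fx$map, start, tm)
  rmsd <- sqrt(mean(rowSums((ref$coords[[1]][rownames(truth), ] - truth)^2)))
  # the displaced start is ~0.5 A off; refinement pulls it to the voxelized
  # density optimum (recorded: ~0.17 A on the clamped 0.4 A-grid map)
  expect_lt(rmsd, 0.25)
  expect_lt(rmsd, 0.5 * sqrt(sum(c(0.4, 0.25, 0.15)^2)))

  # starting at the true pose, S does not decrease
  at_truth <- start; at_truth$t <- list(shift)
  s0 <- nucleoblob:::template_S(fx$map, tm, diag(3), shift)
  ref2 <- refine_fit(fx$map, at_truth, tm)
  expect_gte(ref2$S + 1e-8, s0)

  # flat map: S stays 0 and the pose does not move
  flat <- density_grid(array(0, c(16, 16, 16)), unit_cell(10),
                       normalized = TRUE)
  ref3 <- refine_fit(flat, at_truth, tm)
  expect_equal(ref3$S, 0)
  expect_lt(max(abs(ref3$t[[1]] - shift)), 1e-6)
})

test_that("Watson-Crick scoring behaves at its anchors", {
  pr <- ideal_pair()
  sc <- wc_score(pr$purine, pr$pyrimidine)
  expect_gt(sc$wc_score, 2.5)
  expect_lte(sc$wc_score, 3)
  expect_equal(nrow(sc$bonds), 3)
  expect_true(all(sc$bonds$theta > 140))

  # separated bases: distance moduli dominate, score negative
  far <- pr$pyrimidine
  far[, 1] <- far[, 1] + 15
  expect_lt(wc_score(pr$purine, far)$wc_score, 0)

  # invariant under a global rigid motion
  R <- nucleoblob:::rot_exp(c(0.3, -0.8, 0.5)); tt <- c(3, -2, 7)
  m1 <- sweep(pr$purine %*% t(R), 2, tt, `+`)
  m2 <- sweep(pr$pyrimidine %*% t(R), 2, tt, `+`)
  expect_equal(wc_score(m1, m2)$wc_score, sc$wc_score, tolerance = 1e-9)

  # score never exceeds 3 over random relative poses
  set.seed(5)
  for (i in 1:20) {
    Rr <- nucleoblob:::rot_exp(stats::rnorm(3, 0, 0.4))
    tr <- stats::rnorm(3, 0, 2)
    mm <- sweep(pr$pyrimidine %*% t(Rr), 2, tr, `+`)
    expect_lte(wc_score(pr$purine, mm)$wc_score, 3)
  }

  # missing site atoms raise a typed error
  broken <- pr$pyrimidine[setdiff(rownames(pr$pyrimidine), "N3"), ]
  expect_error(wc_score(pr$purine, broken), "missing hydrogen-bond site")
})

test_that("pairing prunes false bases and keeps unpaired singles", {
  fx <- get_fixture("gc_pair")
  blobs <- find_blobs(fx$map)
  fits <- cached("gc_fits", dplyr::bind_rows(lapply(seq_len(nrow(blobs)),
    function(i) fit_bases_at_blob(fx$map, blobs[i, ]))))
  pairing <- prune_by_pairing(fits)
  expect_equal(nrow(pairing$pairs), 1)
  ev <- evaluate_bases(placed_base_fits(pairing), fx$ref, cell = fx$map$cell)
  expect_true(any(ev$correct[ev$kind == "purine"]))
  expect_true(any(ev$correct[ev$kind == "pyrimidine"]))

  # a threshold above the maximum score never accepts a pair
  p2 <- prune_by_pairing(fits, threshold = 3.1)
  expect_equal(nrow(p2$pairs), 0)
  expect_gt(nrow(p2$singles), 0)
  expect_true(all(p2$singles$unpaired))

  # a single isolated base yields no pairs and one single
  fits1 <- .fixture_cache$one_base_fits
  p1 <- prune_by_pairing(fits1)
  expect_equal(nrow(p1$pairs), 0)
  expect_equal(nrow(p1$singles), 1)
})

test_that("near-identical poses deduplicate to one survivor", {
  fx <- get_fixture("one_base")
  fits <- .fixture_cache$one_base_fits
  f <- fits[1, ]
  shifted <- f
  shifted$coords <- list(f$coords[[1]] + 0.05)
  both <- dplyr::bind_rows(f, shifted)
  expect_equal(nucleoblob:::dedupe_fits(both, 0.3), 1L)
  moved <- f
  moved$coords <- list(f$coords[[1]] + 2)
  expect_equal(nucleoblob:::dedupe_fits(dplyr::bind_rows(f, moved), 0.3),
               c(1L, 2L))
})

test_that("base evaluation applies the C1' and common-atom RMSD criteria", {
  fx <- get_fixture("gc_pair")
  res <- nucleoblob:::reference_residues(fx$ref)
  mk_fit <- function(xyz, kind) {
    tibble::tibble(kind = kind, coords = list(xyz),
                   R = list(diag(3)), t = list(c(0, 0, 0)), S = 1)
  }
  pu <- res[[which(vapply(res, `[[`, character(1), "kind") == "purine")[1]]]
  fits <- mk_fit(pu$xyz, "purine")
  ev <- evaluate_bases(fits, fx$ref)
  expect_true(ev$correct)
  expect_equal(ev$rmsd, 0, tolerance = 1e-12)

  # translated 2 A: incorrect
  ev2 <- evaluate_bases(mk_fit(pu$xyz + 2 / sqrt(3), "purine"), fx$ref)
  expect_false(ev2$correct)

  # rotated 180 degrees in-plane about the ring centroid: the ring overlaps
  # itself but C1' lands far from truth
  ring <- pu$xyz[intersect(rownames(pu$xyz),
                           c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1",
                             "C6")), ]
  ctr <- colMeans(ring)
  Rz <- nucleoblob:::rot_z(pi)
  rot <- sweep(sweep(pu$xyz, 2, ctr) %*% t(Rz), 2, ctr, `+`)
  dimnames(rot) <- dimnames(pu$xyz)
  ev3 <- evaluate_bases(mk_fit(rot, "purine"), fx$ref)
  expect_false(ev3$correct)
  expect_gt(ev3$c1p_err, 1)
})
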