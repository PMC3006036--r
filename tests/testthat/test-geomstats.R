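test_that("frames extract per residue with C1', P and glycosidic N", {
  dx <- build_duplex("GCGCGCGC", "B")
  fr <- extract_frames(dx$atoms)
  expect_equal(nrow(fr), 16)
  expect_equal(sum(!is.na(fr$Px)), 14)   # the two 5' termini lack P
  # round trip through a PDB file
  f <- withr::local_tempfile(fileext = ".pdb")
  write_scene_pdb(dx, f)
  fr2 <- extract_frames(f)
  expect_equal(nrow(fr2), 16)
  expect_equal(fr2$C1x, fr$C1x, tolerance = 1e-3)   # PDB has 3 decimals

  # protein-only input gives an empty result with a warning
  prot <- tibble::tibble(chain = "A", resno = 1:2, name = c("CA", "CA"),
                         x = c(0, 3.8), y = 0, z = 0)
  expect_warning(fr3 <- extract_frames(prot), "C1'|no nucleic")
  expect_equal(nrow(fr3), 0)
})

test_that("alternate locations resolve to the highest occupancy", {
  at <- tibble::tibble(chain = "A", resno = 1,
                       name = c("C1'", "C1'", "N9", "P"),
                       x = c(1, 2, 3, 4), y = 0, z = 0,
                       occ = c(0.3, 0.7, 1, 1))
  fr <- extract_frames(at)
  expect_equal(fr$C1x, 2)
})

test_that("backbone distances and angles match hand geometry", {
  fr <- tibble::tibble(chain = "A", resno = 1:2,
                       Px = c(0, 0), Py = c(0, 0), Pz = c(0, 10),
                       C1x = c(0, 0), C1y = c(0, 0), C1z = c(5.14, 15),
                       Nx = NA_real_, Ny = NA_real_, Nz = NA_real_)
  g <- backbone_geometry(fr)
  expect_equal(g$d_5p_c1[1], 5.14)
  expect_equal(g$d_c1_3p[1], 10 - 5.14)
  expect_equal(g$ang_p_c1_p[1], 180)
})

test_that("the b8mer fixture reproduces the B-form distance ordering", {
  g <- cached("b8_geom", {
    backbone_geometry(extract_frames(get_fixture("b8mer")$ref))
  })
  m53 <- mean(g$d_5p_c1, na.rm = TRUE)
  m35 <- mean(g$d_c1_3p, na.rm = TRUE)
  expect_within(m53, 4.9, 5.4)
  expect_within(m35, 4.0, 4.6)
  expect_gt(m53, m35)
})

test_that("torsions are rigid-motion invariant and mirror-antisymmetric", {
  dx <- build_duplex("GCGC", "B")
  fr <- extract_frames(dx$atoms)
  tt <- eta_theta_prime(fr)
  # random rigid motion
  R <- nucleoblob:::rot_exp(c(0.7, -0.2, 1.1)); tr <- c(5, -3, 11)
  fr2 <- fr
  for (cols in list(c("Px", "Py", "Pz"), c("C1x", "C1y", "C1z"),
                    c("Nx", "Ny", "Nz"))) {
    m <- as.matrix(fr[, cols])
    fr2[, cols] <- sweep(m %*% t(R), 2, tr, `+`)
  }
  tt2 <- eta_theta_prime(fr2)
  expect_equal(tt2$eta, tt$eta, tolerance = 1e-9)
  expect_equal(tt2$theta, tt$theta, tolerance = 1e-9)
  # mirror image negates every defined torsion
  fr3 <- fr
  fr3$Px <- -fr3$Px; fr3$C1x <- -fr3$C1x; fr3$Nx <- -fr3$Nx
  tt3 <- eta_theta_prime(fr3)
  expect_equal(tt3$eta, -tt$eta, tolerance = 1e-9)
  expect_equal(tt3$theta, -tt$theta, tolerance = 1e-9)
})

test_that("planar and collinear point sets give the degenerate torsions", {
  expect_equal(abs(torsion_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                                 c(2, 1, 0))), 180)
  expect_equal(torsion_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                             c(0, 1, 0)), 0)
  expect_true(is.na(torsion_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                  c(3, 1, 0))))
})

test_that("direction assignment reads the distance asymmetry", {
  g <- cached("b8_geom", {
    backbone_geometry(extract_frames(get_fixture("b8mer")$ref))
  })
  ga <- g[g$chain == "A", ]
  d <- assign_direction(ga, "B")
  expect_equal(d$verdict, "forward")
  expect_gt(d$margin, 0)
  # reversed chain
  fr <- extract_frames(get_fixture("b8mer")$ref)
  fra <- fr[fr$chain == "A", ]
  grev <- backbone_geometry(fra[rev(seq_len(nrow(fra))), ])
  expect_equal(assign_direction(grev, "B")$verdict, "reversed")
  # too-short chain is indeterminate
  expect_equal(assign_direction(ga[1:2, ], "B")$verdict, "indeterminate")
})

test_that("circular statistics match hand arithmetic", {
  cs <- circular_mean(c(90, 90, 90))
  expect_equal(cs$mean_deg, 90)
  expect_equal(cs$Rbar, 1)
  cs2 <- circular_mean(c(0, 180))
  expect_equal(cs2$Rbar, 0, tolerance = 1e-12)
  expect_true(is.na(cs2$mean_deg))
  cs3 <- circular_mean(c(350, 10))
  expect_equal(cs3$mean_deg %% 360, 0, tolerance = 1e-9)
  expect_equal(cs3$Rbar, cos(10 * pi / 180), tolerance = 1e-12)
  # exactly the bisector for any two angles on a narrow arc
  expect_equal(circular_mean(c(47.3, 112.9))$mean_deg, (47.3 + 112.9) / 2,
               tolerance = 1e-9)
  # close to the arithmetic mean for concentrated samples off the wrap
  set.seed(8)
  x <- stats::runif(50, 40, 120)
  expect_equal(circular_mean(x)$mean_deg, mean(x), tolerance = 0.01)
  expect_error(circular_mean(numeric(0)), "nonempty")
})

test_that("bimodal splitting recovers a two-mode angle sample", {
  set.seed(31)
  x <- c(stats::rnorm(150, 76, 3), stats::rnorm(90, 86.5, 3))
  sp <- split_bimodal(x)
  expect_within(sp$threshold, 79.25, 83.25)   # near the density minimum
  expect_lt(abs(sp$stats1$n - 150), 10)
  expect_lt(abs(sp$stats2$n - 90), 10)
  expect_lt(abs(sp$stats1$mean_deg - 76), 1.5)
  expect_lt(abs(sp$stats2$mean_deg - 86.5), 1.5)

  # perfectly separated clusters: split found and flagged bimodal
  sp2 <- split_bimodal(c(rep(10, 5), rep(100, 5)))
  expect_true(sp2$bimodal)
  expect_within(sp2$threshold, 10, 100)
  expect_equal(sp2$stats1$Rbar, 1)
  expect_equal(sp2$stats2$Rbar, 1)

  # tight unimodal data: no evidence of bimodality
  set.seed(32)
  sp3 <- split_bimodal(stats::rnorm(100, 50, 1))
  expect_false(sp3$bimodal)
  expect_error(split_bimodal(c(1, 2, 3)), "at least 4")
})

test_that("the split objective is exhaustively maximal on small samples", {
  set.seed(33)
  x <- stats::runif(12, 0, 180)
  sp <- split_bimodal(x)
  xs <- sort(x)
  for (thr in (xs[-1] + xs[-12]) / 2) {
    lo <- x[x <= thr]; hi <- x[x > thr]
    if (!length(lo) || !length(hi)) next
    obj <- length(lo) * circular_mean(lo)$Rbar +
           length(hi) * circular_mean(hi)$Rbar
    expect_lte(obj, sp$objective + 1e-12)
  }
})

test_that("Gaussian fits recover known histogram parameters", {
  # exact noiseless curve: parameters recovered to machine-ish precision
  x <- seq(4.5, 5.1, 0.01)
  y <- 80 * exp(-(x - 4.78)^2 / (2 * 0.05^2))
  ft <- fit_gaussians(x, y, 1)
  expect_equal(ft$components$mu, 4.78, tolerance = 1e-6)
  expect_equal(ft$components$sigma, 0.05, tolerance = 1e-6)
  expect_equal(ft$components$a, 80, tolerance = 1e-4)

  # seeded draws near the RNA backbone distance: 1e4 samples, 0.01 A bins
  set.seed(41)
  d <- stats::rnorm(1e4, 4.78, 0.05)
  h <- hist(d, breaks = seq(4.5, 5.1, 0.01), plot = FALSE)
  ft2 <- fit_gaussians(h$mids, h$counts, 1)
  expect_lt(abs(ft2$components$mu - 4.78), 0.005)
  expect_lt(abs(ft2$components$sigma - 0.05) / 0.05, 0.10)

  # two separated components, returned sorted by mean
  xx <- seq(0, 12, 0.1)
  yy <- 40 * exp(-(xx - 4)^2 / (2 * 0.5^2)) +
        25 * exp(-(xx - 9)^2 / (2 * 0.7^2))
  ft3 <- fit_gaussians(xx, yy, 2)
  expect_equal(ft3$components$mu, c(4, 9), tolerance = 1e-4)
  expect_equal(ft3$components$sigma, c(0.5, 0.7), tolerance = 1e-3)
  expect_error(fit_gaussians(1:4, c(1, 2, 1, 0), 2), "too few")

  # broom-style accessors
  td <- tidy(ft3)
  expect_equal(td$component, 1:2)
  expect_equal(glance(ft3)$n_components, 2)
})

test_that("Gaussian mean recovery is unbiased over seeded replicates", {
  mus <- vapply(1:100, function(s) {
    set.seed(s)
    d <- stats::rnorm(1e3, 50, 5)
    h <- hist(d, breaks = seq(25, 75, 1), plot = FALSE)
    fit_gaussians(h$mids, h$counts, 1)$components$mu
  }, numeric(1))
  expect_lt(abs(mean(mus) - 50), 3 * 5 / sqrt(1e3))
})

test_that("the shipped reference constants are served per family", {
  b <- reference_table("B")
  expect_equal(b$mean[b$quantity == "d_c1_3p"], 4.29)
  expect_equal(b$mean[b$quantity == "d_5p_c1"], 5.14)
  expect_equal(b$sd[b$quantity == "d_5p_c1"], 0.28)
  a <- reference_table("A")
  expect_equal(a$mean[a$quantity == "d_c1_3p"], 4.77)
  expect_equal(a$sd[a$quantity == "d_c1_3p"], 0.05)
  rna <- reference_table("RNA")
  expect_equal(sort(rna$mean[grepl("ang", rna$quantity)]), c(67.9, 71.5))
  z <- reference_table("Z")
  expect_equal(sort(z$mean[z$quantity == "ang_c1_p_c1"]), c(76.1, 86.4))
  expect_equal(z$n[z$quantity == "ang_c1_p_c1"], c(151, 87))
  z1 <- reference_table("Z1")
  expect_true(all(z1$component == 1))
  expect_error(reference_table("Q"), "unknown")
})
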