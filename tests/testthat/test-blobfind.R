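test_that("centre of gravity converges onto an isolated Gaussian peak", {
  m <- gaussian_peak_map(centre = c(5, 5, 5), spacing = 0.5, sd_atom = 0.9)
  res <- converge_centre(m, seed = c(5.7, 5.7, 5.3))
  expect_equal(res$status, "converged")
  expect_lt(sqrt(sum((res$centre - c(5, 5, 5))^2)), 0.1)
  expect_lte(res$n_iter, 20)
})

test_that("convergence stays on the seeded peak of two equal peaks", {
  cell <- unit_cell(20)
  n <- 40; sp <- 0.5
  ax <- (seq_len(n) - 1) * sp
  peak <- function(c0) outer(outer(exp(-(ax - c0[1])^2 / 1.62),
                                   exp(-(ax - c0[2])^2 / 1.62)),
                             exp(-(ax - c0[3])^2 / 1.62))
  m <- density_grid(array(5 * (peak(c(6, 10, 10)) + peak(c(14, 10, 10))),
                          c(n, n, n)), cell, normalized = TRUE)
  res <- converge_centre(m, seed = c(6.4, 10, 10))
  expect_equal(res$status, "converged")
  expect_lt(abs(res$centre[1] - 6), 0.2)
  expect_lt(sqrt(sum((res$centre - c(6.4, 10, 10))^2)), 3.5)
})

test_that("seeds in flat or negative density are rejected, not crashed", {
  cell <- unit_cell(10)
  m <- density_grid(array(-1, c(20, 20, 20)), cell, normalized = TRUE)
  res <- converge_centre(m, seed = c(5, 5, 5))
  expect_equal(res$status, "empty")
  expect_error(converge_centre(m, seed = c(NA, 1, 1)), "seed")
})

test_that("find_blobs recovers isolated atoms once each", {
  # 10 Gaussian atoms >= 4 A apart on a 0.5 A grid, no noise
  cell <- unit_cell(20)
  n <- 40
  set.seed(11)
  centres <- as.matrix(expand.grid(x = c(4, 9, 14), y = c(4, 9, 14), z = 6))
  centres <- rbind(centres, c(9, 9, 12))
  ax <- (seq_len(n) - 1) * 0.5
  v <- array(0, c(n, n, n))
  for (r in seq_len(nrow(centres))) {
    v <- v + 5 * outer(outer(exp(-(ax - centres[r, 1])^2 / 1.62),
                             exp(-(ax - centres[r, 2])^2 / 1.62)),
                       exp(-(ax - centres[r, 3])^2 / 1.62))
  }
  m <- density_grid(v, cell, normalized = TRUE)
  blobs <- find_blobs(m)
  expect_equal(nrow(blobs), 10)
  derr <- vapply(seq_len(nrow(blobs)), function(i) {
    min(sqrt(colSums((t(centres) - c(blobs$x[i], blobs$y[i], blobs$z[i]))^2)))
  }, numeric(1))
  expect_lt(max(derr), 0.3)

  # negated map: no positive seeds, no blobs
  mneg <- m; mneg$values <- -m$values
  expect_equal(nrow(find_blobs(mneg)), 0)
})

test_that("the 1.3 A acceptance mask suppresses near-duplicate blobs", {
  cell <- unit_cell(12)
  n <- 30; ax <- (seq_len(n) - 1) * 0.4
  peak <- function(c0) outer(outer(exp(-(ax - c0[1])^2 / 1.0),
                                   exp(-(ax - c0[2])^2 / 1.0)),
                             exp(-(ax - c0[3])^2 / 1.0))
  m <- density_grid(array(4 * (peak(c(5.5, 6, 6)) + peak(c(6.5, 6, 6))),
                          c(n, n, n)), cell, normalized = TRUE)
  blobs <- find_blobs(m)
  expect_equal(nrow(blobs), 1)
})

test_that("no two accepted centres violate the masking radius", {
  blobs <- find_blobs(get_fixture("b8mer")$map)
  sp <- grid_spacing(get_fixture("b8mer")$map)
  dmin <- min(dist(as.matrix(blobs[, c("x", "y", "z")])))
  expect_gt(dmin, 1.3 - sqrt(sum(sp^2)))
})

test_that("moments eigenstructure classifies sphere, disc and rod shapes", {
  cell <- unit_cell(12)
  n <- 30; sp <- 0.4
  ax <- (seq_len(n) - 1) * sp
  grid3 <- expand.grid(x = ax, y = ax, z = ax)
  ctr <- c(6, 6, 6)
  dx <- grid3$x - ctr[1]; dy <- grid3$y - ctr[2]; dz <- grid3$z - ctr[3]

  # isotropic Gaussian: all three eigenvalues equal within 2%
  v <- array(4 * exp(-(dx^2 + dy^2 + dz^2) / 1.2), c(n, n, n))
  m <- density_grid(v, cell, normalized = TRUE)
  mom <- compute_moments(m, ctr)
  expect_lt(diff(range(mom$eigvals)) / mom$eigvals[1], 0.02)

  # thin uniform disc: perpendicular-axis identity l1 = l2 + l3 and the
  # large-eigenvalue eigenvector along the disc normal
  r2 <- dx^2 + dy^2
  disc <- array(as.numeric(r2 <= 4 & abs(dz) <= 0.21), c(n, n, n))
  md <- density_grid(disc, cell, normalized = TRUE)
  momd <- compute_moments(md, ctr)
  expect_equal(momd$eigvals[1], momd$eigvals[2] + momd$eigvals[3],
               tolerance = 0.03)
  expect_gt(abs(momd$eigvecs[3, 1]), cos(5 * pi / 180))
  expect_equal(planarity(momd$eigvals), 0.5, tolerance = 0.02)

  # uniform rod along z: l1 ~ l2 >> l3, small eigenvector along z
  rod <- array(as.numeric(r2 <= 0.1 & abs(dz) <= 2.3), c(n, n, n))
  mr <- density_grid(rod, cell, normalized = TRUE)
  momr <- compute_moments(mr, ctr)
  expect_equal(momr$eigvals[1], momr$eigvals[2], tolerance = 0.05)
  expect_lt(momr$eigvals[3], 0.2 * momr$eigvals[1])
  expect_gt(abs(momr$eigvecs[3, 3]), cos(5 * pi / 180))

  expect_error(compute_moments(density_grid(array(-1, c(8, 8, 8)), cell,
                                            normalized = TRUE), c(2, 2, 2)),
               "degenerate")
})

test_that("the moments matrix is positive semidefinite and consistent", {
  m <- get_fixture("gc_pair")$map
  blobs <- find_blobs(m)
  for (i in seq_len(nrow(blobs))) {
    ev <- c(blobs$lambda1[i], blobs$lambda2[i], blobs$lambda3[i])
    expect_true(all(diff(ev) <= 1e-9))          # sorted decreasing
    expect_gte(ev[3], -1e-8)                    # PSD
    V <- blobs$eigvecs[[i]]
    expect_lt(max(abs(crossprod(V) - diag(3))), 1e-8)
    # reconstructed moments matrix is symmetric
    M <- V %*% diag(ev) %*% t(V)
    expect_lt(max(abs(M - t(M))), 1e-8)
    expect_gte(blobs$Q[i], 0)
  }
})

test_that("planarity follows the eigenvalue identities", {
  expect_equal(planarity(c(2, 1, 1)), 0.5)
  expect_equal(planarity(c(1, 1, 1)), 0)
  expect_equal(planarity(c(3, 2, 1)), 0.5)   # also satisfies l1 = l2 + l3
  expect_error(planarity(c(0, 0, 0)), "degenerate")
})

test_that("rigid rotation of the density rotates blob eigenvectors with it", {
  # a tilted purine on a cubic grid; the rotated copy is the exact 90-degree
  # array rotation, so voxelization is identical in both maps
  X <- nucleoblob:::template_coords(base_template("purine"))
  Rt <- nucleoblob:::rot_exp(c(0.4, 0.2, 0.1))
  at <- tibble::tibble(element = "C", Z = 7,
                       x = (X %*% t(Rt))[, 1] + 8,
                       y = (X %*% t(Rt))[, 2] + 8,
                       z = (X %*% t(Rt))[, 3] + 8, b = 15)
  cell <- unit_cell(16)
  m <- modify_density(render_map(at, cell = cell, spacing = 0.4,
                                 normalize = "atomic"))
  n <- m$dims[1]
  v2 <- array(0, dim(m$values))
  for (k in seq_len(n)) v2[, , k] <- t(m$values[, , k])[, seq(n, 1)]
  m2 <- m; m2$values <- v2
  blobs <- find_blobs(m)
  # the array map sends position (x, y, z) to (y, 15.6 - x, z)
  for (i in seq_len(nrow(blobs))) {
    c1 <- c(blobs$x[i], blobs$y[i], blobs$z[i])
    c2 <- c(c1[2], 15.6 - c1[1], c1[3])
    mo1 <- compute_moments(m, c1)
    mo2 <- compute_moments(m2, c2)
    expect_equal(mo2$Q, mo1$Q, tolerance = 1e-6)
    expect_lt(max(abs(mo1$eigvals - mo2$eigvals) / mo1$eigvals), 0.02)
    # the eigenframe rotates with the density (sign of eigenvectors free)
    Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    for (k in 1:3) {
      expect_gt(abs(sum((Rz %*% mo1$eigvecs[, k]) * mo2$eigvecs[, k])),
                cos(5 * pi / 180))
    }
  }
})

test_that("blob acceptance order is deterministic", {
  fx <- get_fixture("gc_pair")
  b1 <- find_blobs(fx$map)
  b2 <- find_blobs(fx$map)
  expect_identical(b1[, c("x", "y", "z", "Q")], b2[, c("x", "y", "z", "Q")])
})
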