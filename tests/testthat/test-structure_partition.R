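random_structure <- function(n, sd = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xyz <- matrix(rnorm(3 * n, sd = sd), ncol = 3)
  structure_model("A", seq_len(n), rep("ALA", n),
                  xyz[, 1], xyz[, 2], xyz[, 3])
}

test_that("fit_best_plane recovers an exact plane through coplanar points", {
  set.seed(2)
  x <- runif(12, -5, 5); y <- runif(12, -5, 5)
  z <- 2 * x - y + 5
  m <- structure_model("A", 1:12, rep("ALA", 12), x, y, z)
  pl <- fit_best_plane(m)
  n_exp <- c(2, -1, -1) / sqrt(6)
  sgn <- sign(sum(pl$unit_normal * n_exp))
  expect_equal(pl$unit_normal, sgn * n_exp, tolerance = 1e-9)
  # All points lie on the fitted plane: residual signed distances ~ 0.
  resid <- coords_matrix(m) %*% pl$unit_normal - pl$offset
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("points mirror-symmetric in z give a horizontal plane", {
  set.seed(6)
  xy <- matrix(rnorm(10, sd = 4), ncol = 2)
  # Each (x, y) appears with z = +1 and z = -1: exact symmetry about z = 0.
  x <- rep(xy[, 1], each = 2); y <- rep(xy[, 2], each = 2)
  z <- rep(c(1, -1), 5)
  m <- structure_model("A", 1:10, rep("ALA", 10), x, y, z)
  pl <- fit_best_plane(m)
  expect_equal(abs(pl$unit_normal[3]), 1, tolerance = 1e-9)
  expect_equal(pl$offset * sign(pl$unit_normal[3]), 0, tolerance = 1e-9)
})

test_that("OLS coefficients equal an independent normal-equation solve", {
  m <- random_structure(20, seed = 14)
  pl <- fit_best_plane(m)
  xyz <- coords_matrix(m)
  # Brute-force normal equations for z = b0 + b1 x + b2 y.
  X <- cbind(1, xyz[, 1], xyz[, 2])
  beta <- solve(t(X) %*% X) %*% t(X) %*% xyz[, 3]
  n_raw <- c(beta[2], beta[3], -1)
  n_exp <- n_raw / sqrt(sum(n_raw^2))
  sgn <- sign(sum(pl$unit_normal * n_exp))
  expect_equal(pl$unit_normal, sgn * n_exp, tolerance = 1e-9)
  expect_equal(pl$offset, sgn * (-beta[1]) / sqrt(sum(n_raw^2)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("degenerate point sets are rejected", {
  line <- line_structure(10)
  expect_error(fit_best_plane(line), "collinear")
  # Points in a vertical plane (x = const surface) break the z-on-(x,y)
  # regression but not the PCA fit.
  y <- rnorm(10); z <- rnorm(10)
  vert <- structure_model("A", 1:10, rep("ALA", 10), rep(0, 10), y, z)
  expect_error(fit_best_plane(vert, "ols"), "pca")
  expect_equal(abs(fit_best_plane(vert, "pca")$unit_normal[1]), 1,
               tolerance = 1e-6)
})

test_that("perpendicular plane is orthogonal and follows the main axis", {
  # Points spread mostly along x, fitted normal ~ (0,0,1).
  set.seed(3)
  x <- rnorm(40, sd = 10); y <- rnorm(40, sd = 2); z <- rnorm(40, sd = 0.5)
  m <- structure_model("A", 1:40, rep("ALA", 40), x, y, z)
  pl <- fit_best_plane(m)
  pp <- perpendicular_plane(pl, m)
  expect_lt(abs(sum(pl$unit_normal * pp$unit_normal)), 1e-9)
  expect_equal(abs(pp$unit_normal[1]), 1, tolerance = 0.05)
  expect_equal(pp$labels, c("top", "bottom"))
})

test_that("perpendicular normal matches an independent in-plane PCA", {
  sp <- synthetic_spec(n_residues = 60, chain_model = "helix", seed = 9)
  m <- generate_structure(sp)
  pl <- fit_best_plane(m, "pca")
  pp <- perpendicular_plane(pl, m)
  xyz <- coords_matrix(m)
  n <- pl$unit_normal
  centered <- sweep(xyz, 2, colMeans(xyz))
  proj <- centered - (centered %*% n) %*% t(n)
  axis <- eigen(cov(proj), symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(sum(pp$unit_normal * axis)), 1, tolerance = 1e-6)
})

test_that("assign_sides uses signed distance with ties to the second label", {
  m <- structure_model("A", 1:3, rep("ALA", 3),
                       c(0, 0, 0), c(0, 0, 0), c(-1, 0, 2))
  pl <- partition_plane(c(0, 0, 1), 0)
  expect_equal(unname(assign_sides(m, pl)),
               c("left", "right", "right"))  # on-plane residue -> right

  # Mirror image swaps labels exactly.
  mm <- structure_model("A", 1:3, rep("ALA", 3),
                        c(0, 0, 0), c(0, 0, 0), -c(-1, 0, 2))
  expect_equal(unname(assign_sides(mm, pl)), c("right", "right", "left"))
})

test_that("side chi-square matches the closed form at df = 1", {
  even <- partition_counts(c(50, 50), c(15, 15))
  r0 <- side_chi_square(even)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  counts <- partition_counts(c(50, 50), c(20, 10))
  expect_equal(unname(counts$expected), c(15, 15))
  r <- side_chi_square(counts)
  expect_equal(r$statistic, 10 / 3, tolerance = 1e-12)
  # Independent closed form: chi2_1 survival = 2 * (1 - Phi(sqrt(x))).
  expect_equal(r$p_value, 2 * (1 - pnorm(sqrt(10 / 3))), tolerance = 1e-12)
  expect_equal(r$p_value, 0.0679, tolerance = 1e-3)

  # Side-proportion expected-count arithmetic.
  pc <- partition_counts(c(60, 40), c(7, 3))
  expect_equal(unname(pc$expected), c(6, 4))

  expect_error(side_chi_square(partition_counts(c(10, 0), c(5, 5))),
               "expected")
  expect_warning(side_chi_square(partition_counts(c(50, 50), c(4, 4))),
                 "below 5")
})

test_that("PCA plane test is invariant under rigid-body motion", {
  sp <- synthetic_spec(n_residues = 80, seed = 21)
  m <- generate_structure(sp)
  sites <- c(3, 7, 9, 14, 17, 20, 28, 33, 41, 44, 52, 60, 71, 78)
  t1 <- suppressWarnings(
    plane_partition_test(m, fit_best_plane(m, "pca"), sites)
  )
  m2 <- transform_structure(m)
  t2 <- suppressWarnings(
    plane_partition_test(m2, fit_best_plane(m2, "pca"), sites)
  )
  expect_equal(t2$statistic, t1$statistic, tolerance = 1e-6)
  expect_equal(t2$p_value, t1$p_value, tolerance = 1e-6)
})
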