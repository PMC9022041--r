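test_that("build_instances duplicates shared columns, one per paralog", {
  st <- line_structure(10)
  mapping <- 1:10
  inst <- build_instances(site_set("A", c(1, 2)), site_set("B", 2),
                          mapping, st)
  expect_equal(nrow(inst), 3)
  expect_equal(sum(inst$column == 2), 2)
  expect_true(all(inst$shared[inst$column == 2]))
  two_at_2 <- inst[inst$column == 2, ]
  expect_equal(sort(two_at_2$paralog), c("A", "B"))
  expect_equal(two_at_2$x[1], two_at_2$x[2])  # co-located twin pair

  inst2 <- build_instances(site_set("A", 1), site_set("B", 9), mapping, st)
  expect_equal(nrow(inst2), 2)
  expect_false(any(inst2$shared))
})

test_that("unmapped columns are dropped with a message, all-unmapped errors", {
  st <- line_structure(5)
  mapping <- c(1L, NA, 3L, NA, 5L)
  expect_message(
    inst <- build_instances(site_set("A", c(1, 2)), site_set("B", 3),
                            mapping, st),
    "unmapped"
  )
  expect_equal(nrow(inst), 2)
  expect_error(
    suppressMessages(
      build_instances(site_set("A", 2), site_set("B", 4), mapping, st)
    ),
    "unmapped"
  )
})

test_that("nearest neighbors follow geometry in the two textbook layouts", {
  st <- line_structure(10)  # 3.8 A consecutive spacing
  mapping <- 1:10
  # Two tight blocks: every nearest neighbor is in the same paralog.
  blocks <- build_instances(site_set("A", c(1, 2)),
                            site_set("B", c(9, 10)), mapping, st)
  expect_equal(nearest_affiliations(blocks), c(2L, 0L, 2L, 0L),
               ignore_attr = TRUE)

  # Alternating equally spaced sites: every nearest neighbor is the other.
  alt <- build_instances(site_set("A", c(1, 3)), site_set("B", c(2, 4)),
                         mapping, st)
  expect_equal(nearest_affiliations(alt), c(0L, 2L, 0L, 2L),
               ignore_attr = TRUE)
})

test_that("a single-paralog instance set is rejected downstream", {
  st <- line_structure(5)
  inst <- build_instances(site_set("A", c(1, 3)), site_set("B", integer(0)),
                          1:5, st)
  expect_equal(nrow(inst), 2)
  expect_error(nearest_affiliations(inst), "both paralogs")
})

test_that("nearest_affiliations equals the brute-force all-pairs oracle", {
  set.seed(123)
  for (i in 1:25) {
    n_a <- sample(2:6, 1); n_b <- sample(2:6, 1)
    n_shared <- sample(0:min(n_a, n_b, 2), 1)
    inst <- random_instances(n_a, n_b, n_shared, box = 12)
    expect_equal(nearest_affiliations(inst), brute_affiliations(inst),
                 ignore_attr = TRUE,
                 label = sprintf("set %d (%d A, %d B, %d shared)",
                                 i, n_a, n_b, n_shared))
  }
})

test_that("random-labeling expected counts follow the stated formula", {
  e <- expected_affiliations(2, 2)
  expect_equal(unname(e), c(2 / 3, 4 / 3, 2 / 3, 4 / 3))
  # With the sp18-scale site counts 62 and 30, an A instance has
  # probability 61/91 of a same-paralog neighbor under random labeling.
  e2 <- expected_affiliations(62, 30)
  expect_equal(e2[["A_same"]] / 62, 61 / 91)
  expect_equal(e2[["A_other"]] / 62, 30 / 91)
  # Per-paralog totals are preserved.
  expect_equal(e2[["A_same"]] + e2[["A_other"]], 62)
  expect_equal(e2[["B_same"]] + e2[["B_other"]], 30)

  expect_error(expected_affiliations(5, 0), "at least one")
  expect_error(expected_affiliations(1, 1), "at least 3")
})

test_that("affiliation chi-square matches frozen df = 3 values", {
  e <- c(8 / 3, 4 / 3, 8 / 3, 4 / 3)
  r0 <- affiliation_chi_square(e, e)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  r <- affiliation_chi_square(c(4, 0, 4, 0), e)
  expect_equal(r$statistic, 4, tolerance = 1e-12)
  expect_equal(r$p_value, 0.2615, tolerance = 2e-4)
  expect_equal(r$df, 3)

  # Independent cell-loop summation oracle.
  set.seed(8)
  for (i in 1:10) {
    obs <- rpois(4, 6); exp <- runif(4, 2, 10)
    acc <- 0
    for (k in 1:4) acc <- acc + (obs[k] - exp[k])^2 / exp[k]
    expect_equal(affiliation_chi_square(obs, exp)$statistic, acc,
                 tolerance = 1e-12)
  }

  expect_error(affiliation_chi_square(c(1, 1, 1, 1), c(0, 1, 1, 1)),
               "expected")
})

test_that("observed affiliation counts survive rigid-body motion", {
  set.seed(19)
  inst <- random_instances(5, 4, 1, box = 15)
  obs1 <- nearest_affiliations(inst)
  xyz <- rigid_transform(as.matrix(inst[, c("x", "y", "z")]))
  inst2 <- inst
  inst2$x <- xyz[, 1]; inst2$y <- xyz[, 2]; inst2$z <- xyz[, 3]
  expect_equal(nearest_affiliations(inst2), obs1, ignore_attr = TRUE)
})

test_that("neighbor_test reports both null options deterministically", {
  sp <- synthetic_spec(
    n_residues = 60, p_a = 0.25, p_b = 0.2, seed = 33,
    clustering = list(focus_a = 5, focus_b = 55, decay_length = 4)
  )
  b <- generate_bundle(sp)
  chi <- neighbor_test(b$sites_a, b$sites_b, b$mapping, b$structure)
  expect_equal(chi$df, 3)
  expect_gte(chi$p_value, 0)
  expect_lte(chi$p_value, 1)
  expect_equal(sum(chi$observed[c("A_same", "A_other")]), chi$n_a)
  expect_equal(sum(chi$observed[c("B_same", "B_other")]), chi$n_b)

  p1 <- neighbor_test(b$sites_a, b$sites_b, b$mapping, b$structure,
                      null = "permutation", n_perm = 300, seed = 4)
  p2 <- neighbor_test(b$sites_a, b$sites_b, b$mapping, b$structure,
                      null = "permutation", n_perm = 300, seed = 4)
  expect_identical(p1$p_value, p2$p_value)
  expect_gte(p1$p_value, 0)
  expect_lte(p1$p_value, 1)
})
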