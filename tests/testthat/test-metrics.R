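test_that("weighted connectance matches closed forms and the frozen oracle", {
  expect_equal(weighted_connectance(matrix(5, 1, 1)), 0.5)
  expect_equal(weighted_connectance(matrix(1, 2, 2)), 0.5)
  # frozen from scratch/oracle run of the straight-from-formula script
  expect_equal(weighted_connectance(fix34), 0.298393637520, tolerance = 1e-10)
})

test_that("weighted connectance is <= 0.5, equal only on uniform complete matrices", {
  set.seed(101)
  for (r in 1:20) {
    M <- matrix(rpois(30, 2), 5, 6)
    if (any(rowSums(M) == 0) || any(colSums(M) == 0)) next
    expect_lte(weighted_connectance(M), 0.5 + 1e-12)
  }
  for (k in 2:4) expect_equal(weighted_connectance(matrix(3, k, k)), 0.5)
})

test_that("NODF handles the canonical extremes", {
  expect_equal(nodf(diag(3) + 0), 0)
  expect_equal(nodf(tri3), 100)
  # removing the degree-1 pollinator of the triangle leaves NODF 75
  expect_equal(nodf(remove_pollinators(tri3, "a3")), 75)
  expect_error(nodf(matrix(2, 1, 1)), "undefined")
})

test_that("NODF equals the brute-force pairwise oracle and vegan on seeded matrices", {
  skip_if_not_installed("vegan")
  set.seed(42)
  B6 <- matrix(rbinom(36, 1, 0.5), 6, 6)
  expect_equal(nodf(B6), 58.8888888889, tolerance = 1e-8) # frozen oracle value
  for (seed in 1:8) {
    set.seed(seed)
    M <- matrix(rpois(42, 0.9), 6, 7)
    if (any(rowSums(M) == 0) || any(colSums(M) == 0)) next
    v <- unname(vegan::nestednodf(M)$statistic["NODF"])
    expect_equal(nodf(M), oracle_nodf(M), tolerance = 1e-10)
    expect_equal(nodf(M), v, tolerance = 1e-8)
  }
})

test_that("NODF is invariant under row/column permutation and 0 on permutation matrices", {
  set.seed(7)
  for (r in 1:5) {
    M <- matrix(rpois(30, 1), 5, 6)
    if (any(rowSums(M) == 0) || any(colSums(M) == 0)) next
    Mp <- M[sample(5), sample(6)]
    expect_equal(nodf(M), nodf(Mp), tolerance = 1e-10)
  }
  for (n in 3:5) {
    Pm <- diag(n)[sample(n), ]
    expect_equal(nodf(Pm), 0)
  }
})

test_that("H2' hits its closed-form extremes and errors on degenerate input", {
  expect_equal(h2_prime(matrix(1, 2, 2)), 0)
  expect_equal(h2_prime(diag(c(2, 2))), 1)
  # outer-product counts: observed equals marginal expectation exactly
  op <- outer(c(1, 2), c(2, 1, 3))
  expect_equal(h2_prime(op), 0)
  expect_error(h2_prime(matrix(4, 1, 1)), "undefined|degenerate")
})

test_that("H2' minimum fill matches exhaustive enumeration at m <= 12", {
  cases <- list(list(r = c(4, 3, 5), c = c(4, 3, 5)),
                list(r = c(6, 3, 1), c = c(2, 5, 3)),
                list(r = c(5, 5), c = c(3, 3, 4)))
  for (cs in cases) {
    greedy <- shannon(h2_min_fill(cs$r, cs$c))
    expect_equal(greedy, oracle_h2min_enum(cs$r, cs$c), tolerance = 1e-10)
  }
  # frozen H2' for the fixed 3x3 fixture, computed with the enumeration oracle
  expect_equal(h2_prime(fix33), 0.4848764875, tolerance = 1e-8)
})

test_that("H2' stays in [0, 1] on random count matrices", {
  set.seed(202)
  for (r in 1:25) {
    M <- matrix(rpois(20, 1.5), 4, 5)
    if (any(rowSums(M) == 0) || any(colSums(M) == 0) || sum(M) < 2) next
    h <- h2_prime(M)
    expect_gte(h, 0)
    expect_lte(h, 1)
  }
})

test_that("robustness matches closed forms and the exhaustive-order oracle", {
  for (P in c(1, 3, 4)) {
    M <- matrix(1, P, 3)
    expect_equal(robustness_pollinators(M, replicates = 3, seed = 1),
                 (2 * P - 1) / (2 * P))
  }
  set.seed(9)
  toy <- matrix(rbinom(12, 1, 0.6), 3, 4)
  toy[1, ] <- c(1, 1, 0, 1) # ensure no empty marginals
  toy[, 3] <- c(0, 1, 0)
  exact <- oracle_robustness_exact(toy)
  mc <- robustness_pollinators(toy, replicates = 400, seed = 5)
  expect_lt(abs(mc - exact), 0.02)
  # deterministic removal orders are single-pass and reproducible
  expect_equal(robustness_pollinators(toy, order = "degree_desc"),
               robustness_pollinators(toy, order = "degree_desc"))
})

test_that("robustness Monte-Carlo error shrinks with replicates", {
  set.seed(33)
  M <- matrix(rbinom(20, 1, 0.5), 4, 5)
  M[rowSums(M) == 0, 1] <- 1
  M[1, colSums(M) == 0] <- 1
  exact <- oracle_robustness_exact(M)
  err <- function(reps, seed) abs(robustness_pollinators(M, reps, seed) - exact)
  e_small <- mean(vapply(1:10, function(s) err(20, s), 0))
  e_big <- mean(vapply(1:10, function(s) err(500, s), 0))
  expect_lt(e_big, e_small + 1e-9)
})

test_that("zone_metrics averages per-site indices", {
  site <- build_site_networks(data.frame(
    zone = "A", site = "s1", period = "t",
    pollinator = rep(c("x", "y", "z"), c(3, 2, 1)),
    plant = c("u", "v", "w", "u", "v", "u"), count = 1L))[[1]]
  dup <- site
  dup$site <- "s2"
  zc <- pool_zone(list(site, dup))
  zm <- zone_metrics(zc, replicates = 20, seed = 1)
  single <- network_metrics(site$matrix, replicates = 20, seed = 1)
  expect_equal(nrow(zm$per_site), 2)
  expect_equal(unname(zm$means["nodf"]), single$nodf)
  expect_equal(unname(zm$means["h2_prime"]), single$h2_prime)

  # six synthetic sites: mean equals the hand average of per-site values
  zc6 <- small_zone(31)
  zm6 <- zone_metrics(zc6, replicates = 10, seed = 2)
  expect_equal(unname(zm6$means["nodf"]), mean(zm6$per_site$nodf))
  by_hand <- mean(vapply(zc6$sites, function(s) nodf(s$matrix), 0))
  expect_equal(unname(zm6$means["nodf"]), by_hand)
})

test_that("zone_metrics attaches the failing site id to propagated errors", {
  s1 <- build_site_networks(data.frame(zone = "A", site = "bad", period = "t",
                                       pollinator = "x", plant = "u", count = 2L))
  zc <- pool_zone(s1)
  expect_error(zone_metrics(zc), "bad")
})
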