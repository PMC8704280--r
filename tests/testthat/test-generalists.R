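zone_of <- function(df) zones_from_records(visit_records(df))[[1]]

test_that("Gc reduces to the two-species z-score on one site", {
  df <- data.frame(zone = "A", site = "s1", period = "t",
                   pollinator = rep(c("gen", "spec"), c(3, 1)),
                   plant = c("u", "v", "w", "u"), count = 1L)
  gt <- gc_scores(zone_of(df))
  expect_equal(gt$gc[gt$pollinator == "gen"], (3 - 2) / sqrt(2), tolerance = 1e-10)
  expect_equal(gt$gc[gt$pollinator == "spec"], -(3 - 2) / sqrt(2), tolerance = 1e-10)
  expect_equal(sum(gt$gc), 0, tolerance = 1e-12)
})

test_that("identical degrees are a degenerate input", {
  df <- data.frame(zone = "A", site = "s1", period = "t",
                   pollinator = c("x", "y"), plant = c("u", "v"), count = 1L)
  expect_error(gc_scores(zone_of(df)), "degenerate")
})

test_that("Gc mean-centers to zero and is invariant to count scaling", {
  for (seed in c(21, 22, 23)) {
    zc <- small_zone(seed)
    gt <- gc_scores(zc)
    expect_equal(sum(gt$gc), 0, tolerance = 1e-9)
    # triple every count: distinct-partner structure unchanged, so Gc equal
    scaled <- lapply(zc$sites, function(s) {
      s$matrix <- interaction_matrix(unclass(s$matrix) * 3L)
      s
    })
    gt2 <- gc_scores(pool_zone(scaled))
    expect_equal(gt2$gc[match(gt$pollinator, gt2$pollinator)], gt$gc,
                 tolerance = 1e-9)
  }
})

test_that("absent sites contribute zeros by default, are skipped on request", {
  # 'loc' present at 1 of 2 sites with 2 partners; 'com' at both with 1
  df <- data.frame(zone = "A",
                   site = c("s1", "s1", "s1", "s2", "s2"),
                   period = "t",
                   pollinator = c("loc", "loc", "com", "com", "oth"),
                   plant = c("u", "v", "u", "u", "v"),
                   count = 1L)
  zc <- zone_of(df)
  k_inc <- gc_scores(zc, include_absent_sites = TRUE)
  k_occ <- gc_scores(zc, include_absent_sites = FALSE)
  expect_equal(k_inc$k_i[k_inc$pollinator == "loc"], 1)   # (2 + 0) / 2
  expect_equal(k_occ$k_i[k_occ$pollinator == "loc"], 2)   # occupied site only
  expect_equal(k_inc$k_i[k_inc$pollinator == "com"], 1)
})

test_that("core extraction respects the threshold, monotonically", {
  zc <- small_zone(27)
  gt <- gc_scores(zc)
  empty <- core_generalists(gt, threshold = max(gt$gc) + 1)
  expect_equal(nrow(empty$core), 0)
  expect_equal(empty$coverage_individuals_pct, 0)
  sizes <- vapply(c(0, 0.5, 1, 1.5, 2),
                  function(th) nrow(core_generalists(gt, th)$core), 0L)
  expect_true(all(diff(sizes) <= 0))

  # coverage equals a direct recount from the pooled matrix
  cov <- core_generalists(gt, threshold = 1)
  core_sp <- cov$core$pollinator
  pooled <- zc$pooled
  expect_equal(cov$coverage_individuals_pct,
               100 * sum(unclass(pooled)[, core_sp]) / sum(pooled),
               tolerance = 1e-9)
  expect_equal(cov$coverage_interactions_pct,
               100 * sum(unclass(pooled)[, core_sp] > 0) / n_links(pooled),
               tolerance = 1e-9)
})

test_that("singleton share under both definitions equals a direct recount", {
  # all species with >= 2 individuals and >= 2 links: share 0 both ways
  df <- data.frame(zone = "A", site = "s1", period = "t",
                   pollinator = rep(c("x", "y"), each = 4),
                   plant = rep(c("u", "v", "u", "w"), 2), count = 1L)
  zc <- zone_of(df)
  expect_equal(singleton_share(zc, "one_individual"), 0)
  expect_equal(singleton_share(zc, "one_link"), 0)

  one <- zone_of(data.frame(zone = "A", site = "s1", period = "t",
                            pollinator = "x", plant = "u", count = 1L))
  expect_equal(singleton_share(one, "one_individual"), 100)
  expect_equal(singleton_share(one, "one_link"), 100)

  zc <- small_zone(41)
  pooled <- unclass(zc$pooled)
  by_ind <- 100 * sum(colSums(pooled > 0)[colSums(pooled) == 1]) / sum(pooled > 0)
  by_link <- 100 * sum(colSums(pooled > 0) == 1) / sum(pooled > 0)
  expect_equal(singleton_share(zc, "one_individual"), by_ind, tolerance = 1e-9)
  expect_equal(singleton_share(zc, "one_link"), by_link, tolerance = 1e-9)
})

test_that("nested ranks order by degree, then abundance, then label", {
  M <- matrix(c(1, 1, 0,
                1, 1, 1,
                1, 0, 0), 3, 3, byrow = TRUE,
              dimnames = list(paste0("p", 1:3), c("top", "mid", "low")))
  nr <- nested_rank(M)
  expect_equal(nr$pollinator, c("top", "mid", "low"))
  expect_equal(nr$rank, 1:3)

  # degree tie broken by abundance
  M2 <- matrix(c(10, 1,
                 0, 1), 2, 2, byrow = TRUE,
               dimnames = list(c("p1", "p2"), c("fat", "thin")))
  M2[1, 2] <- 0; M2[2, 2] <- 2 # fat: deg 1 abund 10; thin: deg 1 abund 2
  nr2 <- nested_rank(M2)
  expect_equal(nr2$pollinator[1], "fat")
  # ranks are a permutation of 1..n
  zc <- small_zone(43)
  nr3 <- nested_rank(zc$pooled)
  expect_setequal(nr3$rank, seq_len(n_pollinators(zc$pooled)))
})

test_that("abundance and Gc correlate positively on abundance-driven zones", {
  rhos <- vapply(c(61, 62, 63, 64, 65, 66, 67), function(seed) {
    gt <- gc_scores(small_zone(seed))
    stats::cor(gt$n_individuals, gt$gc, method = "spearman")
  }, 0)
  expect_gt(median(rhos), 0)
})
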