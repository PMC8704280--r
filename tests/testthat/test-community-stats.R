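test_that("summarize_events counts richness and abundance per event", {
  df <- data.frame(zone = "A", site = "s1", period = "t1",
                   pollinator = c("x", "x", "y"), plant = c("u", "u", "v"),
                   count = 1L)
  ev <- summarize_events(df)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$pollinator_richness, 2)
  expect_equal(ev$plant_richness, 2)
  expect_equal(ev$pollinator_abundance, 3)
})

test_that("declared-but-empty events are zero-filled; undeclared flower sites error", {
  df <- data.frame(zone = "A", site = "s1", period = "t1",
                   pollinator = "x", plant = "u", count = 1L)
  design <- data.frame(zone = "A", site = c("s1", "s1"), period = c("t1", "t2"))
  ev <- summarize_events(df, design = design)
  expect_equal(nrow(ev), 2)
  empty <- ev[ev$period == "t2", ]
  expect_equal(empty$pollinator_abundance, 0)
  expect_equal(empty$pollinator_richness, 0)

  fc <- data.frame(zone = "A", site = "s9", period = "t1",
                   plant = "u", flowers = 10)
  expect_error(summarize_events(df, flower_counts = fc), "undeclared")

  fc_ok <- data.frame(zone = "A", site = "s1", period = "t1",
                      plant = c("u", "v"), flowers = c(10, 5))
  ev2 <- summarize_events(df, flower_counts = fc_ok)
  expect_equal(ev2$flower_abundance[ev2$period == "t1"], 15)
})

test_that("event summaries equal direct recounts on a synthetic zone", {
  sim <- generate_zone(small_zone_params(71))
  ev <- summarize_events(sim$records, flower_counts = sim$flowers)
  expect_equal(sum(ev$pollinator_abundance), nrow(sim$records))
  expect_equal(sum(ev$flower_abundance), sum(sim$flowers$flowers))
  one <- sim$records[sim$records$site == ev$site[1] &
                       sim$records$period == ev$period[1], ]
  expect_equal(ev$pollinator_richness[1], length(unique(one$pollinator)))
  expect_true(all(ev$pollinator_richness <= ev$pollinator_abundance))
})

test_that("gaussian comparison reproduces the textbook one-way F", {
  set.seed(81)
  y <- c(rnorm(8, 10), rnorm(8, 12), rnorm(8, 9))
  g <- rep(c("PP", "MC", "SF"), each = 8)
  d <- data.frame(zone = g, val = y)
  cmp <- compare_groups(d, "val", family = "gaussian")
  expect_equal(cmp$stat_type, "F")
  expect_equal(cmp$df, 2)
  expect_equal(cmp$statistic, oracle_anova_f(y, g), tolerance = 1e-8)
  p_classic <- stats::pf(oracle_anova_f(y, g), 2, 21, lower.tail = FALSE)
  expect_equal(cmp$p_value, p_classic, tolerance = 1e-10)
  expect_equal(nrow(cmp$contrasts), 3)
  expect_true(all(cmp$contrasts$p_adj >= 0 & cmp$contrasts$p_adj <= 1))
})

test_that("quasipoisson keeps poisson point estimates, rescales uncertainty", {
  set.seed(82)
  d <- data.frame(zone = rep(c("a", "b", "c"), each = 12),
                  val = rpois(36, rep(c(4, 8, 6), each = 12)))
  po <- compare_groups(d, "val", family = "poisson")
  qp <- compare_groups(d, "val", family = "quasipoisson")
  expect_equal(qp$emm, po$emm, tolerance = 1e-10)
  expect_equal(qp$contrasts$estimate, po$contrasts$estimate, tolerance = 1e-10)
  expect_gte(qp$dispersion, 0)
  expect_equal(qp$contrasts$se, po$contrasts$se * sqrt(qp$dispersion),
               tolerance = 1e-8)
  expect_equal(po$stat_type, "Chisq")
  expect_equal(qp$stat_type, "F")
})

test_that("identical groups give a degenerate, nonsignificant comparison", {
  d <- data.frame(zone = rep(c("a", "b"), each = 5), val = 7)
  cmp <- compare_groups(d, "val", family = "gaussian")
  expect_true(cmp$degenerate)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
  # same means but nonzero noise: not degenerate, p typically large
  set.seed(83)
  d2 <- data.frame(zone = rep(c("a", "b", "c"), each = 20),
                   val = rnorm(60, 5))
  cmp2 <- compare_groups(d2, "val", family = "gaussian")
  expect_false(cmp2$degenerate)
  expect_gt(cmp2$p_value, 0.01)
})

test_that("poisson comparison detects a doubled rate with high power", {
  hits <- 0
  reps <- 200
  set.seed(84)
  for (r in seq_len(reps)) {
    d <- data.frame(zone = rep(c("lo", "hi"), each = 50),
                    val = rpois(100, rep(c(5, 10), each = 50)))
    if (compare_groups(d, "val", family = "poisson")$p_value < 0.01)
      hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})
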