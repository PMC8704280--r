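# Shared fixtures, all built in code at test time.

# full lower-triangular presence matrix: perfectly nested
tri3 <- matrix(c(1, 1, 1,
                 1, 1, 0,
                 1, 0, 0), 3, 3, byrow = TRUE,
               dimnames = list(paste0("p", 1:3), paste0("a", 1:3)))

# fixed count fixtures with frozen oracle values (see test-metrics.R)
fix34 <- matrix(c(2, 1, 0, 3,
                  0, 4, 1, 0,
                  1, 0, 2, 1), 3, 4, byrow = TRUE,
                dimnames = list(paste0("p", 1:3), paste0("a", 1:4)))
fix33 <- matrix(c(3, 1, 0,
                  0, 2, 1,
                  1, 0, 4), 3, 3, byrow = TRUE,
                dimnames = list(paste0("p", 1:3), paste0("a", 1:3)))

# hand-written specimen table: 2 zones x 2 sites
tiny_records <- function() {
  data.frame(
    zone = c("A", "A", "A", "A", "B", "B"),
    site = c("s1", "s1", "s1", "s2", "s1", "s1"),
    period = "t1",
    pollinator = c("bee1", "bee1", "fly1", "bee1", "fly2", "fly2"),
    plant = c("pl1", "pl1", "pl2", "pl2", "pl1", "pl1"),
    group = c("bee", "bee", "fly", "bee", "fly", "fly"),
    count = 1L
  )
}

# small but realistic synthetic zone for module tests (fast: ~200 records)
small_zone_params <- function(seed, mu_b = log(0.12), ...) {
  synth_params(zone = "Z", n_plants = 15, n_pollinators = 30,
               n_sites = 6, n_periods = 5, sigma_p = 1.0, sigma_a = 0.8,
               mu_b = mu_b, lambda = 60, seed = seed, ...)
}

small_zone <- function(seed, ...) {
  sim <- generate_zone(small_zone_params(seed, ...))
  zones_from_records(sim$records, zone = "Z")
}

write_temp_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}
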