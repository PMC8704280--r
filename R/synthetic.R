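#' Parameters for the synthetic community generator
#'
#' The generator emulates a stratified visitation survey: one habitat zone
#' holding `n_sites` sites, each visited for `n_periods` sampling periods.
#' Species are latent: plants carry a trait position \eqn{t_i \sim U(0,1)}
#' and a log-normal relative abundance; pollinators carry a niche optimum
#' \eqn{u_j \sim U(0,1)}, a log-normal activity level, and a log-normal
#' niche breadth \eqn{b_j}. Interaction propensity follows a Gaussian
#' trait-matching kernel \eqn{w_{ij} = \exp(-(t_i-u_j)^2 / 2b_j^2)}; broad
#' breadths make generalists (low H2', high nestedness), narrow breadths
#' specialists. Expected visits in one (site, period) cell are
#' \eqn{\lambda f_i g_j w_{ij}} when both species occupy the site
#' (independent Bernoulli(\eqn{\psi}) site occupancy), and realized counts
#' are Poisson.
#'
#' @param zone zone label
#' @param n_plants,n_pollinators species pool sizes
#' @param n_sites,n_periods survey design (defaults 6 sites, 9 periods)
#' @param mu_p,sigma_p log-normal parameters of plant relative abundance
#' @param mu_a,sigma_a log-normal parameters of pollinator activity
#' @param mu_b,sigma_b log-normal parameters of pollinator niche breadth
#'   (trait-distance units; ~0.05 is a strict specialist, ~0.3 a broad
#'   generalist on the unit trait interval)
#' @param lambda sampling intensity: expected visits per (site, period) for
#'   a perfectly matched pair of unit-abundance species
#' @param psi per-species site-occupancy probability
#' @param group_probs named probabilities for the order-groups
#'   (`bee`, `fly`, `lepidoptera`)
#' @param dominant_share if non-NULL, pollinator 1 is made a numerically
#'   dominant broad-niche fly holding this share of total activity
#'   (emulates a hyperabundant generalist fly)
#' @param flower_total calibration target for the zone's total flower count
#'   (log-normal per site x period x plant)
#' @param flower_sdlog log-sd of the flower counts
#' @param seed integer seed; same seed, same tables, byte for byte
#' @return a validated `synth_params` list
#' @export
synth_params <- function(zone = "Z1", n_plants = 25, n_pollinators = 80,
                         n_sites = 6, n_periods = 9,
                         mu_p = 0, sigma_p = 1.2,
                         mu_a = 0, sigma_a = 1.2,
                         mu_b = log(0.10), sigma_b = 0.6,
                         lambda = 25, psi = 0.65,
                         group_probs = c(bee = 0.35, fly = 0.45,
                                         lepidoptera = 0.20),
                         dominant_share = NULL,
                         flower_total = 65000, flower_sdlog = 1,
                         seed = NULL) {
  p <- list(zone = zone, n_plants = as.integer(n_plants),
            n_pollinators = as.integer(n_pollinators),
            n_sites = as.integer(n_sites), n_periods = as.integer(n_periods),
            mu_p = mu_p, sigma_p = sigma_p, mu_a = mu_a, sigma_a = sigma_a,
            mu_b = mu_b, sigma_b = sigma_b, lambda = lambda, psi = psi,
            group_probs = group_probs, dominant_share = dominant_share,
            flower_total = flower_total, flower_sdlog = flower_sdlog,
            seed = seed)
  with(p, {
    if (any(c(n_plants, n_pollinators, n_sites, n_periods) < 1))
      stop("all pool and design sizes must be >= 1")
    if (any(c(sigma_p, sigma_a, sigma_b, flower_sdlog) < 0))
      stop("sigma parameters must be >= 0")
    if (lambda <= 0) stop("lambda must be > 0")
    if (psi <= 0 || psi > 1) stop("psi must be in (0, 1]")
    if (!is.null(dominant_share) &&
        (dominant_share <= 0 || dominant_share >= 1))
      stop("dominant_share must be in (0, 1)")
    if (abs(sum(group_probs) - 1) > 1e-8)
      stop("group_probs must sum to 1")
  })
  structure(p, class = "synth_params")
}

#' Generate one zone's specimen records (and the latent truth)
#'
#' @param params a [synth_params()] object
#' @return list with `records` (a [visit_records()] table, one row per
#'   specimen), `flowers` (data.frame `zone, site, period, plant, flowers`)
#'   and `truth` (all latent species parameters and site occupancies).
#' @export
generate_zone <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  with_seed(p$seed, {
    plants <- sprintf("plant_%02d", seq_len(p$n_plants))
    polls <- sprintf("poll_%03d", seq_len(p$n_pollinators))
    t_i <- stats::runif(p$n_plants)
    f <- stats::rlnorm(p$n_plants, p$mu_p, p$sigma_p)
    f <- f / sum(f)
    u_j <- stats::runif(p$n_pollinators)
    g <- stats::rlnorm(p$n_pollinators, p$mu_a, p$sigma_a)
    b_j <- stats::rlnorm(p$n_pollinators, p$mu_b, p$sigma_b)
    groups <- sample(names(p$group_probs), p$n_pollinators, replace = TRUE,
                     prob = p$group_probs)
    if (!is.null(p$dominant_share)) {
      g[1] <- p$dominant_share / (1 - p$dominant_share) * sum(g[-1])
      # broad (75th-percentile) but not extreme niche, so the realized
      # specimen share stays near the activity share
      b_j[1] <- stats::qlnorm(0.75, p$mu_b, p$sigma_b)
      groups[1] <- "fly"
    }
    g <- g / sum(g)
    w <- exp(-outer(t_i, u_j, "-")^2 / (2 * rep(b_j, each = p$n_plants)^2))
    occ_plant <- matrix(stats::runif(p$n_sites * p$n_plants) < p$psi,
                        p$n_sites, p$n_plants)
    occ_poll <- matrix(stats::runif(p$n_sites * p$n_pollinators) < p$psi,
                       p$n_sites, p$n_pollinators)
    recs <- list()
    for (s in seq_len(p$n_sites)) {
      lam <- p$lambda * (f * occ_plant[s, ]) %o% (g * occ_poll[s, ]) * w
      for (per in seq_len(p$n_periods)) {
        counts <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
        nz <- which(counts > 0, arr.ind = TRUE)
        if (nrow(nz) == 0) next
        recs[[length(recs) + 1]] <- data.frame(
          zone = p$zone, site = sprintf("site_%d", s),
          period = sprintf("period_%d", per),
          pollinator = rep(polls[nz[, 2]], counts[nz]),
          plant = rep(plants[nz[, 1]], counts[nz]),
          group = rep(groups[nz[, 2]], counts[nz]),
          count = 1L)
      }
    }
    records <- if (length(recs) == 0) {
      structure(data.frame(zone = character(), site = character(),
                           period = character(), pollinator = character(),
                           plant = character(), group = character(),
                           count = integer()),
                class = c("visit_records", "data.frame"))
    } else {
      visit_records(do.call(rbind, recs))
    }
    # flower transect counts: log-normal per (site, period, plant), meanlog
    # chosen so the expected zone total hits flower_total
    ncell <- p$n_sites * p$n_periods * p$n_plants
    meanlog <- log(p$flower_total / ncell) - p$flower_sdlog^2 / 2
    flowers <- expand.grid(site = sprintf("site_%d", seq_len(p$n_sites)),
                           period = sprintf("period_%d", seq_len(p$n_periods)),
                           plant = plants, stringsAsFactors = FALSE)
    flowers <- data.frame(zone = p$zone, flowers)
    flowers$flowers <- round(stats::rlnorm(nrow(flowers), meanlog, p$flower_sdlog))
    truth <- list(plants = plants, pollinators = polls, trait = t_i,
                  optimum = u_j, breadth = b_j, plant_abundance = f,
                  activity = g, groups = stats::setNames(groups, polls),
                  occ_plant = occ_plant, occ_poll = occ_poll, params = p)
    list(records = records, flowers = flowers, truth = truth)
  })
}

#' Three-zone elevational gradient preset
#'
#' Emulates a montane survey with three life zones: a low zone (`"PP"`,
#' ponderosa-pine-like) with narrow pollinator niches (high specialization),
#' a middle zone (`"MC"`, mixed-conifer-like) that is richest and most
#' abundant, and a high zone (`"SF"`, spruce-fir-like) with the fewest
#' plants, broad niches, and one hyperabundant generalist fly holding about
#' a third of the individuals. Niche breadths widen from PP to SF, so
#' zone-level H2' declines (and nestedness rises) with elevation on
#' average. Pool sizes and sampling intensities were calibrated once so the
#' expected specimen totals are of order 340 (PP), 730 (MC) and 630 (SF).
#'
#' @param seed master integer seed; per-zone seeds are derived from it
#' @return named list (`PP`, `MC`, `SF`) of [generate_zone()] results
#' @export
preset_gradient <- function(seed = 1L) {
  zone_seed <- function(k) as.integer((as.numeric(seed) * 101 + k) %% 2147483647)
  spec <- list(
    PP = synth_params(zone = "PP", n_plants = 27, n_pollinators = 92,
                      sigma_p = 1.0, sigma_a = 0.8,
                      mu_b = log(0.055), lambda = 97,
                      group_probs = c(bee = 0.40, fly = 0.48, lepidoptera = 0.12),
                      flower_total = 64000, seed = zone_seed(1)),
    MC = synth_params(zone = "MC", n_plants = 32, n_pollinators = 122,
                      sigma_p = 1.0, sigma_a = 0.8,
                      mu_b = log(0.085), lambda = 143,
                      group_probs = c(bee = 0.33, fly = 0.44, lepidoptera = 0.23),
                      flower_total = 62000, seed = zone_seed(2)),
    SF = synth_params(zone = "SF", n_plants = 20, n_pollinators = 95,
                      sigma_p = 1.0, sigma_a = 0.8,
                      mu_b = log(0.15), lambda = 70,
                      group_probs = c(bee = 0.41, fly = 0.34, lepidoptera = 0.25),
                      dominant_share = 0.30, flower_total = 67000,
                      seed = zone_seed(3))
  )
  lapply(spec, generate_zone)
}
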