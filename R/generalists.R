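#' Core-generalist scores (Gc) for a zone's pollinators
#'
#' For pollinator \eqn{i}, \eqn{k_i} is the mean over the zone's sites of the
#' per-site count of distinct plant partners, and
#' \deqn{G_{c,i} = \frac{k_i - \bar k}{\sigma_k}}
#' a z-score relative to the zone's pollinator community. Species with
#' \eqn{G_c > 1} interact with substantially more partners than the
#' community average and form the network core; the rest are the periphery.
#'
#' @param zone a [pool_zone()] collection
#' @param include_absent_sites if `TRUE` (default), sites where a species was
#'   never caught contribute a partner count of 0 to its mean; if `FALSE`,
#'   only occupied sites are averaged.
#' @param sd_mode `"sample"` (n-1 denominator, default) or `"population"`
#' @return a `gc_table` data.frame, one row per pollinator: `pollinator`,
#'   `group`, `k_i`, `gc`, `n_individuals`, `pct_individuals`,
#'   `unique_partners`, `pct_unique_interactions`, `is_core`; sorted by
#'   decreasing `gc`.
#' @export
gc_scores <- function(zone, include_absent_sites = TRUE,
                      sd_mode = c("sample", "population")) {
  stopifnot(inherits(zone, "zone_collection"))
  sd_mode <- match.arg(sd_mode)
  species <- colnames(zone$pooled)
  if (length(species) < 2)
    stop("Gc undefined: need at least 2 pollinator species")
  n_sites <- length(zone$sites)
  persite <- vapply(species, function(sp) {
    degs <- vapply(zone$sites, function(s) {
      if (sp %in% colnames(s$matrix)) sum(s$matrix[, sp] > 0) else NA_real_
    }, 0)
    if (include_absent_sites) {
      degs[is.na(degs)] <- 0
      mean(degs)
    } else {
      mean(degs, na.rm = TRUE)
    }
  }, 0)
  k_mean <- mean(persite)
  o_k <- stats::sd(persite)
  if (sd_mode == "population")
    o_k <- sqrt(mean((persite - k_mean)^2))
  if (!is.finite(o_k) || o_k < 1e-12)
    stop("degenerate input: all pollinator species have identical k")
  gc <- (persite - k_mean) / o_k
  m_zone <- total_interactions(zone$pooled)
  links_zone <- n_links(zone$pooled)
  n_ind <- colSums(zone$pooled)[species]
  partners <- colSums(unclass(zone$pooled) > 0)[species]
  grp <- if (is.null(zone$groups)) rep(NA_character_, length(species)) else
    as.character(zone$groups[species])
  out <- data.frame(
    pollinator = species,
    group = grp,
    k_i = persite,
    gc = gc,
    n_individuals = as.integer(n_ind),
    pct_individuals = 100 * n_ind / m_zone,
    unique_partners = as.integer(partners),
    pct_unique_interactions = 100 * partners / links_zone,
    row.names = NULL
  )
  out$is_core <- out$gc > 1.0
  out <- out[order(-out$gc, out$pollinator), ]
  rownames(out) <- NULL
  class(out) <- c("gc_table", "data.frame")
  out
}

#' Extract the core-generalist set and its coverage
#'
#' @param gc_table a [gc_scores()] table
#' @param threshold Gc cut-off; species strictly above it are core
#' @return list with `core` (the subset of the table, same ordering),
#'   `coverage_individuals_pct` (share of all zone specimens belonging to
#'   core species) and `coverage_interactions_pct` (share of the zone's
#'   unique links held by core species).
#' @export
core_generalists <- function(gc_table, threshold = 1.0) {
  stopifnot(inherits(gc_table, "data.frame"))
  core <- gc_table[gc_table$gc > threshold, ]
  list(
    core = core,
    coverage_individuals_pct = sum(core$pct_individuals),
    coverage_interactions_pct = sum(core$pct_unique_interactions)
  )
}

#' Share of a zone's unique interactions held by singleton pollinators
#'
#' Two senses of "singleton" are supported: a species represented by exactly
#' one captured individual (`"one_individual"`, default), or a species with
#' exactly one unique plant link at the zone level (`"one_link"`).
#'
#' @param zone a [pool_zone()] collection
#' @param definition singleton sense, see above
#' @return percentage (0-100) of zone-level unique interactions contributed
#'   by singleton pollinator species
#' @export
singleton_share <- function(zone, definition = c("one_individual", "one_link")) {
  stopifnot(inherits(zone, "zone_collection"))
  definition <- match.arg(definition)
  pooled <- zone$pooled
  singles <- if (definition == "one_individual") {
    colSums(pooled) == 1
  } else {
    colSums(unclass(pooled) > 0) == 1
  }
  100 * sum(colSums(unclass(pooled)[, singles, drop = FALSE] > 0)) / n_links(pooled)
}

#' Nested ranks of a network's pollinators
#'
#' Orders pollinators from most to least generalized: decreasing number of
#' distinct plant partners, ties broken by decreasing total interaction
#' count, then alphabetically. Rank 1 is the most generalized species.
#'
#' @param M an [interaction_matrix()] or count matrix (typically a zone's
#'   pooled matrix)
#' @return a `nested_rank_table` data.frame: `pollinator`, `rank`, `degree`,
#'   `abundance`, ordered by rank.
#' @export
nested_rank <- function(M) {
  M <- as_interaction_matrix(M)
  degree <- colSums(unclass(M) > 0)
  abund <- colSums(M)
  ord <- order(-degree, -abund, colnames(M))
  out <- data.frame(
    pollinator = colnames(M)[ord],
    rank = seq_len(ncol(M)),
    degree = as.integer(degree[ord]),
    abundance = as.integer(abund[ord]),
    row.names = NULL
  )
  class(out) <- c("nested_rank_table", "data.frame")
  out
}
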