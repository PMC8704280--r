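#' Delete named pollinator columns from a matrix
#'
#' Species absent from the matrix are ignored; plant rows left with a zero
#' marginal are trimmed. Removing every pollinator is an error.
#'
#' @param M an [interaction_matrix()] or count matrix
#' @param species character vector of pollinator labels to delete
#' @return the trimmed [interaction_matrix()]
#' @export
remove_pollinators <- function(M, species) {
  M <- as_interaction_matrix(M)
  if (length(species) == 0) stop("species set must be nonempty")
  keep <- setdiff(colnames(M), species)
  if (length(keep) == 0) stop("empty network: all pollinator species removed")
  interaction_matrix(unclass(M)[, keep, drop = FALSE])
}

#' Simulated extinction of pollinators across a zone's sites
#'
#' Removes the named species from every site network, recomputes site-level
#' NODF, and reports the change in the zone mean. Sites where the species
#' never occurred keep their original NODF in the "after" mean; sites whose
#' matrix drops below the size at which NODF is defined are excluded from
#' both means, with a warning.
#'
#' @param zone a [pool_zone()] collection
#' @param species character vector of pollinator labels (may be empty, in
#'   which case the result records a 0 percent change)
#' @param absent_sites `"keep"` (default: unaffected sites retain their
#'   original NODF in the after-mean) or `"skip"` (only sites holding at
#'   least one removed species are averaged)
#' @return a `removal_result`: list with `removed`, `per_site` (data.frame
#'   `site`, `nodf_before`, `nodf_after`, `affected`, `excluded`),
#'   `mean_before`, `mean_after`, `percent_change`.
#' @export
simulate_removal <- function(zone, species, absent_sites = c("keep", "skip")) {
  stopifnot(inherits(zone, "zone_collection"))
  absent_sites <- match.arg(absent_sites)
  species <- unique(as.character(species))
  if (length(species) > 0) {
    seen <- vapply(species, function(sp)
      any(vapply(zone$sites, function(s) sp %in% colnames(s$matrix), TRUE)), TRUE)
    if (any(!seen))
      stop("value error: species absent from every site of zone '", zone$zone,
           "': ", paste(species[!seen], collapse = ", "))
  }
  rows <- lapply(zone$sites, function(s) {
    before <- nodf(s$matrix)
    hit <- any(species %in% colnames(s$matrix))
    after <- before
    excluded <- FALSE
    if (hit) {
      after <- tryCatch(nodf(remove_pollinators(s$matrix, species)),
                        error = function(e) NA_real_)
      if (is.na(after)) {
        excluded <- TRUE
        warning("site '", s$site, "' excluded: NODF undefined after removal")
      }
    }
    data.frame(site = s$site, nodf_before = before, nodf_after = after,
               affected = hit, excluded = excluded)
  })
  per_site <- do.call(rbind, rows)
  use <- !per_site$excluded
  if (absent_sites == "skip") use <- use & per_site$affected
  if (!any(use)) stop("no sites left to average after exclusions")
  mean_before <- mean(per_site$nodf_before[use])
  mean_after <- mean(per_site$nodf_after[use])
  pct <- if (length(species) == 0) 0 else
    100 * (mean_after - mean_before) / mean_before
  structure(list(removed = species, per_site = per_site,
                 mean_before = mean_before, mean_after = mean_after,
                 percent_change = pct),
            class = "removal_result")
}

#' @export
print.removal_result <- function(x, ...) {
  cat(sprintf(
    "removal_result: {%s}\n  mean NODF %.2f -> %.2f (%+.2f%%)\n",
    paste(x$removed, collapse = ", "), x$mean_before, x$mean_after,
    x$percent_change))
  invisible(x)
}

#' Batch removal experiment over nested ranks
#'
#' Runs one single-species [simulate_removal()] per requested rank of the
#' zone's [nested_rank()] table (ranks taken from the intact pooled network),
#' plus the combined removal of all of them.
#'
#' @param zone a [pool_zone()] collection
#' @param ranks integer vector of nested ranks (1 = most generalized)
#' @param absent_sites passed to [simulate_removal()]
#' @return list with one `removal_result` per rank (named by species) and a
#'   `combined` entry for the joint removal.
#' @export
rank_removal_sweep <- function(zone, ranks, absent_sites = "keep") {
  stopifnot(inherits(zone, "zone_collection"))
  tab <- nested_rank(zone$pooled)
  if (any(ranks < 1 | ranks > nrow(tab)))
    stop("ranks out of range 1..", nrow(tab))
  spp <- tab$pollinator[match(ranks, tab$rank)]
  out <- lapply(spp, function(sp)
    simulate_removal(zone, sp, absent_sites = absent_sites))
  names(out) <- spp
  out$combined <- simulate_removal(zone, spp, absent_sites = absent_sites)
  out
}
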