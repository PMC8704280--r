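#' Specimen-level visitation records
#'
#' One row per captured insect (or per aggregated observation when `count`
#' > 1): the habitat zone, the site within the zone, the sampling period,
#' the pollinator taxon, the host plant it was captured on, and optionally
#' the pollinator order-group (`bee`, `fly` or `lepidoptera`).
#'
#' @param df data.frame with columns `zone`, `site`, `period`, `pollinator`,
#'   `plant`, and optionally `group` and `count` (defaults to 1).
#' @return a validated `visit_records` data.frame.
#' @export
visit_records <- function(df) {
  required <- c("zone", "site", "period", "pollinator", "plant")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"group" %in% names(df)) df$group <- NA_character_
  if (!"count" %in% names(df)) df$count <- 1L
  for (col in c(required, "group")) df[[col]] <- trimws(as.character(df[[col]]))
  cnt <- suppressWarnings(as.numeric(df$count))
  bad <- which(is.na(cnt) | cnt < 1 | abs(cnt - round(cnt)) > 1e-8)
  if (length(bad) > 0)
    stop("value error: count must be a positive integer; offending row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  df$count <- as.integer(round(cnt))
  for (col in required) {
    empty <- which(is.na(df[[col]]) | df[[col]] == "")
    if (length(empty) > 0)
      stop("value error: empty '", col, "' in row(s): ",
           paste(utils::head(empty, 10), collapse = ", "))
  }
  df <- df[, c(required, "group", "count")]
  class(df) <- c("visit_records", "data.frame")
  df
}

#' Read specimen records from a long-format CSV
#'
#' Expected columns: `zone,site,period,pollinator,plant[,group][,count]`
#' (UTF-8, comma-delimited). Missing `count` defaults to one specimen per
#' row; malformed rows are rejected with their row numbers.
#'
#' @param path CSV file path
#' @return a `visit_records` data.frame
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no records in ", path)
  visit_records(df)
}

#' @rdname read_records
#' @param records a `visit_records` table
#' @export
write_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Aggregate records into one network per site
#'
#' Builds, for every distinct (zone, site) pair, the plant x pollinator
#' count matrix summed over all sampling periods and years. Species never
#' seen at a site are absent from that site's labels.
#'
#' @param records a [visit_records()] table (coerced if a plain data.frame)
#' @return list of `site_network` objects (fields `zone`, `site`, `matrix`),
#'   ordered by zone then site.
#' @export
build_site_networks <- function(records) {
  records <- visit_records(as.data.frame(records))
  if (nrow(records) == 0L) stop("empty record table")
  key <- interaction(records$zone, records$site, drop = TRUE, sep = "\r")
  out <- lapply(levels(key), function(k) {
    sub <- records[key == k, ]
    tab <- stats::xtabs(count ~ plant + pollinator, data = sub)
    structure(list(zone = sub$zone[1], site = sub$site[1],
                   matrix = interaction_matrix(unclass(tab))),
              class = "site_network")
  })
  ord <- order(vapply(out, function(s) s$zone, ""),
               vapply(out, function(s) s$site, ""))
  out[ord]
}

#' @export
print.site_network <- function(x, ...) {
  cat(sprintf("site_network %s/%s: ", x$zone, x$site))
  print(x$matrix)
  invisible(x)
}

#' Pool site networks into a zone-level collection
#'
#' Sums the site matrices over the union of their plant and pollinator
#' labels. A pollinator seen as a per-site singleton link at several sites
#' can therefore be a multi-partner generalist at the zone level.
#'
#' @param sites list of `site_network` objects sharing one zone label
#' @param groups optional named character vector mapping pollinator label to
#'   order-group (carried along for generalist tables)
#' @return a `zone_collection`: fields `zone`, `sites`, `pooled`
#'   (an [interaction_matrix()]) and `groups`.
#' @export
pool_zone <- function(sites, groups = NULL) {
  if (length(sites) == 0L) stop("no sites to pool")
  zones <- unique(vapply(sites, function(s) s$zone, ""))
  if (length(zones) != 1L)
    stop("value error: sites span multiple zones: ",
         paste(zones, collapse = ", "))
  plants <- sort(unique(unlist(lapply(sites, function(s) rownames(s$matrix)))))
  polls <- sort(unique(unlist(lapply(sites, function(s) colnames(s$matrix)))))
  pooled <- matrix(0L, length(plants), length(polls),
                   dimnames = list(plants, polls))
  for (s in sites)
    pooled[rownames(s$matrix), colnames(s$matrix)] <-
      pooled[rownames(s$matrix), colnames(s$matrix)] + unclass(s$matrix)
  structure(list(zone = zones, sites = sites,
                 pooled = interaction_matrix(pooled), groups = groups),
            class = "zone_collection")
}

#' @export
print.zone_collection <- function(x, ...) {
  cat(sprintf("zone_collection '%s': %d sites, pooled ", x$zone, length(x$sites)))
  print(x$pooled)
  invisible(x)
}

#' Build one zone_collection per zone straight from records
#'
#' @param records a [visit_records()] table
#' @param zone optional single zone label to restrict to
#' @return a named list of [pool_zone()] results (or a single
#'   `zone_collection` when `zone` is given)
#' @export
zones_from_records <- function(records, zone = NULL) {
  records <- visit_records(as.data.frame(records))
  if (!is.null(zone)) {
    records <- records[records$zone == zone, ]
    if (nrow(records) == 0L) stop("no records for zone ", zone)
  }
  groups_all <- species_groups(records)
  sites <- build_site_networks(records)
  zs <- unique(vapply(sites, function(s) s$zone, ""))
  out <- lapply(zs, function(z) {
    zsites <- Filter(function(s) s$zone == z, sites)
    g <- groups_all[intersect(names(groups_all), colnames(pool_zone(zsites)$pooled))]
    pool_zone(zsites, groups = g)
  })
  names(out) <- zs
  if (!is.null(zone)) out[[zone]] else out
}

species_groups <- function(records) {
  if (all(is.na(records$group))) return(NULL)
  tapply(records$group, records$pollinator, function(g) {
    g <- g[!is.na(g) & g != ""]
    if (length(g) == 0) NA_character_ else g[1]
  })
}
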