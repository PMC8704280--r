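#' Read a pipeline run configuration (YAML or JSON)
#'
#' Keyed on file extension: `.yml`/`.yaml` via the yaml package, anything
#' else parsed as JSON. See [run_pipeline()] for the recognised keys.
#'
#' @param path config file
#' @return a named list
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Run the full analysis pipeline
#'
#' Stages: obtain records (simulate a preset or read a CSV), build site and
#' zone networks, per-site metrics with zone means, Gc generalist tables,
#' targeted-removal experiments, and group-comparison statistics. All
#' outputs are written as TSV under `out_dir`, along with a `manifest.json`
#' recording package version, seeds, and a hash of the configuration. Any
#' stage failure aborts with the stage name attached.
#'
#' Config keys (all optional unless noted): exactly one input source, either
#' `records` (CSV path) or `simulate` (`preset: "gradient"`); `seed`;
#' `metrics` (`replicates`, `restarts`, `weighted_nodf`); `gc` (`threshold`,
#' `sd_mode`, `include_absent_sites`); `removal` (`zone`, `ranks` or
#' `species`); `stats` (list of `{response, family}`); `flower_counts`
#' (CSV path).
#'
#' @param config named list (see above) or path to a config file
#' @param out_dir output directory (created if absent); overrides
#'   `config$output`
#' @return (invisibly) list of in-memory results per stage
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config_path <- config
    config <- read_run_config(config)
  } else config_path <- NULL
  out_dir <- out_dir %||% config$output %||% stop("no output directory given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }

  has_records <- !is.null(config$records)
  has_sim <- !is.null(config$simulate)
  if (has_records == has_sim)
    stop("config must name exactly one input source: 'records' or 'simulate'")

  src <- stage("input", {
    if (has_records) {
      flw <- if (!is.null(config$flower_counts))
        utils::read.csv(config$flower_counts, stringsAsFactors = FALSE)
      list(records = read_records(config$records), flowers = flw)
    } else {
      preset <- config$simulate$preset %||% "gradient"
      if (!identical(preset, "gradient"))
        stop("unknown simulation preset: ", preset)
      sim <- preset_gradient(seed)
      recs <- visit_records(do.call(rbind, lapply(sim, function(z)
        as.data.frame(z$records))))
      flw <- do.call(rbind, lapply(sim, function(z) z$flowers))
      write_records(recs, file.path(out_dir, "records.csv"))
      utils::write.csv(flw, file.path(out_dir, "flower_counts.csv"),
                       row.names = FALSE)
      list(records = recs, flowers = flw)
    }
  })
  input <- src$records
  flowers <- src$flowers

  zones <- stage("build", zones_from_records(input))
  for (z in names(zones))
    write_matrix(zones[[z]]$pooled, file.path(out_dir, paste0("pooled_", z, ".csv")))

  mopt <- config$metrics %||% list()
  metrics <- stage("metrics", {
    res <- lapply(names(zones), function(z) {
      zm <- zone_metrics(zones[[z]],
                         replicates = mopt$replicates %||% 100,
                         seed = seed,
                         restarts = mopt$restarts %||% 10,
                         weighted_nodf = isTRUE(mopt$weighted_nodf))
      cbind(zm$per_site,
            data.frame(row_type = "site"))
    })
    per_site <- do.call(rbind, res)
    means <- do.call(rbind, lapply(names(zones), function(z) {
      zm <- per_site[per_site$zone == z, ]
      num <- zm[, !(names(zm) %in% c("zone", "site", "row_type"))]
      cbind(data.frame(zone = z, site = "(mean)"), t(colMeans(num)),
            data.frame(row_type = "zone_mean"))
    }))
    out <- rbind(per_site, means)
    tsv(out, "network_metrics.tsv")
    out
  })

  gopt <- config$gc %||% list()
  gc_tables <- stage("generalists", {
    res <- lapply(names(zones), function(z) {
      gt <- gc_scores(zones[[z]],
                      include_absent_sites = gopt$include_absent_sites %||% TRUE,
                      sd_mode = gopt$sd_mode %||% "sample")
      cov <- core_generalists(gt, threshold = gopt$threshold %||% 1.0)
      list(table = cbind(zone = z, gt), coverage = cov)
    })
    names(res) <- names(zones)
    tsv(do.call(rbind, lapply(res, `[[`, "table")), "gc_table.tsv")
    cov <- do.call(rbind, lapply(names(res), function(z)
      data.frame(zone = z,
                 coverage_individuals_pct = res[[z]]$coverage$coverage_individuals_pct,
                 coverage_interactions_pct = res[[z]]$coverage$coverage_interactions_pct)))
    tsv(cov, "gc_coverage.tsv")
    res
  })

  removal <- stage("remove", {
    ropt <- config$removal %||% list(zone = names(zones)[length(zones)],
                                     ranks = c(1, 2, 3))
    z <- ropt$zone %||% names(zones)[1]
    if (!z %in% names(zones)) stop("removal zone '", z, "' not in data")
    res <- if (!is.null(ropt$species)) {
      list(combined = simulate_removal(zones[[z]], unlist(ropt$species)))
    } else {
      rank_removal_sweep(zones[[z]], unlist(ropt$ranks %||% c(1, 2, 3)))
    }
    tab <- do.call(rbind, lapply(names(res), function(nm)
      data.frame(zone = z, removal = nm,
                 removed = paste(res[[nm]]$removed, collapse = ";"),
                 mean_nodf_before = res[[nm]]$mean_before,
                 mean_nodf_after = res[[nm]]$mean_after,
                 percent_change = res[[nm]]$percent_change)))
    tsv(tab, "removal_results.tsv")
    res
  })

  stats_res <- stage("stats", {
    ev <- summarize_events(input, flower_counts = flowers)
    tsv(ev, "event_summaries.tsv")
    specs <- config$stats %||% list(
      list(response = "pollinator_richness", family = "poisson"),
      list(response = "plant_richness", family = "gaussian"),
      list(response = "pollinator_abundance", family = "poisson"),
      list(response = "flower_abundance", family = "quasipoisson"))
    if (is.data.frame(specs))
      specs <- split(specs, seq_len(nrow(specs)))
    res <- lapply(specs, function(sp)
      compare_groups(ev, sp$response, family = sp$family))
    overall <- do.call(rbind, lapply(res, function(x)
      data.frame(response = x$response, family = x$family, df = x$df,
                 stat_type = x$stat_type, statistic = x$statistic,
                 p_value = x$p_value)))
    contr <- do.call(rbind, lapply(res, function(x)
      if (is.null(x$contrasts)) NULL else cbind(response = x$response, x$contrasts)))
    tsv(overall, "group_tests.tsv")
    if (!is.null(contr)) tsv(contr, "group_contrasts.tsv")
    res
  })

  manifest <- list(
    package = "pollinet",
    version = as.character(utils::packageVersion("pollinet")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_path = config_path,
    config_hash = config_hash(config),
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(zones = zones, metrics = metrics, gc = gc_tables,
                 removal = removal, stats = stats_res, manifest = manifest))
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE), tf)
  unname(tools::md5sum(tf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
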