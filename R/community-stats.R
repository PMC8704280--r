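#' Per-sampling-event richness and abundance summaries
#'
#' Collapses specimen records to one row per (zone, site, period) sampling
#' event: distinct pollinator and plant species, specimen count, and — when
#' a flower transect-count table is supplied — total flowers counted. Events
#' that were visited but yielded no captures can be declared through
#' `design` and appear as zero rows (undeclared empty events are simply
#' absent, i.e. treated as not sampled).
#'
#' @param records a [visit_records()] table
#' @param flower_counts optional data.frame `zone, site, period, plant,
#'   flowers`; every (zone, site) it references must appear in `records` or
#'   `design`
#' @param design optional data.frame `zone, site, period` declaring all
#'   visited events (for zero-filling)
#' @return data.frame `zone, site, period, pollinator_richness,
#'   plant_richness, pollinator_abundance, flower_abundance`
#' @export
summarize_events <- function(records, flower_counts = NULL, design = NULL) {
  records <- visit_records(as.data.frame(records))
  key <- function(d) paste(d$zone, d$site, d$period, sep = "\r")
  agg <- stats::aggregate(
    cbind(count) ~ zone + site + period, data = records, FUN = sum)
  names(agg)[names(agg) == "count"] <- "pollinator_abundance"
  rich_p <- stats::aggregate(pollinator ~ zone + site + period, data = records,
                             FUN = function(x) length(unique(x)))
  rich_h <- stats::aggregate(plant ~ zone + site + period, data = records,
                             FUN = function(x) length(unique(x)))
  out <- merge(merge(agg, rich_p, by = c("zone", "site", "period")),
               rich_h, by = c("zone", "site", "period"))
  names(out)[names(out) == "pollinator"] <- "pollinator_richness"
  names(out)[names(out) == "plant"] <- "plant_richness"
  if (!is.null(design)) {
    design <- unique(design[, c("zone", "site", "period")])
    miss <- design[!(key(design) %in% key(out)), , drop = FALSE]
    if (nrow(miss) > 0) {
      miss$pollinator_abundance <- 0L
      miss$pollinator_richness <- 0L
      miss$plant_richness <- 0L
      out <- rbind(out, miss[, names(out)])
    }
  }
  out$flower_abundance <- NA_real_
  if (!is.null(flower_counts)) {
    fc <- flower_counts
    need <- c("zone", "site", "period", "flowers")
    if (!all(need %in% names(fc)))
      stop("flower table must have columns zone, site, period, flowers")
    declared <- unique(paste(records$zone, records$site, sep = "\r"))
    if (!is.null(design))
      declared <- unique(c(declared, paste(design$zone, design$site, sep = "\r")))
    bad <- !(paste(fc$zone, fc$site, sep = "\r") %in% declared)
    if (any(bad))
      stop("flower table references undeclared site(s): ",
           paste(unique(paste(fc$zone[bad], fc$site[bad], sep = "/")), collapse = ", "))
    fa <- stats::aggregate(flowers ~ zone + site + period, data = fc, FUN = sum)
    idx <- match(key(out), key(fa))
    out$flower_abundance <- fa$flowers[idx]
  }
  out <- out[order(out$zone, out$site, out$period),
             c("zone", "site", "period", "pollinator_richness", "plant_richness",
               "pollinator_abundance", "flower_abundance")]
  rownames(out) <- NULL
  out
}

#' GLM comparison of a response across zones, with pairwise contrasts
#'
#' Fits `response ~ zone` under the requested family (log link for the
#' Poisson families, identity for Gaussian). The overall test is an F test
#' on the deviance drop when dispersion is estimated (gaussian,
#' quasipoisson) and a deviance chi-square otherwise (poisson). Pairwise
#' differences of the estimated marginal means are formed on the link scale
#' with Tukey adjustment of the p-values (`ptukey` on the studentized
#' range), the standard practice after a marginal-means fit.
#'
#' @param summaries data.frame such as [summarize_events()] output
#' @param response name of the response column
#' @param family `"gaussian"`, `"poisson"` or `"quasipoisson"`
#' @param group name of the grouping column (default `"zone"`)
#' @return a `group_comparison`: list with `response`, `family`, `df`
#'   (between groups), `stat_type` (`"F"` or `"Chisq"`), `statistic`,
#'   `p_value`, `dispersion`, `degenerate` flag, `emm` (marginal means on
#'   the link scale), and `contrasts` (data.frame `contrast, estimate, se,
#'   statistic, p_adj`).
#' @export
compare_groups <- function(summaries, response,
                           family = c("gaussian", "poisson", "quasipoisson"),
                           group = "zone") {
  family <- match.arg(family)
  if (!response %in% names(summaries)) stop("no column '", response, "'")
  dat <- data.frame(y = summaries[[response]],
                    g = factor(summaries[[group]]))
  dat <- dat[stats::complete.cases(dat), ]
  k <- nlevels(droplevels(dat$g))
  dat$g <- droplevels(dat$g)
  if (k < 2) stop("need at least 2 groups")
  if (any(table(dat$g) < 2)) stop("need at least 2 observations per group")
  fam <- switch(family,
                gaussian = stats::gaussian(),
                poisson = stats::poisson(),
                quasipoisson = stats::quasipoisson())

  degenerate <- stats::var(dat$y) < 1e-12
  if (degenerate) {
    return(structure(list(
      response = response, family = family, df = k - 1L,
      stat_type = if (family == "poisson") "Chisq" else "F",
      statistic = 0, p_value = 1, dispersion = 0, degenerate = TRUE,
      emm = stats::setNames(rep(fam$linkfun(dat$y[1]), k), levels(dat$g)),
      contrasts = NULL), class = "group_comparison"))
  }

  fit <- stats::glm(y ~ g, data = dat, family = fam)
  fit0 <- stats::glm(y ~ 1, data = dat, family = fam)
  df1 <- k - 1L
  df2 <- fit$df.residual
  dev_drop <- fit0$deviance - fit$deviance
  # summary.glm's moment estimate, so contrasts and F share one dispersion
  disp <- if (family == "poisson") 1 else summary(fit)$dispersion
  if (family == "poisson") {
    stat <- dev_drop
    stat_type <- "Chisq"
    p <- stats::pchisq(stat, df1, lower.tail = FALSE)
  } else {
    stat <- (dev_drop / df1) / disp
    stat_type <- "F"
    p <- stats::pf(stat, df1, df2, lower.tail = FALSE)
  }

  # marginal means on the link scale and their covariance
  lv <- levels(dat$g)
  X <- stats::model.matrix(~ g, data = data.frame(g = factor(lv, levels = lv)))
  beta <- stats::coef(fit)
  V <- X %*% summary(fit)$cov.scaled %*% t(X)
  emm <- stats::setNames(as.vector(X %*% beta), lv)
  pairs <- utils::combn(lv, 2)
  tukey_df <- if (family == "poisson") Inf else df2
  contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(p2) {
    a <- pairs[1, p2]; b <- pairs[2, p2]
    est <- emm[a] - emm[b]
    se <- sqrt(V[match(a, lv), match(a, lv)] + V[match(b, lv), match(b, lv)] -
                 2 * V[match(a, lv), match(b, lv)])
    z <- est / se
    padj <- stats::ptukey(sqrt(2) * abs(z), nmeans = k, df = min(tukey_df, 1e7),
                          lower.tail = FALSE)
    data.frame(contrast = paste(a, "-", b), estimate = unname(est),
               se = unname(se), statistic = unname(z), p_adj = padj,
               row.names = NULL)
  }))
  structure(list(response = response, family = family, df = df1,
                 stat_type = stat_type, statistic = unname(stat),
                 p_value = unname(p), dispersion = disp, degenerate = FALSE,
                 emm = emm, contrasts = contrasts),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("GLM (%s): %s ~ group; df = %d, %s = %.3f, p = %.4g\n",
              x$family, x$response, x$df, x$stat_type, x$statistic, x$p_value))
  if (!is.null(x$contrasts)) {
    cat("pairwise contrasts (link scale, Tukey-adjusted):\n")
    print(x$contrasts, digits = 4)
  }
  invisible(x)
}
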