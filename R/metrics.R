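#' Weighted connectance of a bipartite network
#'
#' Weighted linkage density divided by species count. With \eqn{m = \sum
#' a_{ij}} and \eqn{H_i} the base-2 Shannon entropy of row \eqn{i}'s
#' interaction distribution (analogously \eqn{H_j} for columns), the weighted
#' linkage density is
#' \deqn{LD_w = \frac12\Big[\sum_j \frac{a_{\cdot j}}{m} 2^{H_j} +
#'   \sum_i \frac{a_{i\cdot}}{m} 2^{H_i}\Big]}
#' and connectance is \eqn{LD_w / (P + Q)} for \eqn{P} plants and \eqn{Q}
#' pollinators. \eqn{2^{H}} is the effective number of partners, so the
#' index discounts rare, low-weight links; it lies in \eqn{(0, 0.5]}, with
#' 0.5 attained only when every species spreads its interactions uniformly.
#'
#' @param M an [interaction_matrix()] (or coercible count matrix)
#' @return numeric scalar in (0, 0.5]
#' @export
weighted_connectance <- function(M) {
  M <- as_interaction_matrix(M)
  m <- sum(M)
  ent2 <- function(v) {
    p <- v[v > 0] / sum(v)
    -sum(p * log2(p))
  }
  Hrow <- apply(M, 1, ent2)
  Hcol <- apply(M, 2, ent2)
  ldw <- 0.5 * (sum(colSums(M) / m * 2^Hcol) + sum(rowSums(M) / m * 2^Hrow))
  ldw / (nrow(M) + ncol(M))
}

#' Nestedness based on overlap and decreasing fill (NODF)
#'
#' For every ordered pair of rows (and of columns) whose marginal totals
#' strictly decrease, the paired nestedness is 100 times the fraction of the
#' poorer member's presences shared with the richer member; pairs with equal
#' totals contribute 0. NODF is the sum over all row pairs and column pairs
#' divided by \eqn{P(P-1)/2 + Q(Q-1)/2}, giving a 0-100 scale. The default
#' binarizes counts to presence/absence (the classic decreasing-fill
#' definition); `weighted = TRUE` computes the quantitative variant in which
#' a poorer column/row cell contributes only when its count is strictly
#' smaller than the richer one's.
#'
#' @param M an [interaction_matrix()] or count matrix
#' @param weighted logical; compute the weighted (WNODF-style) variant
#' @return numeric scalar in \[0, 100\]
#' @export
nodf <- function(M, weighted = FALSE) {
  M <- as_interaction_matrix(M)
  P <- nrow(M)
  Q <- ncol(M)
  if (P < 2 && Q < 2) stop("NODF undefined: need at least 2 rows or 2 columns")
  axis_sum <- function(X) {
    # X: species-by-feature count matrix; pairs taken among rows of X
    n <- nrow(X)
    if (n < 2) return(0)
    tot <- rowSums(X)
    s <- 0
    for (a in seq_len(n - 1)) {
      for (b in seq((a + 1), n)) {
        if (tot[a] == tot[b]) next
        rich <- if (tot[a] > tot[b]) a else b
        poor <- if (tot[a] > tot[b]) b else a
        fill_poor <- sum(X[poor, ] > 0)
        if (fill_poor == 0) next
        if (weighted) {
          hit <- sum(X[poor, ] > 0 & X[poor, ] < X[rich, ])
        } else {
          hit <- sum(X[poor, ] > 0 & X[rich, ] > 0)
        }
        s <- s + 100 * hit / fill_poor
      }
    }
    s
  }
  X <- if (weighted) unclass(M) else (unclass(M) > 0) * 1L
  (axis_sum(X) + axis_sum(t(X))) / (P * (P - 1) / 2 + Q * (Q - 1) / 2)
}

#' H2' network-level specialization
#'
#' Two-dimensional Shannon entropy of the interaction frequencies,
#' standardized between the most and least specialized configurations
#' compatible with the observed marginal totals:
#' \deqn{H_2' = \frac{H_{2max} - H_2}{H_{2max} - H_{2min}}}
#' where \eqn{H_2 = -\sum p_{ij}\ln p_{ij}} with \eqn{p_{ij} = a_{ij}/m};
#' \eqn{H_{2max}} is the entropy of the outer product of the marginal
#' frequencies (fully opportunistic partner use), and \eqn{H_{2min}} is the
#' entropy of a deterministic greedy minimum-entropy integer fill of the
#' marginals (see [h2_min_fill()]). 0 means partner use follows availability
#' exactly; 1 means the network is as selective as its totals permit. The
#' ratio is clipped into \[0, 1\].
#'
#' @param M an [interaction_matrix()] or count matrix
#' @return numeric scalar in \[0, 1\]
#' @export
h2_prime <- function(M) {
  M <- as_interaction_matrix(M)
  m <- sum(M)
  if (m < 2) stop("H2' undefined: need at least 2 interactions")
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  h2 <- ent(unclass(M) / m)
  r <- rowSums(M) / m
  cc <- colSums(M) / m
  h2max <- ent(as.vector(outer(r, cc)))
  h2min <- ent(h2_min_fill(rowSums(M), colSums(M)) / m)
  if (h2max - h2min < 1e-12)
    stop("H2' degenerate: marginal totals admit a single configuration")
  min(max((h2max - h2) / (h2max - h2min), 0), 1)
}

#' Greedy minimum-entropy fill of integer marginals
#'
#' Repeatedly places `min(remaining row total, remaining column total)` into
#' the admissible cell where that minimum is largest; ties are broken by
#' lowest row index, then lowest column index. The resulting matrix has the
#' given marginals and (at the sizes used here, verified by exhaustive
#' enumeration in the test suite) the minimum Shannon entropy attainable
#' under them.
#'
#' @param row_totals,col_totals non-negative integer vectors with equal sums
#' @return integer matrix with the requested marginals
#' @export
h2_min_fill <- function(row_totals, col_totals) {
  if (abs(sum(row_totals) - sum(col_totals)) > 1e-8)
    stop("row and column totals must have equal sums")
  P <- length(row_totals)
  Q <- length(col_totals)
  fill <- matrix(0L, P, Q)
  rs <- as.numeric(row_totals)
  cs <- as.numeric(col_totals)
  while (sum(rs) > 0.5) {
    cap <- outer(rs, cs, pmin)
    cap[rs <= 0, ] <- -1
    cap[, cs <= 0] <- -1
    # which.max on the transposed-order scan: R scans column-major, so take
    # the first linear index of the max, which is lowest column among ties;
    # we need lowest row then column, so scan the transpose.
    idx <- which(t(cap) == max(cap), arr.ind = TRUE)[1, ]
    # scanning t(cap) column-major = cap row-major, so the first hit is the
    # lowest-row, then lowest-column tie-break; idx is (col, row) of cap
    i <- idx[2]
    j <- idx[1]
    v <- min(rs[i], cs[j])
    fill[i, j] <- fill[i, j] + as.integer(v)
    rs[i] <- rs[i] - v
    cs[j] <- cs[j] - v
  }
  fill
}

#' Pollinator robustness to sequential plant loss
#'
#' Removes plants one at a time in random order; after each removal a
#' pollinator survives iff it retains at least one link. The attack-tolerance
#' curve (x = fraction of plants removed at steps 0..P, y = fraction of
#' pollinators surviving) is integrated by the trapezoid rule and R is the
#' mean area across replicates. A complete bipartite network with P plants
#' gives exactly (2P-1)/(2P); fragile networks fall toward 0.5 and below.
#'
#' @param M an [interaction_matrix()] or count matrix
#' @param replicates number of random removal orders to average over
#' @param seed optional integer seed (local to this call)
#' @param order `"random"` (default), or the deterministic
#'   `"degree_asc"` / `"degree_desc"` orders (least/most-connected plant
#'   first), in which case a single pass is made
#' @return numeric scalar in (0, 1)
#' @export
robustness_pollinators <- function(M, replicates = 100, seed = NULL,
                                   order = c("random", "degree_asc", "degree_desc")) {
  M <- as_interaction_matrix(M)
  order <- match.arg(order)
  B <- unclass(M) > 0
  P <- nrow(B)
  area <- function(ord) {
    y <- numeric(P + 1)
    y[1] <- 1
    present <- rep(TRUE, P)
    for (k in seq_len(P)) {
      present[ord[k]] <- FALSE
      y[k + 1] <- sum(colSums(B[present, , drop = FALSE]) > 0) / ncol(B)
    }
    sum((y[-1] + y[-(P + 1)]) / 2) / P
  }
  if (order != "random") {
    deg <- rowSums(B)
    ord <- order(deg, decreasing = (order == "degree_desc"))
    return(area(ord))
  }
  with_seed(seed, mean(vapply(seq_len(replicates),
                              function(r) area(sample.int(P)), 0)))
}

# Evaluate expr with a locally-set RNG seed, restoring global state after.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' All network-level indices of one interaction matrix
#'
#' @param M an [interaction_matrix()] or count matrix
#' @param replicates,seed passed to [robustness_pollinators()]
#' @param restarts passed to [modularity_bipartite()]
#' @param weighted_nodf logical, passed to [nodf()]
#' @return one-row data.frame with `connectance_w` (and `connectance_w_100`,
#'   the same value x 100), `nodf`, `modularity_q`, `h2_prime`,
#'   `robustness_r`, `n_plants`, `n_pollinators`, `n_links`, `m`.
#' @export
network_metrics <- function(M, replicates = 100, seed = NULL, restarts = 10,
                            weighted_nodf = FALSE) {
  M <- as_interaction_matrix(M)
  cw <- weighted_connectance(M)
  data.frame(
    connectance_w = cw,
    connectance_w_100 = 100 * cw,
    nodf = nodf(M, weighted = weighted_nodf),
    modularity_q = modularity_bipartite(M, seed = if (is.null(seed)) 1L else seed,
                                        restarts = restarts)$q,
    h2_prime = h2_prime(M),
    robustness_r = robustness_pollinators(M, replicates = replicates, seed = seed),
    n_plants = n_plants(M),
    n_pollinators = n_pollinators(M),
    n_links = n_links(M),
    m = total_interactions(M)
  )
}

#' Per-site indices and their zone means
#'
#' Computes [network_metrics()] for every site of a zone and averages them
#' arithmetically, the zone-level reporting convention for gradient
#' comparisons.
#'
#' @param zone a [pool_zone()] collection
#' @inheritParams network_metrics
#' @return list with `per_site` (data.frame, one row per site, `site` first)
#'   and `means` (named numeric vector over the five indices plus sizes)
#' @export
zone_metrics <- function(zone, replicates = 100, seed = NULL, restarts = 10,
                         weighted_nodf = FALSE) {
  stopifnot(inherits(zone, "zone_collection"), length(zone$sites) >= 1)
  rows <- lapply(zone$sites, function(s) {
    row <- tryCatch(
      network_metrics(s$matrix, replicates = replicates, seed = seed,
                      restarts = restarts, weighted_nodf = weighted_nodf),
      error = function(e) stop("site '", s$site, "': ", conditionMessage(e),
                               call. = FALSE))
    cbind(data.frame(zone = s$zone, site = s$site), row)
  })
  per_site <- do.call(rbind, rows)
  num <- per_site[, !(names(per_site) %in% c("zone", "site"))]
  list(per_site = per_site, means = colMeans(num))
}
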