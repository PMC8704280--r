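#' Barber bipartite modularity of a labelled partition
#'
#' \deqn{Q = \frac{1}{m}\sum_{ij}\Big[a_{ij} -
#'   \frac{a_{i\cdot} a_{\cdot j}}{m}\Big]\,\delta(g_i, g_j)}
#' where \eqn{g_i}, \eqn{g_j} are the module labels of plant \eqn{i} and
#' pollinator \eqn{j}. Q is 0 for the single-module partition and can reach
#' 0.5 for a perfectly two-block network; the theoretical range is
#' \eqn{[-0.5, 1]}.
#'
#' @param M an [interaction_matrix()] or count matrix
#' @param row_modules,col_modules module labels for rows / columns
#' @return numeric scalar
#' @export
barber_q <- function(M, row_modules, col_modules) {
  M <- unclass(as_interaction_matrix(M))
  stopifnot(length(row_modules) == nrow(M), length(col_modules) == ncol(M))
  m <- sum(M)
  expected <- outer(rowSums(M), colSums(M)) / m
  same <- outer(row_modules, col_modules, "==")
  sum((M - expected)[same]) / m
}

#' Maximize Barber bipartite modularity
#'
#' Label propagation with agglomerative merging (LPAwb+-style): each plant
#' starts in its own module; rows and columns are alternately reassigned to
#' the module maximizing their Q contribution until no sweep improves Q;
#' module pairs are then greedily merged while Q increases. The best of
#' `restarts` seeded random sweep orders is returned, so the result is
#' deterministic given (matrix, seed, restarts). Exact on small networks
#' (verified against exhaustive partition search in the test suite);
#' heuristic, as all modularity maximizers are, on large ones.
#'
#' @param M an [interaction_matrix()] or count matrix
#' @param seed integer seed for the restart orders (local to this call)
#' @param restarts number of random restarts
#' @return a `module_partition`: list with `row_modules`, `col_modules`
#'   (named integer vectors, labels renumbered 1..k) and `q`.
#' @export
modularity_bipartite <- function(M, seed = 1L, restarts = 10L) {
  M <- as_interaction_matrix(M)
  A <- unclass(M)
  m <- sum(A)
  P <- nrow(A)
  Q <- ncol(A)
  K <- rowSums(A)
  D <- colSums(A)
  # null-model-corrected weights; Q of a partition is sum of W over
  # same-module (i, j) pairs divided by m
  W <- A - outer(K, D) / m

  run_once <- function(init_k = NULL) {
    if (is.null(init_k)) {
      # classic start: every plant its own module, columns join their best
      gr <- sample.int(P)
      gc <- integer(Q)
      for (j in seq_len(Q)) {
        sc <- vapply(unique(gr), function(t) sum(W[gr == t, j]), 0)
        gc[j] <- unique(gr)[which.max(sc)]
      }
    } else {
      # random coarse start: both sides scattered over init_k labels;
      # diversifies the restart basins
      gr <- sample.int(init_k, P, replace = TRUE)
      gc <- sample.int(init_k, Q, replace = TRUE)
    }
    q <- sum(W[outer(gr, gc, "==")]) / m
    propagate <- function() {
      repeat {
        for (i in sample.int(P)) {
          # -i is a guaranteed-fresh singleton label (score 0), taken when
          # every existing module has a negative contribution for this row
          labs <- unique(c(gr, gc, -i))
          sc <- vapply(labs, function(t) sum(W[i, gc == t]), 0)
          gr[i] <<- labs[which.max(sc)]
        }
        for (j in sample.int(Q)) {
          labs <- unique(c(gr, gc, -(P + j)))
          sc <- vapply(labs, function(t) sum(W[gr == t, j]), 0)
          gc[j] <<- labs[which.max(sc)]
        }
        q2 <- sum(W[outer(gr, gc, "==")]) / m
        if (q2 <= q + 1e-12) break
        q <<- q2
      }
    }
    # one greedy merge of the best-improving module pair; TRUE if it merged
    merge_best <- function() {
      labs <- unique(c(gr, gc))
      if (length(labs) < 2) return(FALSE)
      best_gain <- 1e-12
      best_pair <- NULL
      for (a in seq_len(length(labs) - 1)) {
        for (b in seq((a + 1), length(labs))) {
          # merging modules a,b adds the cross terms between them
          ra <- gr == labs[a]; rb <- gr == labs[b]
          ca <- gc == labs[a]; cb <- gc == labs[b]
          gain <- (sum(W[ra, cb, drop = FALSE]) + sum(W[rb, ca, drop = FALSE])) / m
          if (gain > best_gain) {
            best_gain <- gain
            best_pair <- c(labs[a], labs[b])
          }
        }
      }
      if (is.null(best_pair)) return(FALSE)
      gr[gr == best_pair[2]] <<- best_pair[1]
      gc[gc == best_pair[2]] <<- best_pair[1]
      q <<- q + best_gain
      TRUE
    }
    # one Kernighan-Lin chain: force every node through its best single move
    # (negative gains allowed, each node moves once), keep the best prefix;
    # escapes local optima that single-move and pair-merge steps cannot leave
    kl_improve <- function() {
      q0 <- q
      gr0 <- gr
      gc0 <- gc
      best_q <- q
      best_gr <- gr
      best_gc <- gc
      movable <- rep(TRUE, P + Q)
      for (step in seq_len(P + Q)) {
        labs <- unique(c(gr, gc))
        fresh <- min(labs, 0L) - 1L # guaranteed-unoccupied singleton label
        rind <- outer(gr, labs, "==") * 1
        cind <- outer(gc, labs, "==") * 1
        srow <- W %*% cind          # srow[i, t]: row i's affinity for label t
        scol <- crossprod(W, rind)  # scol[j, t]: column j's
        cur_r <- srow[cbind(seq_len(P), match(gr, labs))]
        cur_c <- scol[cbind(seq_len(Q), match(gc, labs))]
        gain_r <- srow - cur_r      # move gains; a fresh label has score 0
        gain_c <- scol - cur_c
        gain_r[cbind(seq_len(P), match(gr, labs))] <- -Inf
        gain_c[cbind(seq_len(Q), match(gc, labs))] <- -Inf
        best <- -Inf
        pick <- NULL
        for (i in seq_len(P)) {
          if (!movable[i]) next
          g <- max(gain_r[i, ], -cur_r[i]) # -cur_r[i]: detach to fresh label
          if (g > best) {
            best <- g
            t <- if (-cur_r[i] > max(gain_r[i, ])) fresh else
              labs[which.max(gain_r[i, ])]
            pick <- list(row = TRUE, idx = i, lab = t)
          }
        }
        for (j in seq_len(Q)) {
          if (!movable[P + j]) next
          g <- max(gain_c[j, ], -cur_c[j])
          if (g > best) {
            best <- g
            t <- if (-cur_c[j] > max(gain_c[j, ])) fresh else
              labs[which.max(gain_c[j, ])]
            pick <- list(row = FALSE, idx = j, lab = t)
          }
        }
        if (is.null(pick)) break
        if (pick$row) gr[pick$idx] <- pick$lab else gc[pick$idx] <- pick$lab
        movable[if (pick$row) pick$idx else P + pick$idx] <- FALSE
        q <- q + best / m
        if (q > best_q + 1e-12) {
          best_q <- q
          best_gr <- gr
          best_gc <- gc
        }
      }
      if (best_q > q0 + 1e-12) {
        q <<- best_q
        gr <<- best_gr
        gc <<- best_gc
        TRUE
      } else {
        q <<- q0
        gr <<- gr0
        gc <<- gc0
        FALSE
      }
    }
    # alternate propagation sweeps, agglomerative merges and KL chains until
    # none of them improves Q
    repeat {
      propagate()
      if (merge_best()) next
      if (!kl_improve()) break
    }
    list(q = q, gr = gr, gc = gc)
  }

  best <- with_seed(seed, {
    res <- lapply(seq_len(max(1L, restarts)), function(r) {
      if (r == 1) run_once() else
        run_once(init_k = sample(2:max(2L, min(P, Q)), 1))
    })
    res[[which.max(vapply(res, function(x) x$q, 0))]]
  })
  relab <- match(c(best$gr, best$gc), unique(c(best$gr, best$gc)))
  structure(list(
    row_modules = stats::setNames(relab[seq_len(P)], rownames(M)),
    col_modules = stats::setNames(relab[P + seq_len(Q)], colnames(M)),
    q = best$q
  ), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules, Q = %.4f\n",
              length(unique(c(x$row_modules, x$col_modules))), x$q))
  invisible(x)
}
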