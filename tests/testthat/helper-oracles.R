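# Independent oracles, written straight from the definitions before the
# implementation and kept free of package internals. Each mirrors a package
# routine through a different route: brute-force pairwise loops, exhaustive
# enumeration, or closed-form textbook formulas.

# NODF: explicit double loop over row pairs and column pairs
oracle_nodf <- function(M) {
  B <- (unclass(M) > 0) * 1
  P <- nrow(B)
  Q <- ncol(B)
  pair <- function(a, b) {
    fa <- sum(a); fb <- sum(b)
    if (fa > fb && fb > 0) return(100 * sum(a & b) / fb)
    if (fb > fa && fa > 0) return(100 * sum(a & b) / fa)
    0
  }
  tot <- 0
  if (P > 1) for (i in 1:(P - 1)) for (k in (i + 1):P) tot <- tot + pair(B[i, ], B[k, ])
  if (Q > 1) for (i in 1:(Q - 1)) for (k in (i + 1):Q) tot <- tot + pair(B[, i], B[, k])
  tot / (P * (P - 1) / 2 + Q * (Q - 1) / 2)
}

shannon <- function(M) {
  p <- M[M > 0] / sum(M)
  -sum(p * log(p))
}

# minimum Shannon entropy over ALL non-negative integer matrices with the
# given marginals, by exhaustive recursion (feasible for m <= ~12)
oracle_h2min_enum <- function(row_totals, col_totals) {
  P <- length(row_totals)
  Q <- length(col_totals)
  best <- Inf
  rec <- function(i, cs_rem, acc) {
    if (i > P) {
      best <<- min(best, shannon(acc))
      return(invisible())
    }
    row <- integer(Q)
    comp <- function(j, rem) {
      if (j == Q) {
        if (rem <= cs_rem[Q]) {
          row[Q] <<- rem
          acc2 <- acc
          acc2[i, ] <- row
          rec(i + 1, cs_rem - row, acc2)
        }
        return(invisible())
      }
      for (v in 0:min(rem, cs_rem[j])) {
        row[j] <<- v
        comp(j + 1, rem - v)
      }
    }
    comp(1, row_totals[i])
    invisible()
  }
  rec(1, col_totals, matrix(0, P, Q))
  best
}

# maximum Barber Q over all set partitions of the P+Q species (restricted
# growth strings); feasible for P+Q <= ~10
oracle_exhaustive_q <- function(M) {
  A <- unclass(M)
  P <- nrow(A)
  Q <- ncol(A)
  m <- sum(A)
  W <- A - outer(rowSums(A), colSums(A)) / m
  n <- P + Q
  best <- -Inf
  a <- integer(n)
  rec <- function(k, mx) {
    if (k > n) {
      gr <- a[1:P]
      gc <- a[(P + 1):n]
      q <- sum(W[outer(gr, gc, "==")]) / m
      if (q > best) best <<- q
      return(invisible())
    }
    for (v in 1:(mx + 1)) {
      a[k] <<- v
      rec(k + 1, max(mx, v))
    }
    invisible()
  }
  rec(1, 0L)
  best
}

# exact robustness: mean trapezoid area over every plant-removal order
oracle_robustness_exact <- function(M) {
  B <- unclass(M) > 0
  P <- nrow(B)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  area <- function(ord) {
    present <- rep(TRUE, P)
    y <- numeric(P + 1)
    y[1] <- 1
    for (k in seq_len(P)) {
      present[ord[k]] <- FALSE
      y[k + 1] <- sum(colSums(B[present, , drop = FALSE]) > 0) / ncol(B)
    }
    sum((y[-1] + y[-(P + 1)]) / 2) / P
  }
  mean(vapply(perms(seq_len(P)), area, 0))
}

# textbook one-way ANOVA F
oracle_anova_f <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g)
  n <- length(y)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  (ssb / (k - 1)) / (ssw / (n - k))
}
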