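# Independent oracles used across the suite. Each is deliberately naive
# (enumeration / closed form) and shares no code with the package internals.

# Phylogenetic covariance by explicit root-to-tip path enumeration:
# V[i, j] = summed length of the edges shared by the two tip paths.
cov_oracle <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  m <- max(tree$edge)
  parent <- integer(m)
  elen <- numeric(m)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_edges <- function(tip) {
    p <- integer(0)
    node <- tip
    while (node != root) {
      p <- c(p, node)
      node <- parent[node]
    }
    p
  }
  paths <- lapply(seq_len(n), path_edges)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in i:n) {
      V[i, j] <- V[j, i] <- sum(elen[intersect(paths[[i]], paths[[j]])])
    }
  }
  V
}

# All nonnegative integer tables with the given margins (tiny cases only).
enumerate_tables <- function(r, c) {
  comps <- function(total, caps) {
    if (length(caps) == 1) {
      if (total <= caps) return(list(total)) else return(list())
    }
    out <- list()
    for (k in 0:min(total, caps[1])) {
      for (rest in comps(total - k, caps[-1])) out <- c(out, list(c(k, rest)))
    }
    out
  }
  if (length(r) == 1) {
    return(lapply(comps(r, c), function(x) matrix(x, 1)))
  }
  res <- list()
  for (x in comps(r[1], c)) {
    for (sub in enumerate_tables(r[-1], c - x)) {
      res <- c(res, list(rbind(x, sub, deparse.level = 0)))
    }
  }
  res
}

# Exact probability of a table under conditional independence given margins.
table_prob <- function(tab, r, c) {
  exp(sum(lfactorial(r)) + sum(lfactorial(c)) -
        lfactorial(sum(r)) - sum(lfactorial(tab)))
}

# Closed-form simple linear regression (the OLS oracle for star-tree PGLS).
ols_oracle <- function(y, x) {
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  c(intercept = b0, slope = b1)
}

# A small deterministic habitat grid: left third natural, middle agricultural,
# right third urban, on a unit-degree bbox.
toy_grid <- function() {
  cls <- matrix("natural", 3, 3)
  cls[, 2] <- "agricultural"
  cls[, 3] <- "urban"
  habitat_grid(cls, bbox = c(0, 3, 0, 3))
}

random_margins <- function(n_r, n_c, N) {
  r <- as.vector(stats::rmultinom(1, N, rep(1, n_r)))
  c <- as.vector(stats::rmultinom(1, N, rep(1, n_c)))
  list(r = r, c = c)
}
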