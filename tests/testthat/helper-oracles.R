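# Independent oracles used across the suite. These deliberately avoid the
# implementation paths they check.

# brute-force CpG o/e: character-by-character counting
brute_cpg_oe <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  keep <- v != "N"
  n_c <- sum(v == "C"); n_g <- sum(v == "G")
  L <- sum(keep)
  n_cpg <- 0L
  for (i in seq_len(length(v) - 1L))
    if (v[i] == "C" && v[i + 1L] == "G") n_cpg <- n_cpg + 1L
  if (n_c == 0L || n_g == 0L || L < 2L) return(NA_real_)
  (n_cpg / (n_c * n_g)) * (L^2 / (L - 1))
}

# independent motif scan: sliding window comparison
brute_find_sites <- function(seq, motif) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  m <- strsplit(motif, "", fixed = TRUE)[[1L]]
  w <- length(m)
  hits <- integer(0)
  for (i in seq_len(length(v) - w + 1L))
    if (all(v[i:(i + w - 1L)] == m)) hits <- c(hits, i - 1L)
  hits
}

# Exhaustive Dollo oracle: minimal loss count over ALL 0/1 node-state
# assignments with exactly one gain, per leaf-presence pattern. Returns a
# vector indexed by the presence pattern's binary key (leaf i contributes
# 2^(i-1)); entry for the all-absent pattern is NA.
dollo_oracle_table <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  edge <- tree$edge
  root <- setdiff(edge[, 1L], edge[, 2L])
  states <- as.matrix(expand.grid(rep(list(0:1), n_all), KEEP.OUT.ATTRS = FALSE))
  pa <- states[, edge[, 1L], drop = FALSE]
  ch <- states[, edge[, 2L], drop = FALSE]
  gains <- rowSums(pa == 0L & ch == 1L) + states[, root]
  losses <- rowSums(pa == 1L & ch == 0L)
  keys <- as.integer(states[, seq_len(n_tip), drop = FALSE] %*%
                       2^(seq_len(n_tip) - 1L))
  out <- rep(NA_real_, 2^n_tip)
  ok <- gains == 1L
  for (i in which(ok)) {
    k <- keys[i] + 1L
    if (is.na(out[k]) || losses[i] < out[k]) out[k] <- losses[i]
  }
  out
}

# random rooted tree, possibly polytomous (short internal branches collapsed)
random_test_tree <- function(n_leaves, polytomy_prob = 0.5) {
  tr <- ape::rtree(n_leaves, tip.label = paste0("s", seq_len(n_leaves)))
  if (stats::runif(1) < polytomy_prob && n_leaves >= 4L)
    tr <- ape::di2multi(tr, tol = stats::quantile(tr$edge.length, 0.3))
  tr
}

# Holm step-down computed from the definition (independent of p.adjust)
holm_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(cummax((m - seq_len(m) + 1L) * p[o]), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# trapezoid integral of a density on a uniform grid
trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
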