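# Independent oracles and small fixtures shared across test files. The
# oracles deliberately use brute-force enumeration / direct formula
# evaluation, never the package's own code paths.

# Exhaustive gap scan: apply the midpoint rule by explicit loop.
oracle_gap_midpoint <- function(values, tail_exclusion = 0.1) {
  v <- sort(values)
  n <- length(v)
  lo <- max(1, ceiling(tail_exclusion * n))
  hi <- min(n - 1, floor((1 - tail_exclusion) * n))
  if (lo > hi) { lo <- 1; hi <- n - 1 }
  idx <- lo:hi
  widths <- vapply(idx, function(i) v[i + 1] - v[i], 0)
  if (max(widths) == 0) {
    idx <- 1:(n - 1)
    widths <- vapply(idx, function(i) v[i + 1] - v[i], 0)
  }
  med <- median(v)
  best_i <- NA
  best_w <- -Inf
  best_d <- Inf
  for (k in seq_along(idx)) {
    i <- idx[k]
    w <- widths[k]
    centre <- (v[i] + v[i + 1]) / 2
    d <- abs(centre - med)
    better <- w > best_w ||
      (w == best_w && (d < best_d || (d == best_d && i < best_i)))
    if (better) { best_i <- i; best_w <- w; best_d <- d }
  }
  (v[best_i] + v[best_i + 1]) / 2
}

# Full hypergeometric enumeration for the Fisher exact test on a 2x2 table
# [a b; c d]. Two-sided: sum of point probabilities <= observed (with the
# standard relative tolerance for floating-point ties); one-sided greater:
# upper tail on the [1,1] cell.
oracle_fisher <- function(tab, alternative = "two.sided") {
  a <- tab[1, 1]
  k <- sum(tab[1, ])          # row-1 margin (draws)
  m <- sum(tab[, 1])          # col-1 margin (successes)
  n <- sum(tab)
  supp <- max(0, k + m - n):min(k, m)
  d <- dhyper(supp, m, n - m, k)
  if (alternative == "two.sided") {
    sum(d[d <= d[supp == a] * (1 + 1e-7)])
  } else {
    sum(d[supp >= a])
  }
}

# Exact one-sided rank-sum p by enumerating every assignment of the pooled
# observations to the two groups (no ties assumed).
oracle_wilcox_less <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  cs <- combn(length(pooled), n1)
  stat <- colSums(matrix(r[cs], nrow = n1))
  mean(stat <= obs)
}

# 3-term chain ontology root <- A <- B (is_a, weight 0.8) used by the
# hand-propagated similarity checks.
chain_ontology <- function() {
  ontology_graph(c("root", "A", "B"),
                 data.frame(child = c("A", "B"), parent = c("root", "A"),
                            relation = "is_a", stringsAsFactors = FALSE))
}

# Tiny deterministic expression matrix: 2 strongly bimodal genes with
# disjoint low modes + 1 flat gene, 40 samples.
tiny_expr <- function() {
  set.seed(101)
  n <- 40
  low1 <- seq_len(10)           # samples 1-10 low in bimA
  low2 <- 11:20                 # samples 11-20 low in bimB
  bimA <- rnorm(n, 8, 0.3); bimA[low1] <- rnorm(10, 3, 0.3)
  bimB <- rnorm(n, 9, 0.3); bimB[low2] <- rnorm(10, 4, 0.3)
  flat <- rnorm(n, 6, 0.3)
  m <- rbind(bimA = bimA, bimB = bimB, flat = flat)
  colnames(m) <- sprintf("s%02d", seq_len(n))
  m
}

# Mutation matrix with one perfectly exclusive planted pair over 100
# samples plus an unrelated frequent gene.
tiny_mut <- function() {
  n <- 100
  m <- matrix("WT", 3, n,
              dimnames = list(c("mutA", "mutB", "noise"),
                              sprintf("s%03d", seq_len(n))))
  m["mutA", 1:20] <- "MUT"
  m["mutB", 21:40] <- "MUT"
  set.seed(7)
  m["noise", sample(n, 12)] <- "MUT"
  m
}
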