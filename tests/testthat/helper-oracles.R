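# Independent brute-force oracles.  Each one re-derives a quantity from
# first principles (enumeration, triple loops, closed forms) without
# touching the package's implementation path.

# Adjusted Rand index between two label vectors.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, probabilities from binomial coefficients.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  pr <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  obs <- pr[xs == a]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# MCC by testing every vertex subset for maximal-clique-hood.
# adj: symmetric 0/1 matrix, no self loops.
oracle_mcc <- function(adj) {
  n <- nrow(adj)
  stopifnot(n <= 15)
  mcc <- numeric(n)
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0)
    s <- length(members)
    if (s < 2) next
    sub <- adj[members, members, drop = FALSE]
    if (sum(sub) != s * (s - 1)) next            # not a clique
    outside <- setdiff(seq_len(n), members)
    maximal <- !any(vapply(outside, function(v)
      all(adj[v, members] == 1), TRUE))
    if (maximal) mcc[members] <- mcc[members] + factorial(s - 1)
  }
  mcc
}

# Unnormalized betweenness: per-source BFS shortest-path counts with
# dependency accumulation, each unordered pair counted once.
oracle_betweenness_bfs <- function(adj) {
  n <- nrow(adj)
  bt <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- numeric(n); sigma[s] <- 1
    order_ <- integer(0)
    frontier <- s
    while (length(frontier)) {
      order_ <- c(order_, frontier)
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] == 1)) {
          if (!is.finite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- union(nxt, w)
          }
          if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
        }
      }
      frontier <- nxt
    }
    delta <- numeric(n)
    for (w in rev(order_)) {
      for (v in which(adj[w, ] == 1)) {
        if (dist[v] == dist[w] - 1)
          delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bt[w] <- bt[w] + delta[w]
    }
  }
  bt / 2
}

# Classic unsigned TOM by explicit triple loop.
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- a[i, j]
    for (u in seq_len(n)) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
    tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# Pearson correlation from raw sums.
oracle_cor <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# One-sided left-tail permutation p with tie counting and +1 correction,
# by direct enumeration over all regroupings.
oracle_perm_p <- function(values, na) {
  n <- length(values)
  sel <- utils::combn(n, na)
  obs <- mean(values[seq_len(na)]) - mean(values[-seq_len(na)])
  d <- apply(sel, 2L, function(ix) mean(values[ix]) - mean(values[-ix]))
  (sum(d <= obs) + 1) / (length(d) + 1)
}

# Tanimoto by bitwise loops.
oracle_tanimoto <- function(u, v) {
  sum(u & v) / sum(u | v)
}

# Random connected-ish adjacency matrix for graph oracles.
random_adj <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  a + t(a)
}

adj_to_graph <- function(adj, genes = sprintf("g%02d", seq_len(nrow(adj)))) {
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  ppi_graph(data.frame(protein1 = genes[idx[, 1]],
                       protein2 = genes[idx[, 2]],
                       combined_score = 900),
            nodes = genes)
}
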