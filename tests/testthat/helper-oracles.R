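# Independent oracles and small fixture builders shared across the suite.
# Each oracle is a brute-force or enumeration route kept deliberately
# different from the package's implementation path.

# Floyd-Warshall all-pairs shortest paths on an undirected edge list
fw_distances <- function(ids, edges_a, edges_b) {
  n <- length(ids)
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  for (e in seq_along(edges_a)) {
    i <- match(edges_a[e], ids); j <- match(edges_b[e], ids)
    d[i, j] <- 1; d[j, i] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# naive UPGMA on similarities: cluster list, cross-pair means recomputed
# from the ORIGINAL matrix at every step
naive_upgma <- function(sim, tau) {
  groups <- as.list(rownames(sim))
  heights <- numeric(0)
  repeat {
    if (length(groups) < 2L) break
    best <- -Inf; bi <- bj <- NA
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (j <= i) next
      avg <- mean(sim[groups[[i]], groups[[j]]])
      if (avg > best + 1e-12) { best <- avg; bi <- i; bj <- j }
    }
    if (best < tau) break
    heights <- c(heights, best)
    groups[[bi]] <- c(groups[[bi]], groups[[bj]])
    groups[[bj]] <- NULL
  }
  list(groups = lapply(groups, sort), heights = heights)
}

# canonical form of a partition for set-equality comparison
partition_key <- function(groups) {
  unname(sort(vapply(groups, function(g) paste(sort(g), collapse = "|"),
                     character(1))))
}

# hypergeometric upper tail by exhaustive enumeration of all size-n draws
hyper_tail_enum <- function(k, K, n, N) {
  draws <- combn(N, n)
  successes <- colSums(draws <= K)  # items 1..K are the annotated ones
  mean(successes >= k)
}

# exact permutation Mann-Whitney p with U computed by pair counting:
# U(S) = sum over i in S, j outside S of [x_i > x_j] + 0.5 [x_i == x_j].
# Using G[i,j] = that indicator, sum(G[S, -S]) = sum(rowSums(G)[S]) - |S|/2
# - choose(|S|, 2) because within-S pairs contribute exactly 1 each and the
# diagonal 0.5 each.
perm_mwu <- function(x, y, alternative) {
  pooled <- c(x, y)
  n <- length(pooled); n_x <- length(x)
  G <- outer(pooled, pooled, ">") + 0.5 * outer(pooled, pooled, "==")
  rs <- rowSums(G)
  inner <- n_x / 2 + choose(n_x, 2)
  U <- sum(G[seq_len(n_x), -seq_len(n_x), drop = FALSE])
  mu <- n_x * length(y) / 2
  combos <- combn(n, n_x)
  u_all <- colSums(matrix(rs[combos], nrow = n_x)) - inner
  eps <- 1e-9
  switch(alternative,
         greater = mean(u_all >= U - eps),
         less = mean(u_all <= U + eps),
         two_sided = mean(abs(u_all - mu) >= abs(U - mu) - eps))
}

# brute-force Benjamini-Hochberg step-up
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running_min <- Inf
  for (i in rev(seq_len(m))) {
    running_min <- min(running_min, p[o[i]] * m / i)
    q[o[i]] <- min(running_min, 1)
  }
  q
}

# random symmetric similarity matrix in [0,1]
random_sim <- function(n, ids = sprintf("n%02d", seq_len(n))) {
  s <- matrix(0, n, n, dimnames = list(ids, ids))
  vals <- runif(n * (n - 1) / 2)
  s[upper.tri(s)] <- vals
  s <- s + t(s)
  diag(s) <- 1
  s
}

# small random network fixture with classified nodes
random_net <- function(n_nodes = 8L, p_edge = 0.4) {
  ids <- sprintf("q%02d", seq_len(n_nodes))
  records <- tibble::tibble(
    protein_id = ids,
    protein_ratio = sample(c(2, 0.5, 1), n_nodes, replace = TRUE)
  )
  records <- classify_ratios(records)
  pairs <- t(combn(ids, 2L))
  keep <- runif(nrow(pairs)) < p_edge
  links <- tibble::tibble(protein_a = pairs[keep, 1L],
                          protein_b = pairs[keep, 2L],
                          confidence = round(runif(sum(keep)), 3),
                          channel = sample(c("physical", "functional"),
                                           sum(keep), replace = TRUE))
  suppressMessages(build_network(ids, links, records))
}

# minimal classified records for explicit networks
tiny_records <- function(ids, classes) {
  ratio <- c(up = 2, down = 0.5, unchanged = 1)[classes]
  classify_ratios(tibble::tibble(protein_id = ids,
                                 protein_ratio = unname(ratio)))
}

tiny_links <- function(a, b, confidence = 0.8, channel = "functional") {
  tibble::tibble(protein_a = a, protein_b = b,
                 confidence = confidence, channel = channel)
}
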