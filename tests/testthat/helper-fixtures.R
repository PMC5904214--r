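# Fixtures are built in code; oracles here are deliberately naive
# (enumeration, brute force) and independent of the package internals.

make_expr <- function(values, scale = "log2") {
  expression_matrix(values, scale)
}

rand_expr <- function(n_genes, n_samples, seed = 1, scale = "log2") {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples, 6, 1), n_genes, n_samples,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n_samples))))
  })
  if (scale != "log2") m <- abs(m)
  expression_matrix(m, scale)
}

two_factor_annotation <- function() {
  data.frame(sample_id = c("WT_dox_1", "WT_dox_2", "WT_lps_1", "WT_lps_2",
                           "p52_dox_1", "p52_dox_2", "p52_lps_1",
                           "p52_lps_2"),
             p52 = c(0, 0, 0, 0, 1, 1, 1, 1),
             lps = c(0, 0, 1, 1, 0, 0, 1, 1))
}

# Connected Erdos-Renyi graph with named nodes.
rand_connected_graph <- function(n, p) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# Brute-force minimum Steiner cost: minimum |S| - 1 over node supersets of
# the terminals whose induced subgraph is connected.
brute_steiner_cost <- function(g, terminals) {
  nodes <- sort(igraph::V(g)$name)
  tset <- which(nodes %in% terminals)
  others <- setdiff(seq_along(nodes), tset)
  best <- Inf
  for (k in 0:length(others)) {
    combos <- if (k == 0) list(integer())
              else asplit(utils::combn(others, k), 2)
    for (extra in combos) {
      S <- c(tset, extra)
      if (length(S) - 1 >= best) next
      sg <- igraph::induced_subgraph(g, nodes[S])
      if (igraph::is_connected(sg)) best <- length(S) - 1
    }
  }
  best
}

# Enumeration oracle for the hypergeometric upper tail, plain choose().
enum_hyper_upper <- function(N, K, n, x) {
  lo <- max(0, n + K - N); hi <- min(K, n)
  xs <- lo:hi
  probs <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  sum(probs[xs >= x])
}

# Enumeration oracle for Fisher 2x2 (a,b,c,d by row).
enum_fisher <- function(a, b, c, d, sided) {
  N <- a + b + c + d; r1 <- a + b; c1 <- a + c
  lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- choose(c1, xs) * choose(N - c1, r1 - xs) / choose(N, r1)
  if (sided == "greater") sum(probs[xs >= a])
  else sum(probs[probs <= probs[xs == a] * (1 + 1e-7)])
}

# Naive BH step-up oracle.
enum_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
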