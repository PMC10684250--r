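# Independent oracles and small fixture builders shared across the suite.
# Each oracle deliberately uses a different route than the implementation it
# checks (explicit combinatorial sums, textbook step-up, pairwise loops).

# Hypergeometric upper tail by direct summation of choose() terms.
oracleHypergeomTail <- function(N, K, n, k) {
  if (k == 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg by the textbook step-up rule: sort ascending, multiply
# p_(i) by m/i, enforce monotonicity by a cumulative minimum from the top.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Topological coefficient by exhaustive pairwise loops over an igraph graph.
oracleTC <- function(g) {
  n <- igraph::vcount(g)
  nb <- lapply(seq_len(n), function(v)
    as.integer(igraph::neighbors(g, v)))
  deg <- lengths(nb)
  tc <- rep(NA_real_, n)
  for (v in seq_len(n)) {
    if (deg[v] < 2) next
    js <- c()
    for (w in seq_len(n)) {
      if (w == v) next
      shared <- length(intersect(nb[[v]], nb[[w]]))
      if (shared == 0) next
      js <- c(js, shared + as.integer(w %in% nb[[v]]))
    }
    if (length(js)) tc[v] <- mean(js) / deg[v]
  }
  tc
}

# A minimal valid EnrichmentTable with prescribed raw p-values per pathway.
# Filler counts (N, K, n, k) satisfy the class invariants; significance is
# raw p < alpha unless flags are given explicitly.
toyTable <- function(entity, p, pathwayIds = names(p), alpha = 0.05,
                     significant = NULL) {
  stopifnot(!is.null(names(p)), all(names(p) %in% pathwayIds))
  if (is.null(significant)) significant <- unname(p) < alpha
  res <- data.frame(pathway = names(p), N = 1000L, K = 50L, n = 20L,
                    k = 5L, p_raw = unname(p), p_adj = NA_real_,
                    significant = significant, stringsAsFactors = FALSE)
  res <- res[order(res$p_raw, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  new("EnrichmentTable", entityId = entity, results = res, alpha = alpha,
      adjust = "none", pathwayIds = pathwayIds)
}

# Write lines to a tempfile and return the path.
tmpWrite <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
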