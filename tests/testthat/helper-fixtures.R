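# Shared fixtures and independent oracles used across the suite.

# naive direct evaluation of the ionization factor (overflow-prone on
# purpose; the stable implementation is checked against it where it is
# representable)
naiveLogPhi <- function(acidic, basic, ph) {
  acidic <- sort(acidic)
  basic <- sort(basic, decreasing = TRUE)
  phi <- 1
  if (length(acidic))
    phi <- phi + sum(10^(seq_along(acidic) * ph - cumsum(acidic)))
  if (length(basic))
    phi <- phi + sum(10^(cumsum(basic) - seq_along(basic) * ph))
  log10(phi)
}

# matrix-power oracle for the random-walk encoding
rwOracle <- function(adj, K) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  P <- adj / ifelse(deg > 0, deg, 1)
  out <- matrix(0, n, K)
  M <- diag(n)
  for (k in seq_len(K)) {
    M <- M %*% P
    out[, k] <- diag(M)
  }
  out
}

# breadth-first-search hop distances, independent of igraph
bfsDist <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    k <- 0
    while (length(frontier)) {
      k <- k + 1
      nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 &
                     is.infinite(d[s, ]))
      d[s, nxt] <- k
      frontier <- nxt
    }
  }
  d
}

# one assay record row
makeRecord <- function(id, ph, log_s, solid = "crystalline",
                       censored = "none", spread = 0) {
  data.frame(compound_id = id, ph = ph, log_s = log_s, solid_state = solid,
             censored = censored, replicate_spread = spread)
}

# one compound row for the curation table
makeCompound <- function(id, smiles = "CCO", acidic = numeric(0),
                         basic = numeric(0), is_salt = FALSE) {
  fmt <- function(x) if (length(x)) paste(x, collapse = ";") else ""
  data.frame(compound_id = id, smiles = smiles, is_salt = is_salt,
             acidic_pkas = fmt(acidic), basic_pkas = fmt(basic))
}

# small random connected-ish graph as an adjacency matrix
randomAdj <- function(n, p = 0.4) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1  # path spine
  extra <- which(upper.tri(adj) & matrix(runif(n * n) < p, n, n))
  adj[extra] <- 1
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  diag(adj) <- 0
  adj
}

# tiny model configuration for fast training tests
tinyConfig <- function(...) {
  args <- list(...)
  defaults <- list(nLayers = 1L, hiddenDim = 8L, nHeads = 2L, rwSteps = 4L,
                   batchSize = 16L)
  do.call(modelConfig, utils::modifyList(defaults, args))
}

tinyGraphs <- function(smiles) {
  gs <- lapply(smiles, buildGraph, config = molgraphFeatures(rwSteps = 4L))
  names(gs) <- names(smiles)
  gs
}

# small task table with given S0 targets (other tasks unobserved)
s0OnlyTable <- function(ids, s0, hq = rep(TRUE, length(ids))) {
  buildTaskTable(list(S0 = data.frame(compound_id = ids, value = s0,
                                      high_quality = hq)))
}
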