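# Brute-force oracle for speech-graph attributes, independent of the
# package implementation (base-R matrices, exhaustive enumeration; no
# igraph). Used to cross-check every attribute on random multigraphs.

oracle_adjacency <- function(g) {
  nodes <- graphNodes(g)
  edges <- graphEdges(g)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    i <- match(edges[k, 1L], nodes)
    j <- match(edges[k, 2L], nodes)
    A[i, j] <- A[i, j] + 1
  }
  A
}

# All-pairs shortest directed path lengths by Floyd-Warshall on the
# simple projection (self-loops removed).
oracle_distances <- function(A) {
  n <- nrow(A)
  B <- (A > 0)
  diag(B) <- FALSE
  d <- matrix(Inf, n, n)
  d[B] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Shortest-path counts sigma[s, t] by dynamic programming over the
# distance matrix.
oracle_sigma <- function(A, d) {
  n <- nrow(A)
  B <- (A > 0)
  diag(B) <- FALSE
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(d[s, ])
    for (v in ord) {
      if (v == s || !is.finite(d[s, v])) next
      preds <- which(B[, v] & d[s, ] == d[s, v] - 1)
      sigma[s, v] <- sum(sigma[s, preds])
    }
  }
  sigma
}

oracle_betweenness_mean <- function(A) {
  n <- nrow(A)
  if (n < 3L) return(0)
  d <- oracle_distances(A)
  sigma <- oracle_sigma(A, d)
  bc <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || s == v || t == v) next
    if (is.finite(d[s, t]) && d[s, v] + d[v, t] == d[s, t] &&
        sigma[s, t] > 0)
      bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
  }
  mean(bc / ((n - 1) * (n - 2)))
}

oracle_lsc <- function(A) {
  n <- nrow(A)
  d <- oracle_distances(A)
  reach <- is.finite(d)
  comp <- rep(0L, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cid <- cid + 1L
    members <- which(reach[i, ] & reach[, i])
    comp[members] <- cid
  }
  max(tabulate(comp))
}

oracle_clustering_mean <- function(A) {
  n <- nrow(A)
  U <- ((A + t(A)) > 0)
  diag(U) <- FALSE
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(U[v, ])
    k <- length(nb)
    if (k < 2L) next
    tri <- 0L
    for (a in seq_len(k - 1L)) for (b in seq((a + 1L), k))
      if (U[nb[a], nb[b]]) tri <- tri + 1L
    cc[v] <- tri / (k * (k - 1) / 2)
  }
  mean(cc)
}

oracle_avg_neighbor_degree_mean <- function(A) {
  n <- nrow(A)
  U <- ((A + t(A)) > 0)
  diag(U) <- FALSE
  deg <- rowSums(U)
  vals <- numeric(0)
  for (v in seq_len(n)) {
    nb <- which(U[v, ])
    if (length(nb)) vals <- c(vals, mean(deg[nb]))
  }
  if (!length(vals)) 0 else mean(vals)
}

# Exhaustive enumeration of distinct directed 2- and 3-cycles (with
# edge multiplicity) over distinct node sets; independent of the trace
# formulas.
oracle_enumerate_cycles <- function(A) {
  n <- nrow(A)
  c2 <- 0
  c3 <- 0
  if (n >= 2L)
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n))
      c2 <- c2 + A[i, j] * A[j, i]
  if (n >= 3L)
    for (i in seq_len(n - 2L)) for (j in seq((i + 1L), n - 1L))
      for (k in seq((j + 1L), n))
        c3 <- c3 + A[i, j] * A[j, k] * A[k, i] +
                   A[i, k] * A[k, j] * A[j, i]
  c(L2 = c2, L3 = c3)
}

oracle_attributes <- function(g) {
  A <- oracle_adjacency(g)
  n <- nrow(A)
  e <- sum(A)
  A2 <- A %*% A
  d <- oracle_distances(A)
  fin <- d[is.finite(d) & d > 0]
  data.frame(
    N = n, E = e, PE = sum(pmax(A - 1, 0)),
    L1 = sum(diag(A)), L2 = sum(diag(A2)) / 2,
    L3 = sum(diag(A2 %*% A)) / 3,
    LSC = oracle_lsc(A),
    ATD = 2 * e / n,
    density = if (n >= 2L) e / (n * (n - 1)) else 0,
    diameter = if (length(fin)) max(fin) else 0,
    CC = oracle_clustering_mean(A),
    ASP = if (length(fin)) mean(fin) else 0,
    mean_betweenness = oracle_betweenness_mean(A),
    avg_neighbor_degree = oracle_avg_neighbor_degree_mean(A))
}

# Seeded random directed multigraphs (N <= 12, E <= 40), optionally
# self-loop-free; isolated nodes are possible.
random_speech_graph <- function(seed, allow_loops = TRUE) {
  withr::with_seed(seed, {
    n <- sample(1:12, 1L)
    nodes <- paste0("w", seq_len(n))
    emax <- sample(0:40, 1L)
    if (emax > 0L && (n >= 2L || allow_loops)) {
      src <- sample(nodes, emax, replace = TRUE)
      dst <- sample(nodes, emax, replace = TRUE)
      keep <- if (allow_loops) rep(TRUE, emax) else src != dst
      edges <- cbind(src[keep], dst[keep])
    } else {
      edges <- matrix(character(), 0L, 2L)
    }
    methods::new("SpeechGraph", reportId = paste0("rand", seed),
                 nodes = nodes, edges = edges)
  })
}

# LemmaSequence shortcut for micro-fixtures.
lemseq <- function(lemmas, id = "t", raw = length(lemmas)) {
  methods::new("LemmaSequence", reportId = id, lemmas = lemmas,
               nRawTokens = as.integer(raw))
}
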