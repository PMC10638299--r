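#' Build the directed word-adjacency multigraph of a report
#'
#' Distinct content lemmas become nodes and every pair of consecutive
#' lemmas contributes one directed edge, in narrative order. Repeated
#' adjacencies are kept as parallel edges and consecutive identical
#' lemmas as self-loops — recurrence is what the downstream attributes
#' quantify. A sequence of L lemmas yields exactly max(0, L - 1) edges.
#'
#' @param seq a [LemmaSequence-class] with at least one lemma.
#' @return a [SpeechGraph-class].
#' @export
buildGraph <- function(seq) {
  lem <- seq@lemmas
  if (!length(lem)) {
    cnd <- simpleCondition(
      paste0("report '", seq@reportId, "': empty lemma sequence, skipped"))
    class(cnd) <- c("dreamgraphs_skip_record", "error", "condition")
    stop(cnd)
  }
  n <- length(lem)
  edges <- if (n >= 2L) cbind(lem[-n], lem[-1L]) else
    matrix(character(), 0L, 2L)
  methods::new("SpeechGraph", reportId = seq@reportId,
               nodes = unique(lem), edges = edges)
}

## Multiplicity adjacency matrix A[i, j] = number of i -> j edges.
.adjacencyMatrix <- function(g) {
  n <- length(g@nodes)
  A <- matrix(0, n, n, dimnames = list(g@nodes, g@nodes))
  if (nrow(g@edges)) {
    i <- match(g@edges[, 1L], g@nodes)
    j <- match(g@edges[, 2L], g@nodes)
    for (k in seq_along(i)) A[i[k], j[k]] <- A[i[k], j[k]] + 1
  }
  A
}

## igraph views of a SpeechGraph. mode "multi" keeps parallel edges and
## self-loops; "simple" is the directed simple projection (self-loops
## dropped: they affect no path, SCC or centrality); "undirected" is the
## undirected simple projection used for clustering and neighbor degree.
.asIgraph <- function(g, mode = c("multi", "simple", "undirected")) {
  mode <- match.arg(mode)
  edges <- g@edges
  if (mode != "multi" && nrow(edges)) {
    edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
    if (mode == "undirected" && nrow(edges)) {
      flip <- edges[, 1L] > edges[, 2L]
      edges[flip, ] <- edges[flip, 2:1]
    }
    edges <- unique(edges)
  }
  ig <- igraph::make_empty_graph(n = 0, directed = (mode != "undirected"))
  ig <- igraph::add_vertices(ig, length(g@nodes), name = g@nodes)
  if (nrow(edges)) ig <- igraph::add_edges(ig, t(edges))
  ig
}

#' Loop counts from adjacency-matrix traces
#'
#' With A the multiplicity adjacency matrix, L1 = trace(A) counts
#' self-loops, L2 = trace(A^2)/2 counts loops of two nodes and
#' L3 = trace(A^3)/3 loops of three nodes. On graphs without self-loops
#' the trace formulas equal exhaustive enumeration of distinct directed
#' 2- and 3-cycles (with edge multiplicity); self-loops contaminate the
#' traces with mixed closed walks (e.g. a self-loop walked three times,
#' or a self-loop combined with a 2-cycle), and L3 can then be
#' fractional. L3 is reported as computed, following the trace
#' convention of the speech-graph literature.
#'
#' @param g a [SpeechGraph-class].
#' @return named numeric `c(L1, L2, L3)`.
#' @export
cycleCounts <- function(g) {
  A <- .adjacencyMatrix(g)
  if (!nrow(A)) return(c(L1 = 0, L2 = 0, L3 = 0))
  A2 <- A %*% A
  c(L1 = sum(diag(A)), L2 = sum(diag(A2)) / 2,
    L3 = sum(diag(A2 %*% A)) / 3)
}

#' Parallel edge count
#'
#' Repeated directed adjacencies beyond the first: PE = sum over ordered
#' node pairs of max(0, multiplicity - 1). Repeated self-loops count too.
#'
#' @param g a [SpeechGraph-class].
#' @return non-negative integer.
#' @export
parallelEdgeCount <- function(g) {
  A <- .adjacencyMatrix(g)
  as.integer(sum(pmax(A - 1, 0)))
}

#' Largest strongly connected component size
#'
#' Node count of the largest SCC of the directed simple projection; edge
#' multiplicity is irrelevant to reachability.
#'
#' @param g a [SpeechGraph-class] with at least one node.
#' @return integer in `[1, N]`.
#' @export
lscSize <- function(g) {
  ig <- .asIgraph(g, "simple")
  as.integer(max(igraph::components(ig, mode = "strong")$csize))
}

#' Diameter and average shortest path
#'
#' Directed shortest-path lengths (edge counts, multiplicity ignored)
#' over all ordered pairs u != v with a finite path; the diameter is
#' their maximum and ASP their mean. Both are 0 when no such pair
#' exists, so disconnected and single-node graphs stay finite.
#'
#' @param g a [SpeechGraph-class].
#' @return named numeric `c(diameter, ASP)`.
#' @export
pathStats <- function(g) {
  ig <- .asIgraph(g, "simple")
  d <- igraph::distances(ig, mode = "out")
  if (nrow(d) >= 2L) diag(d) <- Inf
  finite <- d[is.finite(d) & d > 0]
  if (!length(finite)) return(c(diameter = 0, ASP = 0))
  c(diameter = max(finite), ASP = mean(finite))
}

#' Mean local clustering coefficient
#'
#' On the undirected simple projection (self-loops dropped): for each
#' node with degree k >= 2, the fraction of its neighbor pairs that are
#' connected; 0 for k < 2. Returns the mean over all nodes.
#'
#' @param g a [SpeechGraph-class] with at least one node.
#' @return real in `[0, 1]`.
#' @export
meanClustering <- function(g) {
  ig <- .asIgraph(g, "undirected")
  cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  mean(cc)
}

#' Mean normalized betweenness centrality
#'
#' Standard pair-dependency betweenness on the directed simple
#' projection, normalized by (N-1)(N-2); 0 for N < 3 (no interior
#' positions exist). Returns the mean over nodes.
#'
#' @param g a [SpeechGraph-class] with at least one node.
#' @return real in `[0, 1]`.
#' @export
meanBetweenness <- function(g) {
  n <- length(g@nodes)
  if (n < 3L) return(0)
  ig <- .asIgraph(g, "simple")
  mean(igraph::betweenness(ig, directed = TRUE, normalized = TRUE))
}

#' Mean average neighbor degree
#'
#' On the undirected simple projection, the average degree of each
#' node's neighbors, averaged over nodes with at least one neighbor;
#' 0 for an edgeless graph.
#'
#' @param g a [SpeechGraph-class] with at least one node.
#' @return non-negative real.
#' @export
avgNeighborDegreeMean <- function(g) {
  ig <- .asIgraph(g, "undirected")
  if (igraph::ecount(ig) == 0L) return(0)
  knn <- suppressWarnings(igraph::knn(ig)$knn)
  mean(knn[!is.na(knn)])
}

#' Compute all structural attributes of a speech graph
#'
#' Assembles the attribute set: N (nodes), E (edges, multiplicity
#' included, so E = sequence length - 1), PE (parallel edges), L1/L2/L3
#' (loop counts), LSC (largest strongly connected component), ATD = 2E/N,
#' density = E/(N(N-1)) (0 for N < 2; can exceed 1 on highly repetitive
#' input because E keeps multiplicity), diameter, CC (mean clustering),
#' ASP (average shortest path), mean betweenness and mean average
#' neighbor degree. Conventions: paths, SCC and betweenness are directed
#' on the simple projection; clustering and neighbor degree use the
#' undirected simple projection.
#'
#' @param g a [SpeechGraph-class] with at least one node.
#' @return one-row data.frame with the 14 attribute columns.
#' @export
computeAttributes <- function(g) {
  n <- length(g@nodes)
  if (n == 0L) {
    cnd <- simpleCondition(
      paste0("report '", g@reportId, "': empty graph, skipped"))
    class(cnd) <- c("dreamgraphs_skip_record", "error", "condition")
    stop(cnd)
  }
  e <- nrow(g@edges)
  cyc <- cycleCounts(g)
  ps <- pathStats(g)
  data.frame(
    N = n, E = e, PE = parallelEdgeCount(g),
    L1 = unname(cyc["L1"]), L2 = unname(cyc["L2"]), L3 = unname(cyc["L3"]),
    LSC = lscSize(g),
    ATD = 2 * e / n,
    density = if (n >= 2L) e / (n * (n - 1)) else 0,
    diameter = unname(ps["diameter"]),
    CC = meanClustering(g),
    ASP = unname(ps["ASP"]),
    mean_betweenness = meanBetweenness(g),
    avg_neighbor_degree = avgNeighborDegreeMean(g))
}

#' Per-dream attribute table for an annotated corpus
#'
#' Builds one speech graph per report and computes all attributes.
#' Reports whose lemma sequence is empty after content filtering are
#' skipped with a warning naming the report.
#'
#' @param annotated output of [annotateCorpus()].
#' @return data.frame with id columns (report_id, dreamer_id,
#'   dreamer_group, dream_type, condition) and the 14 attribute columns.
#' @export
computeCorpusAttributes <- function(annotated) {
  rows <- lapply(annotated, function(rec) {
    att <- tryCatch({
      g <- buildGraph(rec$sequence)
      computeAttributes(g)
    }, dreamgraphs_skip_record = function(cnd) {
      warning(conditionMessage(cnd), call. = FALSE)
      NULL
    })
    if (is.null(att)) return(NULL)
    cbind(data.frame(report_id = rec$sequence@reportId,
                     dreamer_id = rec$dreamer_id,
                     dreamer_group = rec$dreamer_group,
                     dream_type = rec$dream_type,
                     condition = rec$condition,
                     stringsAsFactors = FALSE),
          att)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) stop("no non-empty reports in corpus", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
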