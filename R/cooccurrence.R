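## Sentence-wise retained-word sequences for a set of annotated reports.
## allPos = TRUE keeps every word token (the published co-occurrence
## networks include auxiliaries like haber/ser/estar); the default keeps
## the NOUN/VERB/ADJ content filter.
.sentenceWords <- function(annotated, unit = c("lemma", "surface"),
                           allPos = FALSE) {
  unit <- match.arg(unit)
  out <- list()
  for (rec in annotated) {
    toks <- rec$tokens
    if (!allPos) toks <- toks[toks$pos %in% .CONTENT_POS, , drop = FALSE]
    if (!nrow(toks)) next
    w <- if (unit == "lemma") toks$lemma else tolower(toks$surface)
    out <- c(out, split(w, toks$sentence_index))
  }
  out
}

#' Term frequencies of an annotated report subset
#'
#' Counts content words (NOUN/VERB/ADJ; or all words with
#' `allPos = TRUE`) across the given reports, by lemma or by surface
#' form. Descending counts, ties broken lexicographically.
#'
#' @param annotated output of [annotateCorpus()] (optionally subset).
#' @param unit `"lemma"` (default) or `"surface"` (keeps inflected forms
#'   distinct).
#' @param allPos include non-content words too.
#' @return data.frame(word, count), ranked.
#' @export
termFrequencies <- function(annotated, unit = c("lemma", "surface"),
                            allPos = FALSE) {
  if (!length(annotated)) stop("no reports", call. = FALSE)
  words <- unlist(.sentenceWords(annotated, unit, allPos),
                  use.names = FALSE)
  if (!length(words))
    return(data.frame(word = character(), count = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(words)
  out <- data.frame(word = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$word), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sentence-adjacency co-occurrence network
#'
#' Restricts the vocabulary to the `topK` most frequent words, then, for
#' every sentence, each adjacent pair of retained words (adjacency taken
#' within the sentence's retained-word sequence, never across sentence
#' boundaries) adds one to the undirected edge count. Self-pairs are
#' ignored. Centrality is weighted degree normalized by the total edge
#' weight.
#'
#' @param annotated output of [annotateCorpus()] (optionally subset,
#'   e.g. to one condition).
#' @param topK vocabulary size, `>= 2`.
#' @param unit `"lemma"` (default) or `"surface"`.
#' @param allPos include non-content words (the published networks kept
#'   auxiliaries); default `FALSE`.
#' @return a [CooccurrenceNetwork-class].
#' @export
cooccurrenceEdges <- function(annotated, topK, unit = c("lemma", "surface"),
                              allPos = FALSE) {
  unit <- match.arg(unit)
  if (topK < 2L) stop("topK must be >= 2", call. = FALSE)
  freq <- termFrequencies(annotated, unit, allPos)
  keepWords <- utils::head(freq$word, topK)
  counts <- new.env(parent = emptyenv())
  for (sw in .sentenceWords(annotated, unit, allPos)) {
    sw <- sw[sw %in% keepWords]
    if (length(sw) < 2L) next
    a <- sw[-length(sw)]
    b <- sw[-1L]
    ok <- a != b
    if (!any(ok)) next
    key <- ifelse(a[ok] < b[ok], paste(a[ok], b[ok], sep = "\r"),
                  paste(b[ok], a[ok], sep = "\r"))
    for (k in key)
      assign(k, (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L,
             envir = counts)
  }
  keys <- ls(counts)
  if (length(keys)) {
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    edges <- data.frame(word_a = parts[, 1L], word_b = parts[, 2L],
                        count = vapply(keys, function(k) counts[[k]],
                                       integer(1L)),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$word_a, edges$word_b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(word_a = character(), word_b = character(),
                        count = integer(), stringsAsFactors = FALSE)
  }
  nodes <- data.frame(word = keepWords,
                      frequency = freq$count[seq_along(keepWords)],
                      stringsAsFactors = FALSE)
  total <- sum(edges$count)
  cen <- stats::setNames(rep(0, nrow(nodes)), nodes$word)
  if (total > 0) {
    for (i in seq_len(nrow(edges))) {
      cen[edges$word_a[i]] <- cen[edges$word_a[i]] + edges$count[i]
      cen[edges$word_b[i]] <- cen[edges$word_b[i]] + edges$count[i]
    }
    cen <- cen / total
  }
  methods::new("CooccurrenceNetwork", nodes = nodes, edges = edges,
               centrality = cen)
}

#' Most central words of a co-occurrence network
#'
#' Ranks words by centrality (weighted degree over total edge weight by
#' construction of [cooccurrenceEdges()]); ties broken lexicographically.
#'
#' @param net a [CooccurrenceNetwork-class].
#' @param topN how many words to return.
#' @return data.frame(word, centrality), ranked.
#' @export
centralWords <- function(net, topN = 10L) {
  if (!nrow(net@nodes)) stop("empty network", call. = FALSE)
  cen <- net@centrality
  out <- data.frame(word = names(cen), centrality = unname(cen),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$centrality, out$word), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, topN)
}

#' Export a co-occurrence network
#'
#' Writes GraphML (node attributes `name` and `frequency`, edge attribute
#' `count`) or a pair of CSVs (`<path>` with edges, `<path>` nodes file
#' alongside).
#'
#' @param net a [CooccurrenceNetwork-class].
#' @param path output path.
#' @param format `"graphml"` or `"csv"` (writes `path` for edges and
#'   `nodes_<basename>` for nodes).
#' @return invisibly, `path`.
#' @export
exportCooccurrence <- function(net, path, format = c("graphml", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(net@edges, path, row.names = FALSE,
                     fileEncoding = "UTF-8")
    nodePath <- file.path(dirname(path),
                          paste0("nodes_", basename(path)))
    nodes <- net@nodes
    nodes$centrality <- unname(net@centrality[nodes$word])
    utils::write.csv(nodes, nodePath, row.names = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    ig <- igraph::make_empty_graph(n = 0, directed = FALSE)
    ig <- igraph::add_vertices(ig, nrow(net@nodes), name = net@nodes$word,
                               frequency = net@nodes$frequency)
    if (nrow(net@edges)) {
      ig <- igraph::add_edges(ig, t(as.matrix(net@edges[, 1:2])),
                              count = net@edges$count)
    }
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}
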