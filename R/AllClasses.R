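#' @import methods
NULL

## Condition codes: dream type within dreamer group. Only these five
## group x type pairs are meaningful; everything else is rejected.
.CONDITION_MAP <- c(
  "non_lucid_dreamer.non_lucid" = "NN",
  "lucid_dreamer.non_lucid"     = "NL",
  "lucid_dreamer.lucid"         = "LL",
  "obe_dreamer.non_lucid"       = "NO",
  "obe_dreamer.obe"             = "OO"
)

.DREAMER_GROUPS <- c("non_lucid_dreamer", "lucid_dreamer", "obe_dreamer")
.DREAM_TYPES    <- c("non_lucid", "lucid", "obe")
.CONDITIONS     <- c("NN", "NL", "NO", "LL", "OO")
.CONTENT_POS    <- c("NOUN", "VERB", "ADJ")

## Attribute column order used by every table writer/reader.
.ATTRIBUTE_NAMES <- c(
  "N", "E", "PE", "L1", "L2", "L3", "LSC", "ATD", "density",
  "diameter", "CC", "ASP", "mean_betweenness", "avg_neighbor_degree"
)

#' LemmaSequence: ordered content lemmas of one report
#'
#' Holds the content-word lemmas of a single dream report in narrative
#' order, after part-of-speech filtering to NOUN/VERB/ADJ, together with
#' the raw word-token count of the unfiltered text.
#'
#' @slot reportId single character, report identifier.
#' @slot lemmas character vector of content lemmas, narrative order.
#' @slot nRawTokens single integer, word tokens before filtering
#'   (punctuation and letterless tokens excluded).
#' @exportClass LemmaSequence
setClass("LemmaSequence",
  representation(reportId = "character", lemmas = "character",
                 nRawTokens = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@reportId) != 1L) msg <- c(msg, "reportId must be length 1")
    if (any(!nzchar(object@lemmas))) msg <- c(msg, "lemmas must be non-empty strings")
    if (length(object@nRawTokens) != 1L || is.na(object@nRawTokens) ||
        object@nRawTokens < 0L)
      msg <- c(msg, "nRawTokens must be a single non-negative integer")
    if (length(msg)) msg else TRUE
  })

#' SpeechGraph: directed word-adjacency multigraph of one report
#'
#' Distinct lemmas are nodes; every consecutive-lemma adjacency in the
#' narrative contributes one directed edge, so edges may repeat (parallel
#' edges) and may be self-pairs. Edge order follows the narrative.
#'
#' @slot reportId single character.
#' @slot nodes character vector of distinct lemmas.
#' @slot edges two-column character matrix (source, target), one row per
#'   edge occurrence, in narrative order; may have zero rows.
#' @exportClass SpeechGraph
setClass("SpeechGraph",
  representation(reportId = "character", nodes = "character",
                 edges = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@reportId) != 1L) msg <- c(msg, "reportId must be length 1")
    if (anyDuplicated(object@nodes)) msg <- c(msg, "nodes must be distinct")
    if (!is.character(object@edges) || ncol(object@edges) != 2L)
      msg <- c(msg, "edges must be a 2-column character matrix")
    else if (nrow(object@edges) > 0L &&
             !all(object@edges %in% object@nodes))
      msg <- c(msg, "every edge endpoint must be a node")
    if (length(msg)) msg else TRUE
  })

#' LexiconAnnotator: deterministic lexicon-based annotator
#'
#' A table-driven tokenizer/tagger/lemmatizer: each surface form maps to a
#' fixed (POS, lemma) pair; unknown words fall back to `defaultPos` with
#' the lowercased surface as lemma. Sentences split on `.`, `!`, `?`.
#' Deterministic by construction, so the downstream pipeline is testable
#' without a pretrained language model; any annotator honouring the same
#' contract (universal POS tags, lowercased lemmas) can be substituted.
#'
#' @slot table data.frame with columns surface, pos, lemma (surface unique,
#'   lowercased).
#' @slot defaultPos single character, tag for out-of-lexicon words.
#' @exportClass LexiconAnnotator
setClass("LexiconAnnotator",
  representation(table = "data.frame", defaultPos = "character"),
  validity = function(object) {
    msg <- character()
    need <- c("surface", "pos", "lemma")
    if (!all(need %in% names(object@table)))
      msg <- c(msg, "table needs columns surface, pos, lemma")
    else if (anyDuplicated(object@table$surface))
      msg <- c(msg, "duplicate surface forms in lexicon")
    if (length(object@defaultPos) != 1L)
      msg <- c(msg, "defaultPos must be length 1")
    if (length(msg)) msg else TRUE
  })

#' RunConfig: pipeline configuration
#'
#' @slot annotatorName character, annotator to use ("lexicon").
#' @slot madThreshold positive real, MAD multiples for the outlier screen.
#' @slot madConstant positive real, MAD consistency constant.
#' @slot weightRule "log_n_plus_1" or "uniform" model weights.
#' @slot cooccurTopK positive integer, vocabulary size of the
#'   co-occurrence network.
#' @slot randomSeed integer seed.
#' @slot sumOfSquaresType "II" or "III" for F tests.
#' @slot contrastAdjust p-value adjustment for pairwise contrasts:
#'   "none", "bonferroni" or "holm".
#' @exportClass RunConfig
setClass("RunConfig",
  representation(annotatorName = "character", madThreshold = "numeric",
                 madConstant = "numeric", weightRule = "character",
                 cooccurTopK = "integer", randomSeed = "integer",
                 sumOfSquaresType = "character", contrastAdjust = "character"),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@madThreshold) || object@madThreshold <= 0)
      msg <- c(msg, "madThreshold must be a positive finite number")
    if (!is.finite(object@madConstant) || object@madConstant <= 0)
      msg <- c(msg, "madConstant must be a positive finite number")
    if (!object@weightRule %in% c("log_n_plus_1", "uniform"))
      msg <- c(msg, "weightRule must be 'log_n_plus_1' or 'uniform'")
    if (is.na(object@cooccurTopK) || object@cooccurTopK < 2L)
      msg <- c(msg, "cooccurTopK must be an integer >= 2")
    if (!object@sumOfSquaresType %in% c("II", "III"))
      msg <- c(msg, "sumOfSquaresType must be 'II' or 'III'")
    if (!object@contrastAdjust %in% c("none", "bonferroni", "holm"))
      msg <- c(msg, "contrastAdjust must be 'none', 'bonferroni' or 'holm'")
    if (length(msg)) msg else TRUE
  })

#' CooccurrenceNetwork: sentence-adjacency word network
#'
#' @slot nodes data.frame(word, frequency), restricted to the top-k
#'   frequent words.
#' @slot edges data.frame(word_a, word_b, count), undirected, word_a <
#'   word_b lexicographically.
#' @slot centrality named numeric, word -> centrality score.
#' @exportClass CooccurrenceNetwork
setClass("CooccurrenceNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 centrality = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(c("word", "frequency") %in% names(object@nodes)))
      msg <- c(msg, "nodes needs columns word, frequency")
    if (!all(c("word_a", "word_b", "count") %in% names(object@edges)))
      msg <- c(msg, "edges needs columns word_a, word_b, count")
    else if (nrow(object@edges) && any(object@edges$count < 1))
      msg <- c(msg, "edge counts must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' ComparisonResult: one-way condition comparison of an attribute
#'
#' @slot attribute attribute compared.
#' @slot F,dfNum,dfDen,P omnibus F test of the condition factor.
#' @slot contrasts data.frame(pair, estimate, t, df, P) of all level pairs.
#' @slot groupMeans data.frame(condition, mean, n) of weighted group means.
#' @exportClass ComparisonResult
setClass("ComparisonResult",
  representation(attribute = "character", F = "numeric", dfNum = "integer",
                 dfDen = "integer", P = "numeric", contrasts = "data.frame",
                 groupMeans = "data.frame"))

#' AssociationResult: attribute-pair association with per-condition slopes
#'
#' @slot response,covariate attribute names of the fitted pair.
#' @slot F,dfNum,dfDen,P F test of the condition x covariate interaction.
#' @slot slopes data.frame(condition, slope, se, t, df, P).
#' @exportClass AssociationResult
setClass("AssociationResult",
  representation(response = "character", covariate = "character",
                 F = "numeric", dfNum = "integer", dfDen = "integer",
                 P = "numeric", slopes = "data.frame"))

setMethod("show", "LemmaSequence", function(object) {
  cat("LemmaSequence '", object@reportId, "': ", length(object@lemmas),
      " content lemmas of ", object@nRawTokens, " word tokens\n", sep = "")
})

setMethod("show", "SpeechGraph", function(object) {
  cat("SpeechGraph '", object@reportId, "': ", length(object@nodes),
      " nodes, ", nrow(object@edges), " directed edges (multiplicity kept)\n",
      sep = "")
})

setMethod("show", "LexiconAnnotator", function(object) {
  cat("LexiconAnnotator: ", nrow(object@table), " surface forms, unknown -> ",
      object@defaultPos, "\n", sep = "")
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig: annotator=", object@annotatorName,
      ", MAD threshold=", object@madThreshold,
      " (constant ", object@madConstant, ")",
      ", weights=", object@weightRule,
      ", SS type ", object@sumOfSquaresType,
      ", cooccur top-k=", object@cooccurTopK,
      ", seed=", object@randomSeed, "\n", sep = "")
})

setMethod("show", "CooccurrenceNetwork", function(object) {
  cat("CooccurrenceNetwork: ", nrow(object@nodes), " words, ",
      nrow(object@edges), " undirected edges, total weight ",
      sum(object@edges$count), "\n", sep = "")
})

setMethod("show", "ComparisonResult", function(object) {
  cat("Condition comparison of ", object@attribute, ": F(", object@dfNum,
      ", ", object@dfDen, ") = ", signif(object@F, 4), ", P = ",
      signif(object@P, 3), "\n", sep = "")
  if (nrow(object@contrasts)) {
    cat("Pairwise contrasts:\n")
    print(object@contrasts, row.names = FALSE)
  }
})

setMethod("show", "AssociationResult", function(object) {
  cat("Association of ", object@response, " with ", object@covariate,
      ": interaction F(", object@dfNum, ", ", object@dfDen, ") = ",
      signif(object@F, 4), ", P = ", signif(object@P, 3), "\n", sep = "")
  print(object@slopes, row.names = FALSE)
})
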