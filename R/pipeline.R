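#' Run the per-dream and per-dreamer stages of the pipeline
#'
#' Convenience wrapper: annotates every report, builds each speech graph
#' and its attributes, collapses to per-dreamer averages per condition,
#' and applies the MAD exclusion screen. The comparison/association
#' stages are separate ([compareAttribute()], [associateAttributes()])
#' because they take caller-chosen condition subsets and attribute pairs.
#'
#' @param corpus validated corpus data.frame (see [readCorpus()]).
#' @param annotator a [LexiconAnnotator-class]; default the packaged
#'   Spanish toy lexicon.
#' @param config a [RunConfig-class].
#' @return list with `perDream` (attribute table, one row per report),
#'   `dreamers` (screened per-dreamer averages), `exclusions` (MAD screen
#'   report).
#' @export
analyzeCorpus <- function(corpus, annotator = defaultLexiconAnnotator(),
                          config = runConfig()) {
  annotated <- annotateCorpus(corpus, annotator)
  perDream <- computeCorpusAttributes(annotated)
  averages <- averageAttributes(perDream)
  screened <- applyExclusion(averages, config)
  list(perDream = perDream, dreamers = screened$averages,
       exclusions = screened$exclusions)
}
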