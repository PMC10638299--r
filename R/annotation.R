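#' Build a lexicon-based annotator from a TSV table
#'
#' The TSV has one `surface<TAB>pos<TAB>lemma` triple per line; `#` starts
#' a comment. Surfaces are matched case-insensitively (stored lowercased),
#' lemmas are lowercased. Duplicate surfaces with conflicting entries are
#' an error; exact duplicate rows are collapsed.
#'
#' A ~200-entry Spanish toy lexicon covering frequent dream-report words
#' (ver, casa, cuerpo, salir, sentir, soñar, haber, ...) plus common
#' function words ships with the package; [defaultLexiconAnnotator()]
#' loads it.
#'
#' @param tablePath path to the TSV.
#' @param defaultPos POS tag assigned to out-of-lexicon words
#'   (default `"NOUN"`).
#' @return a [LexiconAnnotator-class].
#' @export
buildLexiconAnnotator <- function(tablePath, defaultPos = "NOUN") {
  lines <- readLines(tablePath, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    tab <- data.frame(surface = character(), pos = character(),
                      lemma = character(), stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 3L)
    if (length(bad))
      stop("lexicon line ", bad[1L], " does not have 3 tab-separated fields",
           call. = FALSE)
    m <- do.call(rbind, parts)
    tab <- data.frame(surface = tolower(m[, 1L]), pos = m[, 2L],
                      lemma = tolower(m[, 3L]), stringsAsFactors = FALSE)
    tab <- unique(tab)
    dup <- tab$surface[duplicated(tab$surface)]
    if (length(dup))
      stop("conflicting lexicon entries for surface form(s): ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  methods::new("LexiconAnnotator", table = tab, defaultPos = defaultPos)
}

#' @rdname buildLexiconAnnotator
#' @export
defaultLexiconAnnotator <- function(defaultPos = "NOUN") {
  buildLexiconAnnotator(system.file("extdata", "lexicon_es.tsv",
                                    package = "dreamgraphs",
                                    mustWork = TRUE),
                        defaultPos = defaultPos)
}

## Word tokens of one string: letter runs (Unicode-aware, so Spanish
## diacritics and enye survive). Tokens without letters never appear.
.wordTokens <- function(x) {
  toks <- regmatches(x, gregexpr("\\p{L}+", x, perl = TRUE))[[1L]]
  toks[nzchar(toks)]
}

#' Annotate a report text
#'
#' Splits the text into sentences (on `.`, `!`, `?`), tokenizes each
#' sentence into word tokens (letter runs; numbers and punctuation are
#' dropped and never counted as words), and assigns each token a
#' universal POS tag and a lowercased lemma by lexicon lookup, falling
#' back to the annotator's default POS with the lowercased surface as
#' lemma for unknown words. Deterministic: identical text yields an
#' identical annotation.
#'
#' @param text a single non-empty string.
#' @param annotator a [LexiconAnnotator-class] (or any object with
#'   `table`/`defaultPos` slots honouring the same contract).
#' @param reportId identifier used in error messages.
#' @return data.frame with columns surface, pos, lemma, sentence_index
#'   (0-based, non-decreasing; sentences with no word tokens are skipped).
#' @export
annotateText <- function(text, annotator, reportId = "<text>") {
  if (length(text) != 1L || !nzchar(trimws(text)))
    stop("report '", reportId, "': text must be a single non-empty string",
         call. = FALSE)
  sentences <- strsplit(text, "[.!?]+", perl = TRUE)[[1L]]
  tokens <- lapply(sentences, .wordTokens)
  tokens <- tokens[lengths(tokens) > 0L]
  if (!length(tokens))
    return(data.frame(surface = character(), pos = character(),
                      lemma = character(), sentence_index = integer(),
                      stringsAsFactors = FALSE))
  surface <- unlist(tokens, use.names = FALSE)
  sentence_index <- rep(seq_along(tokens) - 1L, lengths(tokens))
  key <- tolower(surface)
  idx <- match(key, annotator@table$surface)
  pos <- ifelse(is.na(idx), annotator@defaultPos, annotator@table$pos[idx])
  lemma <- ifelse(is.na(idx), key, annotator@table$lemma[idx])
  data.frame(surface = surface, pos = pos, lemma = lemma,
             sentence_index = sentence_index, stringsAsFactors = FALSE)
}

#' Filter annotated tokens to content lemmas
#'
#' Keeps exactly the tokens tagged NOUN, VERB or ADJ, maps them to their
#' lemmas and preserves narrative order, with no placeholder gaps.
#' Duplicated lemmas are kept: recurrence is the signal the downstream
#' graph attributes measure. The raw token count records all word tokens
#' before filtering.
#'
#' @param tokens data.frame from [annotateText()].
#' @param reportId report identifier for the result.
#' @return a [LemmaSequence-class] (possibly with zero lemmas).
#' @export
filterContentLemmas <- function(tokens, reportId) {
  keep <- tokens$pos %in% .CONTENT_POS
  methods::new("LemmaSequence", reportId = as.character(reportId),
               lemmas = tokens$lemma[keep],
               nRawTokens = nrow(tokens))
}

#' Annotate every report of a corpus
#'
#' @param corpus validated corpus data.frame (see [readCorpus()]).
#' @param annotator a [LexiconAnnotator-class]; default the packaged
#'   Spanish toy lexicon.
#' @return named list (by report_id) with one element per report:
#'   `list(sequence = LemmaSequence, tokens = token data.frame,
#'   condition, dreamer_id, dreamer_group, dream_type)`.
#' @export
annotateCorpus <- function(corpus, annotator = defaultLexiconAnnotator()) {
  out <- lapply(seq_len(nrow(corpus)), function(i) {
    rid <- corpus$report_id[i]
    toks <- tryCatch(annotateText(corpus$text[i], annotator, reportId = rid),
                     error = function(e)
                       stop("annotating report '", rid, "': ",
                            conditionMessage(e), call. = FALSE))
    list(sequence = filterContentLemmas(toks, rid), tokens = toks,
         condition = corpus$condition[i], dreamer_id = corpus$dreamer_id[i],
         dreamer_group = corpus$dreamer_group[i],
         dream_type = corpus$dream_type[i])
  })
  names(out) <- corpus$report_id
  out
}
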