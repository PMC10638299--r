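#' Derive the condition code from dreamer group and dream type
#'
#' Condition codes pair the dream type with the dreamer group: NN
#' (non-lucid dream, non-lucid dreamer), NL (non-lucid dream, lucid
#' dreamer), LL (lucid dream, lucid dreamer), NO (non-lucid dream, OBE
#' dreamer), OO (out-of-body experience, OBE dreamer). Only these five
#' pairings are meaningful: non-lucid dreamers contribute only non-lucid
#' dreams, lucid dreamers non-lucid and lucid dreams, OBE dreamers
#' non-lucid dreams and OBEs.
#'
#' @param dreamerGroup character vector in
#'   `c("non_lucid_dreamer", "lucid_dreamer", "obe_dreamer")`.
#' @param dreamType character vector in `c("non_lucid", "lucid", "obe")`.
#' @return character vector of condition codes.
#' @examples
#' deriveCondition("obe_dreamer", "non_lucid")  # "NO"
#' @export
deriveCondition <- function(dreamerGroup, dreamType) {
  key <- paste(dreamerGroup, dreamType, sep = ".")
  cond <- .CONDITION_MAP[key]
  bad <- which(is.na(cond))
  if (length(bad))
    stop("invalid dreamer_group/dream_type combination at position ",
         bad[1L], ": '", dreamerGroup[bad[1L]], "' x '", dreamType[bad[1L]],
         "'", call. = FALSE)
  unname(cond)
}

.validateCorpus <- function(df, where = "corpus") {
  need <- c("dreamer_id", "dreamer_group", "dream_type", "text")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(where, ": missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) stop(where, ": empty corpus", call. = FALSE)
  if (!"report_id" %in% names(df))
    df$report_id <- sprintf("r%04d", seq_len(nrow(df)))
  badg <- which(!df$dreamer_group %in% .DREAMER_GROUPS)
  if (length(badg))
    stop(where, ": invalid dreamer_group '", df$dreamer_group[badg[1L]],
         "' at row ", badg[1L], call. = FALSE)
  badt <- which(!df$dream_type %in% .DREAM_TYPES)
  if (length(badt))
    stop(where, ": invalid dream_type '", df$dream_type[badt[1L]],
         "' at row ", badt[1L], call. = FALSE)
  blank <- which(!nzchar(trimws(df$text)))
  if (length(blank))
    stop(where, ": empty text at row ", blank[1L], call. = FALSE)
  df$condition <- deriveCondition(df$dreamer_group, df$dream_type)
  first <- c("report_id", "dreamer_id", "dreamer_group", "dream_type",
             "condition", "text")
  df[, c(first, setdiff(names(df), first)), drop = FALSE]
}

#' Read a dream-report corpus
#'
#' Reads a corpus of dream reports from CSV or JSONL (one JSON object per
#' line), validates every record (known group/type values, the five legal
#' group x type pairings, non-empty text) and derives the condition code.
#' A missing `report_id` column is synthesized from row order, so reruns
#' on the same file are stable.
#'
#' @param path file path.
#' @param format `"csv"` or `"jsonl"`; default guessed from the extension.
#' @return data.frame with columns report_id, dreamer_id, dreamer_group,
#'   dream_type, condition, text (row order preserved; extra columns such
#'   as time/date are kept but ignored downstream).
#' @export
readCorpus <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  df <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("corpus: empty corpus", call. = FALSE)
    recs <- lapply(lines, jsonlite::fromJSON)
    keys <- unique(unlist(lapply(recs, names)))
    cols <- lapply(keys, function(k)
      vapply(recs, function(r) {
        v <- r[[k]]
        if (is.null(v)) NA_character_ else as.character(v)
      }, character(1L)))
    names(cols) <- keys
    as.data.frame(cols, stringsAsFactors = FALSE)
  }
  if ("text" %in% names(df) && anyNA(df$text))
    stop("corpus: record lacking \"text\" at row ",
         which(is.na(df$text))[1L], call. = FALSE)
  .validateCorpus(df, where = paste0("corpus (", path, ")"))
}

#' Write a dream-report corpus
#'
#' @param corpus validated corpus data.frame (see [readCorpus()]).
#' @param path output path.
#' @param format `"csv"` or `"jsonl"`.
#' @return invisibly, `path`.
#' @export
writeCorpus <- function(corpus, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(corpus, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(corpus)))
      writeLines(as.character(jsonlite::toJSON(as.list(corpus[i, ,
        drop = FALSE]), auto_unbox = TRUE)), con)
  }
  invisible(path)
}

#' Write / read a per-dream or per-dreamer attribute table
#'
#' Columns are written in a stable order: identifier columns first, then
#' the attributes N, E, PE, L1, L2, L3, LSC, ATD, density, diameter, CC,
#' ASP, mean_betweenness, avg_neighbor_degree, then anything else.
#' Values round-trip at full double precision.
#'
#' @param records data.frame of attribute rows sharing one schema.
#' @param path CSV path.
#' @return `writeAttributeTable` invisibly returns `path`;
#'   `readAttributeTable` returns the data.frame.
#' @export
writeAttributeTable <- function(records, path) {
  if (is.list(records) && !is.data.frame(records)) {
    if (!length(records)) {
      records <- as.data.frame(stats::setNames(
        rep(list(numeric()), length(.ATTRIBUTE_NAMES)), .ATTRIBUTE_NAMES))
      records <- cbind(data.frame(report_id = character()), records)
    } else {
    schemas <- unique(lapply(records, names))
    if (length(schemas) > 1L)
      stop("records have mixed schemas", call. = FALSE)
    records <- do.call(rbind, lapply(records, as.data.frame,
                                     stringsAsFactors = FALSE))
    }
  }
  ids <- intersect(c("report_id", "dreamer_id", "dreamer_group",
                     "dream_type", "condition", "n_dreams", "weight"),
                   names(records))
  attrs <- intersect(.ATTRIBUTE_NAMES, names(records))
  rest <- setdiff(names(records), c(ids, attrs))
  out <- records[, c(ids, attrs, rest), drop = FALSE]
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(x) format(x, digits = 17,
                                                  trim = TRUE,
                                                  scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = which(!num))
  invisible(path)
}

#' @rdname writeAttributeTable
#' @export
readAttributeTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Export / import a speech graph
#'
#' GraphML keeps lemma node labels (attribute `name`) and preserves edge
#' multiplicity as repeated edges; the TSV edge list has one
#' `source<TAB>target` line per edge occurrence, in narrative order.
#'
#' @param graph a [SpeechGraph-class].
#' @param path output path.
#' @param format `"graphml"` or `"edgelist_tsv"`.
#' @return `exportGraph` invisibly returns `path`; `importGraph` returns a
#'   [SpeechGraph-class] (narrative edge order is preserved by TSV; GraphML
#'   preserves the edge multiset).
#' @export
exportGraph <- function(graph, path, format = c("graphml", "edgelist_tsv")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown graph format: ",
                                              format[1L], call. = FALSE))
  if (format == "edgelist_tsv") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    e <- graph@edges
    if (nrow(e))
      writeLines(paste(e[, 1L], e[, 2L], sep = "\t"), con)
  } else {
    ig <- .asIgraph(graph, mode = "multi")
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname exportGraph
#' @param reportId identifier to attach to the imported graph.
#' @export
importGraph <- function(path, format = c("graphml", "edgelist_tsv"),
                        reportId = basename(path)) {
  format <- match.arg(format)
  if (format == "edgelist_tsv") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
      edges <- matrix(character(), 0L, 2L)
      nodes <- character()
    } else {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      edges <- do.call(rbind, parts)
      nodes <- unique(as.vector(t(edges)))
    }
  } else {
    ig <- igraph::read_graph(path, format = "graphml")
    nodes <- igraph::vertex_attr(ig, "name")
    em <- igraph::as_edgelist(ig, names = FALSE)
    edges <- matrix(nodes[em], ncol = 2L)
  }
  methods::new("SpeechGraph", reportId = reportId, nodes = nodes,
               edges = edges)
}

#' Construct a run configuration
#'
#' @param annotatorName annotator to use; only `"lexicon"` ships.
#' @param madThreshold MAD multiples beyond which a dreamer average is an
#'   outlier (default 3).
#' @param madConstant MAD consistency constant (default 1.4826, the value
#'   that makes the MAD estimate the SD under normality).
#' @param weightRule `"log_n_plus_1"` (natural log of dream count plus
#'   one) or `"uniform"` model weights.
#' @param cooccurTopK vocabulary size of co-occurrence networks.
#' @param randomSeed integer seed for stochastic steps.
#' @param sumOfSquaresType `"II"` (default) or `"III"` for F tests.
#' @param contrastAdjust p-value adjustment for pairwise contrasts
#'   (default `"none"`).
#' @return a [RunConfig-class].
#' @export
runConfig <- function(annotatorName = "lexicon", madThreshold = 3,
                      madConstant = 1.4826, weightRule = "log_n_plus_1",
                      cooccurTopK = 60L, randomSeed = 1L,
                      sumOfSquaresType = "II", contrastAdjust = "none") {
  methods::new("RunConfig", annotatorName = annotatorName,
               madThreshold = as.numeric(madThreshold),
               madConstant = as.numeric(madConstant),
               weightRule = weightRule,
               cooccurTopK = as.integer(cooccurTopK),
               randomSeed = as.integer(randomSeed),
               sumOfSquaresType = sumOfSquaresType,
               contrastAdjust = contrastAdjust)
}

.CONFIG_KEYS <- c(annotator_name = "annotatorName",
                  mad_threshold = "madThreshold",
                  mad_constant = "madConstant",
                  weight_rule = "weightRule",
                  cooccur_top_k = "cooccurTopK",
                  random_seed = "randomSeed",
                  sum_of_squares_type = "sumOfSquaresType",
                  contrast_adjust = "contrastAdjust")

#' Load a run configuration from YAML or JSON
#'
#' Unspecified keys take the defaults of [runConfig()]; unknown keys are
#' an error (no silent typo tolerance). The resulting configuration is
#' echoed as a message.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file; an empty file yields
#'   all defaults.
#' @return a [RunConfig-class].
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (file.size(path) == 0L) list() else jsonlite::fromJSON(path)
  } else {
    v <- yaml::read_yaml(path)
    if (is.null(v)) list() else v
  }
  unknown <- setdiff(names(vals), names(.CONFIG_KEYS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  numKeys <- c("mad_threshold", "mad_constant", "cooccur_top_k",
               "random_seed")
  for (k in intersect(numKeys, names(vals)))
    if (!is.numeric(vals[[k]]))
      stop("config key '", k, "' must be numeric", call. = FALSE)
  args <- stats::setNames(vals, .CONFIG_KEYS[names(vals)])
  cfg <- do.call(runConfig, args)
  message("config: ", paste0(
    "annotator=", cfg@annotatorName,
    " mad_threshold=", cfg@madThreshold,
    " mad_constant=", cfg@madConstant,
    " weight_rule=", cfg@weightRule,
    " cooccur_top_k=", cfg@cooccurTopK,
    " random_seed=", cfg@randomSeed,
    " ss_type=", cfg@sumOfSquaresType,
    " contrast_adjust=", cfg@contrastAdjust))
  cfg
}
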