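#' Per-dreamer "average graphs"
#'
#' Collapses per-dream attribute rows to one row per (dreamer, condition):
#' the arithmetic mean of every attribute, the dream count, and the model
#' weight ln(n_dreams + 1). The log weight keeps dreamers with many
#' dreams from dominating the model fits while still crediting them with
#' more information; the base of the logarithm rescales all weights
#' equally and leaves weighted least squares estimates unchanged, so the
#' natural log is used.
#'
#' @param perDream data.frame from [computeCorpusAttributes()] (or any
#'   table with dreamer_id, condition and attribute columns).
#' @return data.frame with dreamer_id, condition, n_dreams, weight and
#'   one mean per attribute column, ordered by (condition, dreamer_id).
#' @export
averageAttributes <- function(perDream) {
  if (!nrow(perDream)) stop("no attribute rows to aggregate", call. = FALSE)
  need <- c("dreamer_id", "condition")
  miss <- setdiff(need, names(perDream))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  attrs <- intersect(.ATTRIBUTE_NAMES, names(perDream))
  key <- interaction(perDream$condition, perDream$dreamer_id, drop = TRUE)
  rows <- lapply(split(perDream, key), function(d) {
    n <- nrow(d)
    out <- data.frame(dreamer_id = d$dreamer_id[1L],
                      condition = d$condition[1L],
                      n_dreams = n, weight = log(n + 1),
                      stringsAsFactors = FALSE)
    for (a in attrs) out[[a]] <- mean(d[[a]])
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$dreamer_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' MAD outlier mask
#'
#' Flags values more than `threshold` MADs from the median, where
#' MAD = `constant` * median(|x - median(x)|) (constant 1.4826 makes the
#' MAD a consistent SD estimate under normality). Degenerate cases: with
#' fewer than 3 values, or when the MAD is 0 (no spread), nothing is
#' flagged and a warning is issued — the latter avoids the pathology of
#' flagging every value that differs at all from the median.
#'
#' @param values numeric vector, all finite.
#' @param threshold positive real (default 3).
#' @param constant positive real (default 1.4826).
#' @return logical mask, TRUE = outlier.
#' @export
madOutliers <- function(values, threshold = 3, constant = 1.4826) {
  if (any(!is.finite(values)))
    stop("non-finite values in MAD screen", call. = FALSE)
  if (length(values) < 3L) {
    warning("fewer than 3 values: no MAD exclusions", call. = FALSE)
    return(rep(FALSE, length(values)))
  }
  med <- stats::median(values)
  madv <- stats::mad(values, constant = constant)
  if (madv == 0) {
    warning("MAD is zero: no exclusions", call. = FALSE)
    return(rep(FALSE, length(values)))
  }
  abs(values - med) > threshold * madv
}

#' Apply the MAD exclusion screen to dreamer averages
#'
#' Within each condition group, runs the MAD screen on the per-dreamer
#' mean node count and mean edge count; a row flagged on either is
#' removed. This filters out dreamers reporting exceptionally long or
#' short dreams within a condition. A single pass is applied (the screen
#' is not iterated on the filtered group), and a dreamer excluded in one
#' condition keeps their rows in other conditions.
#'
#' @param averages data.frame from [averageAttributes()].
#' @param config a [RunConfig-class]; `madThreshold` and `madConstant`
#'   are used.
#' @return `list(averages = filtered data.frame, exclusions = data.frame
#'   with one row per (condition, attribute) screen: condition, attribute,
#'   median, mad, n_excluded, excluded_dreamers)`.
#' @export
applyExclusion <- function(averages, config = runConfig()) {
  if (!nrow(averages)) stop("no dreamer averages", call. = FALSE)
  thr <- config@madThreshold
  cst <- config@madConstant
  reports <- list()
  drop <- rep(FALSE, nrow(averages))
  for (cond in unique(averages$condition)) {
    sel <- which(averages$condition == cond)
    for (attr in c("N", "E")) {
      x <- averages[[attr]][sel]
      mask <- withCallingHandlers(
        madOutliers(x, threshold = thr, constant = cst),
        warning = function(w) {
          message("condition ", cond, ", mean ", attr, ": ",
                  conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      madv <- if (length(x) >= 3L) stats::mad(x, constant = cst) else NA_real_
      reports[[length(reports) + 1L]] <- data.frame(
        condition = cond, attribute = attr,
        median = stats::median(x), mad = madv,
        n_excluded = sum(mask),
        excluded_dreamers = paste(averages$dreamer_id[sel][mask],
                                  collapse = ";"),
        stringsAsFactors = FALSE)
      drop[sel[mask]] <- TRUE
    }
  }
  list(averages = averages[!drop, , drop = FALSE],
       exclusions = do.call(rbind, reports))
}
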