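#' ModelFit: a fitted weighted linear model plus its design metadata
#'
#' @slot fit the underlying `lm` fit (weighted least squares).
#' @slot data the model frame used (dreamer averages subset).
#' @slot response response attribute name.
#' @slot covariate covariate attribute name, or `NA_character_`.
#' @slot factorName grouping factor column (normally `"condition"`).
#' @slot reference reference level of the factor.
#' @exportClass ModelFit
setClass("ModelFit",
  representation(fit = "ANY", data = "data.frame", response = "character",
                 covariate = "character", factorName = "character",
                 reference = "character"))

setMethod("show", "ModelFit", function(object) {
  cat("Weighted linear model: ", object@response, " ~ ",
      if (is.na(object@covariate)) object@factorName else
        paste0(object@covariate, " * ", object@factorName),
      "  (reference ", object@reference, ", ",
      nrow(object@data), " rows, residual df ",
      object@fit$df.residual, ")\n", sep = "")
})

#' Fit a weighted linear model on dreamer averages
#'
#' Fits `response ~ factor` (no covariate) or
#' `response ~ covariate * factor` (factor main effects, covariate, and
#' their interaction) by weighted least squares, minimizing the weighted
#' residual sum of squares. The factor uses treatment coding; NN is the
#' reference level when present (the control condition in both of the
#' package's standard comparisons). Weights default to the `weight`
#' column (ln(n_dreams + 1)); rescaling all weights by a constant leaves
#' the estimates unchanged.
#'
#' @param rows data.frame of dreamer averages (see [averageAttributes()]).
#' @param response attribute column to model.
#' @param covariate optional attribute column; `NULL` for a one-way model.
#' @param factorName grouping column, default `"condition"`.
#' @param weights positive weights, default `rows$weight` (all 1 if
#'   absent).
#' @param reference reference factor level; default `"NN"` if present.
#' @return a [ModelFit-class].
#' @export
fitWeightedLm <- function(rows, response, covariate = NULL,
                          factorName = "condition", weights = NULL,
                          reference = NULL) {
  if (!response %in% names(rows))
    stop("unknown response attribute: ", response, call. = FALSE)
  if (!is.null(covariate) && !covariate %in% names(rows))
    stop("unknown covariate attribute: ", covariate, call. = FALSE)
  if (is.null(weights))
    weights <- if ("weight" %in% names(rows)) rows$weight else
      rep(1, nrow(rows))
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite", call. = FALSE)
  lev <- sort(unique(as.character(rows[[factorName]])))
  if (is.null(reference))
    reference <- if ("NN" %in% lev) "NN" else lev[1L]
  small <- names(which(table(rows[[factorName]]) < 2L))
  if (length(small))
    stop("factor level(s) with fewer than 2 rows: ",
         paste(small, collapse = ", "), call. = FALSE)
  d <- data.frame(.y = rows[[response]],
                  .g = stats::relevel(factor(rows[[factorName]], levels = lev),
                                      ref = reference),
                  .w = weights)
  if (!is.null(covariate)) d$.x <- rows[[covariate]]
  ## a single-level factor carries no information: drop it from the
  ## formula (lm cannot build contrasts for one level)
  form <- if (length(lev) > 1L) {
    if (is.null(covariate)) .y ~ .g else .y ~ .x * .g
  } else {
    if (is.null(covariate)) .y ~ 1 else .y ~ .x
  }
  nPar <- if (is.null(covariate)) length(lev) else 2L * length(lev)
  if (nrow(d) < nPar + 1L)
    stop("too few rows (", nrow(d), ") for ", nPar, " parameters",
         call. = FALSE)
  fit <- stats::lm(form, data = d, weights = .w)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  methods::new("ModelFit", fit = fit, data = d, response = response,
               covariate = if (is.null(covariate)) NA_character_ else
                 covariate,
               factorName = factorName, reference = reference)
}

## Maps user-facing term names to the internal design columns.
.termName <- function(fit, term) {
  if (term == fit@factorName) return(".g")
  if (!is.na(fit@covariate) && term == fit@covariate) return(".x")
  if (term %in% c(paste0(fit@covariate, ":", fit@factorName),
                  paste0(fit@factorName, ":", fit@covariate),
                  "interaction"))
    return(".x:.g")
  stop("term '", term, "' is not in the design", call. = FALSE)
}

#' F test of a model term
#'
#' Type II sums of squares by default: each term is tested against the
#' model that omits it while respecting marginality (main effects are
#' tested without their interactions in the comparison), equivalent to an
#' F test on the drop in weighted residual sum of squares between the two
#' nested fits. Type III is available via `type`.
#'
#' @param fit a [ModelFit-class].
#' @param term `"condition"`, the covariate name, or `"interaction"`.
#' @param type `"II"` (default) or `"III"`.
#' @return named list `F`, `df_num`, `df_den`, `P`.
#' @export
anovaTermTest <- function(fit, term, type = c("II", "III")) {
  type <- match.arg(type)
  tn <- .termName(fit, term)
  tab <- car::Anova(fit@fit, type = type)
  if (!tn %in% rownames(tab))
    stop("term '", term, "' not found in ANOVA table", call. = FALSE)
  r <- tab[tn, ]
  list(F = r[["F value"]], df_num = r[["Df"]],
       df_den = tab["Residuals", "Df"], P = r[["Pr(>F)"]])
}

#' Pairwise contrasts between factor levels
#'
#' Differences of adjusted group means for every level pair, evaluated at
#' the weighted grand mean of the covariate when one is present; t
#' statistics use the model's residual variance and residual df.
#' P values are unadjusted by default (multiplicity adjustment is a
#' deliberate configuration hook).
#'
#' @param fit a [ModelFit-class].
#' @param adjust `"none"` (default), `"bonferroni"` or `"holm"`.
#' @return data.frame(pair, estimate, se, t, df, P).
#' @export
pairwiseContrasts <- function(fit, adjust = c("none", "bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  at <- NULL
  if (!is.na(fit@covariate))
    at <- list(.x = stats::weighted.mean(fit@data$.x, fit@data$.w))
  em <- emmeans::emmeans(fit@fit, specs = ".g", data = fit@data, at = at)
  pr <- summary(emmeans::contrast(em, method = "pairwise", adjust = adjust),
                infer = c(FALSE, TRUE))
  data.frame(pair = as.character(pr$contrast), estimate = pr$estimate,
             se = pr$SE, t = pr$t.ratio, df = pr$df, P = pr$p.value,
             stringsAsFactors = FALSE)
}

#' Per-condition slopes of the covariate
#'
#' In the interaction model, the slope of each condition is the covariate
#' coefficient plus that condition's interaction coefficient (the
#' reference condition's slope is the bare covariate coefficient);
#' standard errors come from the coefficient covariance and df is the
#' model's residual df.
#'
#' @param fit a [ModelFit-class] fitted with a covariate.
#' @return data.frame(condition, slope, se, t, df, P).
#' @export
groupSlopes <- function(fit) {
  if (is.na(fit@covariate))
    stop("model has no covariate/interaction; slopes undefined",
         call. = FALSE)
  tr <- emmeans::emtrends(fit@fit, specs = ".g", var = ".x",
                          data = fit@data)
  s <- summary(tr, infer = c(FALSE, TRUE))
  data.frame(condition = as.character(s$.g), slope = s$.x.trend,
             se = s$SE, t = s$t.ratio, df = s$df, P = s$p.value,
             stringsAsFactors = FALSE)
}

#' One-way condition comparison of an attribute
#'
#' Fits the weighted one-way model of an attribute on condition, tests
#' the condition effect with an F test, and computes all pairwise
#' contrasts. The standard cohorts are the typical-dream set
#' (NN, LL, OO) and the non-lucid set (NN, NL, NO), but any subset of
#' conditions with at least two levels works.
#'
#' @param cohort dreamer-average data.frame (post exclusion).
#' @param attribute attribute column to compare.
#' @param conditions optional character vector of conditions to keep.
#' @param config a [RunConfig-class] (weight rule, SS type, contrast
#'   adjustment).
#' @return a [ComparisonResult-class].
#' @export
compareAttribute <- function(cohort, attribute, conditions = NULL,
                             config = runConfig()) {
  if (!is.null(conditions))
    cohort <- cohort[cohort$condition %in% conditions, , drop = FALSE]
  if (length(unique(cohort$condition)) < 2L)
    stop("need at least 2 conditions", call. = FALSE)
  w <- if (config@weightRule == "uniform") rep(1, nrow(cohort)) else
    cohort$weight
  fit <- fitWeightedLm(cohort, attribute, weights = w)
  ft <- anovaTermTest(fit, "condition", type = config@sumOfSquaresType)
  ctr <- pairwiseContrasts(fit, adjust = config@contrastAdjust)
  gm <- do.call(rbind, lapply(split(seq_len(nrow(cohort)),
                                    cohort$condition), function(i)
    data.frame(condition = cohort$condition[i[1L]],
               mean = stats::weighted.mean(cohort[[attribute]][i], w[i]),
               n = length(i), stringsAsFactors = FALSE)))
  rownames(gm) <- NULL
  methods::new("ComparisonResult", attribute = attribute, F = ft$F,
               dfNum = as.integer(ft$df_num), dfDen = as.integer(ft$df_den),
               P = ft$P, contrasts = ctr, groupMeans = gm)
}

#' Attribute-pair association with condition interaction
#'
#' Fits the full weighted model `response ~ covariate * condition`, tests
#' the interaction (does the slope differ between conditions?), and
#' reports the per-condition slopes with t statistics. Either attribute
#' of a pair may be the response; the caller chooses the orientation.
#' With a single condition this reduces to a simple weighted regression
#' (slope reported, interaction F is NA).
#'
#' @param cohort dreamer-average data.frame (post exclusion).
#' @param response response attribute column.
#' @param covariate covariate attribute column.
#' @param conditions optional character vector of conditions to keep.
#' @param config a [RunConfig-class].
#' @return an [AssociationResult-class].
#' @export
associateAttributes <- function(cohort, response, covariate,
                                conditions = NULL, config = runConfig()) {
  if (!is.null(conditions))
    cohort <- cohort[cohort$condition %in% conditions, , drop = FALSE]
  w <- if (config@weightRule == "uniform") rep(1, nrow(cohort)) else
    cohort$weight
  if (length(unique(cohort$condition)) < 2L) {
    fit <- fitWeightedLm(cbind(cohort, .one = "all"), response,
                         covariate = covariate, factorName = ".one",
                         weights = w, reference = "all")
    ## single group: plain weighted regression, no interaction test
    sm <- summary(fit@fit)$coefficients
    slopes <- data.frame(condition = unique(cohort$condition),
                         slope = sm[".x", "Estimate"],
                         se = sm[".x", "Std. Error"],
                         t = sm[".x", "t value"],
                         df = fit@fit$df.residual,
                         P = sm[".x", "Pr(>|t|)"],
                         stringsAsFactors = FALSE)
    return(methods::new("AssociationResult", response = response,
                        covariate = covariate, F = NA_real_,
                        dfNum = NA_integer_, dfDen = NA_integer_,
                        P = NA_real_, slopes = slopes))
  }
  fit <- fitWeightedLm(cohort, response, covariate = covariate,
                       weights = w)
  ft <- anovaTermTest(fit, "interaction", type = config@sumOfSquaresType)
  methods::new("AssociationResult", response = response,
               covariate = covariate, F = ft$F,
               dfNum = as.integer(ft$df_num),
               dfDen = as.integer(ft$df_den), P = ft$P,
               slopes = groupSlopes(fit))
}
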