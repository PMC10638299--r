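# Closed-form weighted least squares oracle: solves the weighted normal
# equations directly and computes nested-model F tests from weighted
# residual sums of squares.

wls_solve <- function(X, y, w) {
  XtW <- t(X * w)
  solve(XtW %*% X, XtW %*% y)
}

wls_rss <- function(X, y, w) {
  beta <- wls_solve(X, y, w)
  r <- y - X %*% beta
  sum(w * r^2)
}

# F test for dropping the columns `drop` from design X (full vs reduced).
wls_nested_f <- function(X, y, w, drop) {
  rssFull <- wls_rss(X, y, w)
  rssRed <- wls_rss(X[, setdiff(colnames(X), drop), drop = FALSE], y, w)
  dfNum <- length(drop)
  dfDen <- nrow(X) - ncol(X)
  f <- ((rssRed - rssFull) / dfNum) / (rssFull / dfDen)
  list(F = f, df_num = dfNum, df_den = dfDen,
       P = stats::pf(f, dfNum, dfDen, lower.tail = FALSE))
}
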