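cohort_fixture <- function(nPerGroup = 10, means = c(NN = 0, LL = 0, OO = 0),
                           slopes = NULL, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    conds <- rep(names(means), each = nPerGroup)
    x <- stats::runif(length(conds), 0, 10)
    mu <- means[conds] + if (is.null(slopes)) 0 else slopes[conds] * x
    n <- sample(1:9, length(conds), replace = TRUE)
    data.frame(dreamer_id = paste0("d", seq_along(conds)),
               condition = conds, n_dreams = n, weight = log(n + 1),
               y = stats::rnorm(length(conds), mu, sd), x = x,
               stringsAsFactors = FALSE)
  })
}

test_that("weighted LM solves the weighted normal equations", {
  d <- data.frame(dreamer_id = paste0("d", 1:3), condition = "NN",
                  weight = 1, y = c(0, 1, 4), x = c(0, 1, 2))
  fit <- fitWeightedLm(cbind(d, .one = "g"), "y", covariate = "x",
                       factorName = ".one", weights = rep(1, 3),
                       reference = "g")
  # single group reduces to simple regression: (0,0),(1,1),(2,4) gives
  # slope 2 and intercept -1/3
  expect_equal(unname(coef(fit@fit)), c(-1 / 3, 2), tolerance = 1e-12)

  # weighted: estimates equal the closed-form solution on a random fixture
  co <- cohort_fixture(8, slopes = c(NN = 0.5, LL = -0.2, OO = 0.1))
  fitW <- fitWeightedLm(co, "y", covariate = "x")
  X <- stats::model.matrix(fitW@fit)
  beta <- wls_solve(X, co$y, co$weight)
  expect_equal(unname(coef(fitW@fit)), as.vector(beta), tolerance = 1e-10)

  # rescaling all weights leaves the estimates unchanged
  fitW2 <- fitWeightedLm(co, "y", covariate = "x",
                         weights = 2 * co$weight)
  expect_equal(coef(fitW2@fit), coef(fitW@fit), tolerance = 1e-12)

  # with unit weights the fit is ordinary least squares
  fitU <- fitWeightedLm(co, "y", covariate = "x",
                        weights = rep(1, nrow(co)))
  ols <- stats::lm(co$y ~ co$x * stats::relevel(factor(co$condition), "NN"))
  expect_equal(unname(coef(fitU@fit)), unname(coef(ols)), tolerance = 1e-10)
})

test_that("design errors are named", {
  co <- cohort_fixture(5)
  co$const <- 1  # constant covariate is collinear with the intercept
  expect_error(fitWeightedLm(co, "y", covariate = "const"),
               "rank-deficient")
  tiny <- co[c(1, which(co$condition == "LL")), ]
  expect_error(fitWeightedLm(tiny, "y"), "fewer than 2 rows")
  expect_error(fitWeightedLm(co, "zzz"), "unknown response")
  expect_error(fitWeightedLm(co, "y", covariate = "zzz"),
               "unknown covariate")
  bad <- co
  bad$weight[1] <- -1
  expect_error(fitWeightedLm(bad, "y"), "positive")
})

test_that("type II F equals the nested weighted-RSS F", {
  co <- cohort_fixture(6, means = c(NN = 1, LL = 3, OO = 2),
                       slopes = c(NN = 0.3, LL = 0.3, OO = -0.4), seed = 4)
  fit <- fitWeightedLm(co, "y", covariate = "x")
  X <- stats::model.matrix(fit@fit)
  intCols <- grep(":", colnames(X), value = TRUE)

  got <- anovaTermTest(fit, "interaction")
  want <- wls_nested_f(X, co$y, co$weight, intCols)
  expect_equal(got$F, want$F, tolerance = 1e-10)
  expect_equal(got$df_num, want$df_num)
  expect_equal(got$df_den, want$df_den)
  expect_equal(got$P, want$P, tolerance = 1e-10)

  # one-way model: condition term against the intercept-only fit
  fit1 <- fitWeightedLm(co, "y")
  X1 <- stats::model.matrix(fit1@fit)
  got1 <- anovaTermTest(fit1, "condition")
  want1 <- wls_nested_f(X1, co$y, co$weight,
                        grep("^\\.g", colnames(X1), value = TRUE))
  expect_equal(got1$F, want1$F, tolerance = 1e-10)

  expect_error(anovaTermTest(fit1, "nonsense"), "not in the design")
})

test_that("pairwise contrasts behave like model contrasts", {
  # two identical groups: estimate ~ 0, P ~ 1
  d <- data.frame(dreamer_id = paste0("d", 1:8),
                  condition = rep(c("NN", "OO"), each = 4),
                  weight = 1, y = rep(c(1, 2, 3, 4), 2))
  fit <- fitWeightedLm(d, "y")
  ctr <- pairwiseContrasts(fit)
  expect_equal(nrow(ctr), 1L)
  expect_equal(ctr$estimate, 0, tolerance = 1e-12)
  expect_gt(ctr$P, 0.99)

  # a 2-level contrast equals the model coefficient t test
  d2 <- cohort_fixture(7, means = c(NN = 0, OO = 2), seed = 8)
  fit2 <- fitWeightedLm(d2, "y")
  sm <- summary(fit2@fit)$coefficients
  ctr2 <- pairwiseContrasts(fit2)
  expect_equal(abs(ctr2$t), abs(sm[".gOO", "t value"]), tolerance = 1e-10)
  expect_equal(ctr2$P, sm[".gOO", "Pr(>|t|)"], tolerance = 1e-10)

  # three groups yield all three pairs
  d3 <- cohort_fixture(5, seed = 9)
  expect_equal(nrow(pairwiseContrasts(fitWeightedLm(d3, "y"))), 3L)
})

test_that("per-condition slopes come from the interaction coefficients", {
  co <- cohort_fixture(8, slopes = c(NN = 0.4, LL = 0.1, OO = -0.3),
                       seed = 12)
  fit <- fitWeightedLm(co, "y", covariate = "x")
  sl <- groupSlopes(fit)
  cf <- coef(fit@fit)
  # reference condition slope is the bare covariate coefficient
  expect_equal(sl$slope[sl$condition == "NN"], unname(cf[".x"]),
               tolerance = 1e-10)
  expect_equal(sl$slope[sl$condition == "OO"],
               unname(cf[".x"] + cf[".x:.gOO"]), tolerance = 1e-10)
  expect_equal(unique(sl$df), fit@fit$df.residual)

  expect_error(groupSlopes(fitWeightedLm(co, "y")), "no covariate")
})

test_that("simulated slopes are recovered within three standard errors", {
  hits <- 0L
  for (s in 1:20) {
    co <- cohort_fixture(15, slopes = c(NN = 0.5, OO = -0.5)[c("NN", "OO")],
                         means = c(NN = 0, OO = 0), sd = 0.5, seed = 100 + s)
    sl <- groupSlopes(fitWeightedLm(co, "y", covariate = "x"))
    ok <- abs(sl$slope[sl$condition == "NN"] - 0.5) <=
            3 * sl$se[sl$condition == "NN"] &&
          abs(sl$slope[sl$condition == "OO"] + 0.5) <=
            3 * sl$se[sl$condition == "OO"]
    hits <- hits + ok
  }
  expect_gte(hits, 19L)
})

test_that("condition comparisons detect large mean differences", {
  rejections <- 0L
  for (s in 1:10) {
    co <- cohort_fixture(10, means = c(NN = 10, OO = 20), sd = 1,
                         seed = 200 + s)
    co$density <- co$y
    cmp <- compareAttribute(co, "density")
    rejections <- rejections + (cmp@P < 0.05)
    expect_equal(cmp@dfNum, 1L)
  }
  expect_equal(rejections, 10L)

  # identical groups: F ~ 0
  d <- data.frame(dreamer_id = paste0("d", 1:8),
                  condition = rep(c("NN", "OO"), each = 4), weight = 1,
                  density = rep(c(1, 2, 3, 4), 2))
  expect_lt(compareAttribute(d, "density")@F, 1e-20)
})

test_that("associations support both orientations and single conditions", {
  co <- cohort_fixture(15, slopes = c(NN = 0.5, OO = -0.5),
                       means = c(NN = 0, OO = 0), sd = 0.5, seed = 33)
  co$ASP <- co$y
  co$E <- co$x
  a1 <- associateAttributes(co, "ASP", "E")
  expect_lt(a1@P, 0.05)
  sl <- conditionSlopes(a1)
  expect_lt(sl$slope[sl$condition == "OO"], 0)
  expect_gt(sl$slope[sl$condition == "NN"], 0)

  # orientation is the caller's choice
  a2 <- associateAttributes(co, "E", "ASP")
  expect_equal(a2@response, "E")
  expect_equal(a2@covariate, "ASP")

  # single condition reduces to a simple weighted regression
  one <- co[co$condition == "NN", ]
  a3 <- associateAttributes(one, "ASP", "E")
  expect_true(is.na(a3@F))
  wfit <- stats::lm(ASP ~ E, data = one, weights = one$weight)
  expect_equal(conditionSlopes(a3)$slope, unname(coef(wfit)["E"]),
               tolerance = 1e-10)
})

test_that("null-condition P values are approximately uniform", {
  ps <- vapply(1:300, function(s) {
    co <- cohort_fixture(8, seed = 5000 + s)
    anovaTermTest(fitWeightedLm(co, "y"), "condition")$P
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
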