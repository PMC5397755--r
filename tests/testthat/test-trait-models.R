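test_that("all-subsets enumeration has 2^T - 1 members", {
  expect_length(enumerate_models(c("body", "habitat", "diet", "activity")),
                15L)
  expect_identical(enumerate_models("body"), list("body"))
  three <- enumerate_models(c("a", "b", "c"))
  expect_length(three, 7L)
  expect_identical(sort(vapply(three, paste, character(1), collapse = "+")),
                   sort(c("a", "b", "c", "a+b", "a+c", "b+c", "a+b+c")))
})

test_that("subset OLS fits match the explicit normal-equation solution", {
  set.seed(21)
  n <- 12
  pred <- data.frame(p1 = rnorm(n), p2 = runif(n, 0, 10),
                     p3 = rexp(n))
  y <- 2 * pred$p1 - 0.5 * pred$p2 + rnorm(n, sd = 0.3)
  for (terms in enumerate_models(names(pred))) {
    fit <- fit_ols(y, pred, terms)
    # oracle: standardize, then solve X'X b = X'y by matrix algebra
    xs <- scale(as.matrix(pred[terms]))
    ys <- as.numeric(scale(y))
    X <- cbind(1, xs)
    b <- solve(t(X) %*% X, t(X) %*% ys)
    expect_equal(unname(fit$coefficients), unname(b[-1, 1]),
                 tolerance = 1e-10)
    rss <- sum((ys - X %*% b)^2)
    expect_equal(fit$r2, 1 - rss / sum((ys - mean(ys))^2))
    # Gaussian log-likelihood at sigma^2 = RSS/n
    ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
    expect_equal(fit$loglik, ll, tolerance = 1e-10)
    k <- length(terms) + 2
    expect_equal(fit$aicc,
                 -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  }
})

test_that("AICc arithmetic: penalty term, small-sample guard, and the cost
           of an irrelevant predictor", {
  set.seed(2)
  n <- 11
  pred <- data.frame(x = 1:n, junk = rnorm(n))
  y <- 1:n + c(0.3, -0.5, 0.4, 0.1, -0.3, 0.5, -0.4, 0.2, -0.1,
               0.35, -0.45)
  f1 <- fit_ols(y, pred, "x")
  expect_equal(f1$k, 3)
  expect_equal(f1$aicc - (-2 * f1$loglik + 2 * 3), 2 * 3 * 4 / (11 - 3 - 1))
  expect_gt(f1$r2, 0.98)
  # a noise predictor barely changes RSS, so its AICc penalty dominates
  f2 <- fit_ols(y, pred, c("x", "junk"))
  expect_gt(f2$aicc, f1$aicc)
  # n - k - 1 <= 0 is refused
  expect_error(fit_ols(y[1:4], pred[1:4, ], "x"), "AICc undefined")
  # collinear predictors are refused
  pred$dup <- pred$x * 2
  expect_error(fit_ols(y, pred, c("x", "dup")), "collinear|rank")
})

test_that("model ranking produces normalized Akaike weights with the
           closed-form ratio structure", {
  fake <- function(terms, aicc)
    structure(list(terms = terms, n = 11, k = length(terms) + 2,
                   loglik = NA_real_, aicc = aicc, r2 = 0.5,
                   coefficients = setNames(rep(1, length(terms)), terms),
                   se = setNames(rep(0.1, length(terms)), terms),
                   coefficients_raw = setNames(rep(1, length(terms)), terms)),
              class = "trait_fit")
  tab <- rank_models(list(fake("a", 100), fake("b", 102), fake("c", 100)))
  expect_equal(tab$delta_aicc, c(0, 0, 2))
  expect_equal(sum(tab$weight), 1)
  expect_equal(tab$weight[1], tab$weight[2])  # equal AICc, equal support
  expect_equal(tab$weight[1] / tab$weight[3], exp(1))
  # weights invariant to a constant added to every AICc
  tab2 <- rank_models(list(fake("a", 600), fake("b", 602), fake("c", 600)))
  expect_equal(tab2$weight, tab$weight)
})

test_that("the confidence set keeps models within delta_max, inclusive", {
  fake <- function(terms, aicc)
    structure(list(terms = terms, n = 11, k = 3, loglik = NA_real_,
                   aicc = aicc, r2 = 0,
                   coefficients = setNames(1, terms),
                   se = setNames(0.1, terms),
                   coefficients_raw = setNames(1, terms)),
              class = "trait_fit")
  # the published delta ladder: 0, 0.5, 0.67, 1.36 in, 2.9 out
  tab <- rank_models(list(fake("body", 162.33), fake("habitat", 162.83),
                          fake("activity", 163.00), fake("diet", 163.69),
                          fake("two", 165.23)))
  cs <- confidence_set(tab, delta_max = 2)
  expect_identical(nrow(cs), 4L)
  expect_identical(cs$terms, c("body", "habitat", "activity", "diet"))
  # exact boundary is retained
  tab2 <- rank_models(list(fake("a", 100), fake("b", 102)))
  expect_identical(nrow(confidence_set(tab2, 2)), 2L)
  # a single candidate is its own confidence set
  tab3 <- rank_models(list(fake("a", 50)))
  expect_identical(nrow(confidence_set(tab3, 2)), 1L)
})

test_that("zero-substitution averaging follows the weighted hand arithmetic", {
  fake <- function(terms, aicc, beta)
    structure(list(terms = terms, n = 11, k = length(terms) + 2,
                   loglik = NA_real_, aicc = aicc, r2 = 0,
                   coefficients = setNames(beta, terms),
                   se = setNames(rep(0.2, length(terms)), terms),
                   coefficients_raw = setNames(beta, terms)),
              class = "trait_fit")
  # delta chosen so renormalized weights are exactly (0.6, 0.4):
  # delta2 = 2 log(0.6/0.4)
  d2 <- 2 * log(0.6 / 0.4)
  tab <- rank_models(list(fake("a", 100, 1.0), fake("b", 100 + d2, 0.5)))
  avg <- model_average(tab, traits = c("a", "b"))
  expect_equal(avg$coefficient[avg$trait == "a"], 0.6 * 1.0)
  expect_equal(avg$coefficient[avg$trait == "b"], 0.4 * 0.5)
  # single-model set: averaged coefficients are that model's coefficients
  one <- confidence_set(rank_models(list(fake("a", 10, 0.7))), 2)
  avg1 <- model_average(one)
  expect_equal(avg1$coefficient, 0.7)
  expect_identical(avg1$n_models, 1L)
  # conditional averaging ignores models lacking the trait
  avgc <- model_average(tab, traits = c("a", "b"), method = "conditional")
  expect_equal(avgc$coefficient[avgc$trait == "a"], 1.0)
  # a trait in no retained model is reported as a flagged zero
  avg0 <- model_average(tab, traits = c("a", "b", "ghost"))
  g <- avg0[avg0$trait == "ghost", ]
  expect_equal(g$coefficient, 0)
  expect_identical(g$n_models, 0L)
  expect_equal(c(g$ci_low, g$ci_high), c(0, 0))
})

test_that("AICc ordering is invariant to shifting the response and
           approaches AIC for large n", {
  set.seed(31)
  n <- 20
  pred <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- pred$a + rnorm(n)
  t1 <- rank_models(lapply(enumerate_models(names(pred)), function(tr)
    fit_ols(y, pred, tr)))
  t2 <- rank_models(lapply(enumerate_models(names(pred)), function(tr)
    fit_ols(y + 1000, pred, tr)))
  expect_identical(t1$terms, t2$terms)
  expect_equal(t1$aicc, t2$aicc, tolerance = 1e-8)

  n <- 1e4
  predL <- data.frame(a = rnorm(n))
  yL <- predL$a + rnorm(n)
  fL <- fit_ols(yL, predL, "a")
  aic <- -2 * fL$loglik + 2 * fL$k
  expect_lt(fL$aicc - aic, 0.01)
})

test_that("a pure body-mass effect is recovered as the top-ranked trait", {
  set.seed(77)
  n <- 11
  traits <- data.frame(body = rlnorm(n, log(60), 0.8),
                       habitat = sample(1:5, n, replace = TRUE),
                       diet = rbinom(n, 1, 0.5),
                       activity = rbinom(n, 1, 0.5))
  shift <- 150 * as.numeric(scale(traits$body)) + rnorm(n, sd = 15)
  sel <- trait_model_selection(shift, traits)
  expect_identical(nrow(sel$table), 15L)
  expect_equal(sum(sel$table$weight), 1)
  expect_identical(sel$table$terms[1], "body")
  avg <- sel$averaged
  expect_identical(avg$importance_rank[avg$trait == "body"], 1L)
  expect_gt(avg$coefficient[avg$trait == "body"], 0)
})
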