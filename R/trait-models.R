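# All-subsets OLS of centre shifts on species traits, ranked by AICc.
# k counts intercept, slopes and the residual variance, so a one-slope
# model has k = 3 and AICc values are comparable across implementations.

#' Enumerate candidate trait models
#'
#' All non-empty subsets of the trait set; the intercept is always included
#' and no interactions are considered, so T traits give 2^T - 1 models.
#'
#' @param traits character vector of trait (predictor) names.
#' @return List of character vectors, ordered by model size then trait order.
#' @export
enumerate_models <- function(traits) {
  stopifnot(length(traits) >= 1, !anyDuplicated(traits))
  out <- list()
  for (size in seq_along(traits)) {
    sets <- utils::combn(traits, size, simplify = FALSE)
    out <- c(out, sets)
  }
  out
}

#' Fit one candidate model by ordinary least squares
#'
#' Predictors (and, by default, the response) are standardized to zero mean
#' and unit sample variance before fitting, so slopes are directly
#' comparable across traits.  AICc is computed from the Gaussian
#' log-likelihood with variance RSS/n as
#' `-2 logLik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param response numeric response vector.
#' @param predictors data frame of candidate predictors (columns are
#'   traits).
#' @param terms which predictor columns enter this model (default: all).
#' @param standardize_response scale the response to unit variance as well
#'   (default `TRUE`).
#' @return List of class `trait_fit`: `terms`, `n`, `k`, `loglik`, `aicc`,
#'   `r2`, `coefficients` (standardized slopes), `se` (their standard
#'   errors), `coefficients_raw` (original-scale slopes).
#' @export
fit_ols <- function(response, predictors, terms = names(predictors),
                    standardize_response = TRUE) {
  predictors <- as.data.frame(predictors)
  stopifnot(length(terms) >= 1, all(terms %in% names(predictors)),
            length(response) == nrow(predictors))
  n <- length(response)
  k <- length(terms) + 2L  # slopes + intercept + residual variance
  if (n - k - 1 <= 0)
    stop("AICc undefined: n - k - 1 <= 0 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  x <- predictors[terms]
  sds <- vapply(x, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("constant predictor(s): ", paste(terms[sds == 0], collapse = ", "),
         call. = FALSE)
  xs <- as.data.frame(scale(x))
  y_sd <- if (standardize_response) stats::sd(response) else 1
  if (y_sd == 0) y_sd <- 1
  ys <- (response - if (standardize_response) mean(response) else 0) / y_sd
  dat <- cbind(.y = ys, xs)
  fit <- stats::lm(.y ~ ., data = dat)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient fit (collinear predictors): ",
         paste(terms, collapse = ", "), call. = FALSE)
  ll <- stats::logLik(fit)
  stopifnot(attr(ll, "df") == k)
  aicc <- -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((ys - mean(ys))^2)
  beta <- stats::coef(fit)[-1]
  se <- sqrt(diag(stats::vcov(fit)))[-1]
  names(beta) <- names(se) <- terms
  structure(list(terms = terms, n = n, k = k, loglik = as.numeric(ll),
                 aicc = aicc, r2 = 1 - rss / tss,
                 coefficients = beta, se = se,
                 coefficients_raw = beta * y_sd / sds),
            class = "trait_fit")
}

#' Rank candidate fits by AICc
#'
#' @param fits list of [fit_ols()] results.
#' @return Data frame of class `model_table`, sorted by AICc (ties broken by
#'   fewer terms): `terms`, `n_terms`, `k`, `aicc`, `delta_aicc`, `weight`
#'   (Akaike weight over all candidates), `r2`.  The reordered fits are kept
#'   in the `"fits"` attribute for downstream averaging.
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  tab <- data.frame(
    terms = vapply(fits, function(f) paste(f$terms, collapse = "+"),
                   character(1)),
    n_terms = vapply(fits, function(f) length(f$terms), integer(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    r2 = vapply(fits, function(f) f$r2, numeric(1)))
  ord <- order(tab$aicc, tab$n_terms)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  rel <- exp(-tab$delta_aicc / 2)
  tab$weight <- rel / sum(rel)
  tab <- tab[c("terms", "n_terms", "k", "aicc", "delta_aicc", "weight", "r2")]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  class(tab) <- c("model_table", "data.frame")
  tab
}

#' Confidence set of near-best models
#'
#' Models whose AICc lies within `delta_max` of the best model's, boundary
#' inclusive.
#'
#' @param table a [rank_models()] table.
#' @param delta_max maximum `delta_aicc` retained (default 2).
#' @return The retained subset, still a `model_table` with its fits.
#' @export
confidence_set <- function(table, delta_max = 2) {
  stopifnot(inherits(table, "model_table"), delta_max > 0)
  keep <- table$delta_aicc <= delta_max
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- attr(table, "fits")[keep]
  class(out) <- c("model_table", "data.frame")
  out
}

#' Model-averaged standardized coefficients
#'
#' Full (zero-substitution) averaging over a model set: a trait absent from
#' a model contributes a zero coefficient with that model's weight.
#' Conditional averaging (over only the models containing the trait) is
#' available as an alternative.  Weights are renormalized within the set.
#' The 95% interval uses the weighted unconditional variance — each model's
#' squared standard error plus its squared deviation from the averaged
#' coefficient — with a normal quantile.  Relative importance ranks traits
#' by decreasing absolute averaged coefficient.
#'
#' @param set a `model_table` (typically from [confidence_set()]) carrying
#'   its fits.
#' @param traits traits to report (default: union of terms over the set).
#' @param method `"full"` (default) or `"conditional"`.
#' @return Data frame: `trait`, `coefficient`, `ci_low`, `ci_high`,
#'   `coefficient_raw`, `n_models` (models containing the trait),
#'   `importance_rank`.
#' @export
model_average <- function(set, traits = NULL,
                          method = c("full", "conditional")) {
  method <- match.arg(method)
  stopifnot(inherits(set, "model_table"), nrow(set) >= 1)
  fits <- attr(set, "fits")
  if (is.null(fits) || length(fits) != nrow(set))
    stop("model table has lost its fitted models", call. = FALSE)
  w <- set$weight / sum(set$weight)
  if (is.null(traits))
    traits <- unique(unlist(lapply(fits, `[[`, "terms")))
  rows <- lapply(traits, function(tr) {
    beta <- vapply(fits, function(f)
      if (tr %in% f$terms) f$coefficients[[tr]] else 0, numeric(1))
    se <- vapply(fits, function(f)
      if (tr %in% f$terms) f$se[[tr]] else 0, numeric(1))
    braw <- vapply(fits, function(f)
      if (tr %in% f$terms) f$coefficients_raw[[tr]] else 0, numeric(1))
    has <- vapply(fits, function(f) tr %in% f$terms, logical(1))
    if (!any(has))
      return(data.frame(trait = tr, coefficient = 0, ci_low = 0,
                        ci_high = 0, coefficient_raw = 0, n_models = 0L))
    if (method == "full") {
      wt <- w
    } else {
      wt <- ifelse(has, w, 0)
      wt <- wt / sum(wt)
    }
    bbar <- sum(wt * beta)
    v <- sum(wt * (se^2 + (beta - bbar)^2))
    hw <- stats::qnorm(0.975) * sqrt(v)
    data.frame(trait = tr, coefficient = bbar, ci_low = bbar - hw,
               ci_high = bbar + hw, coefficient_raw = sum(wt * braw),
               n_models = sum(has))
  })
  out <- do.call(rbind, rows)
  out$importance_rank <- rank(-abs(out$coefficient), ties.method = "first")
  rownames(out) <- NULL
  out
}

#' All-subsets trait model selection in one call
#'
#' Fits every non-empty trait subset by [fit_ols()], ranks by AICc, takes
#' the `delta_max` confidence set and averages coefficients within it.
#'
#' @param response numeric response (one value per species).
#' @param predictors data frame of traits (one row per species).
#' @param delta_max confidence-set width on the AICc scale (default 2).
#' @param method averaging method, see [model_average()].
#' @return List: `table` (all models ranked), `confidence_set`, `averaged`.
#' @export
trait_model_selection <- function(response, predictors, delta_max = 2,
                                  method = c("full", "conditional")) {
  method <- match.arg(method)
  subsets <- enumerate_models(names(predictors))
  fits <- lapply(subsets, function(tr) fit_ols(response, predictors, tr))
  tab <- rank_models(fits)
  cs <- confidence_set(tab, delta_max)
  avg <- model_average(cs, traits = names(predictors), method = method)
  list(table = tab, confidence_set = cs, averaged = avg)
}
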