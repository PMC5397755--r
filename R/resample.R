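# Effort standardization and shift inference.  Both periods are resampled
# without replacement at every site down to the site's shared quota; range
# points recomputed on each of the R paired resamples give, per species and
# range point, R paired differences (modern minus historical) whose mean is
# the shift estimate.

#' Per-site standardization quota
#'
#' The number of individuals both periods are subsampled to at one site:
#' the smaller of the two periods' totals there.  Zero is a valid quota.
#'
#' @param hist_n,mod_n individuals captured at the site in the earlier and
#'   later period (non-negative).
#' @return Integer quota.
#' @export
site_quota <- function(hist_n, mod_n) {
  stopifnot(hist_n >= 0, mod_n >= 0)
  as.integer(min(hist_n, mod_n))
}

#' Quotas for every site of a dataset
#'
#' Site pools contain only the individuals of the analysed species set, so
#' quotas refer to the species actually entering the range-shift analysis.
#'
#' @param dataset a [survey_dataset()].
#' @param species_list species whose individuals form the site pools
#'   (default: all species in the dataset).
#' @return Data frame: `site_id`, per-period totals, `quota`.
#' @export
site_quotas <- function(dataset, species_list = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (is.null(species_list))
    species_list <- sort(unique(dataset$captures$species))
  m1 <- species_site_matrix(dataset, dataset$periods[1], species_list)
  m2 <- species_site_matrix(dataset, dataset$periods[2], species_list)
  t1 <- colSums(m1)
  t2 <- colSums(m2)
  out <- data.frame(site_id = dataset$sites$site_id, t1, t2,
                    quota = as.integer(pmin(t1, t2)))
  names(out)[2:3] <- paste0("n_", dataset$periods)
  rownames(out) <- NULL
  out
}

#' Subsample one site's captures without replacement
#'
#' Treats each captured individual as one ball labelled by species and draws
#' `quota` of them uniformly without replacement, so the per-species counts
#' are multivariate hypergeometric.  Uses the current RNG state.
#'
#' @param counts non-negative integer vector of per-species counts at the
#'   site.
#' @param quota number of individuals to retain; must not exceed
#'   `sum(counts)`.
#' @return Integer vector of resampled counts (same length and names as
#'   `counts`); sums to `quota` and is bounded above by `counts`.
#' @export
resample_site <- function(counts, quota) {
  total <- sum(counts)
  if (quota > total)
    stop("quota (", quota, ") exceeds site total (", total, ")",
         call. = FALSE)
  if (quota == total) {
    out <- as.integer(counts)
    names(out) <- names(counts)
    return(out)
  }
  out <- integer(length(counts))
  names(out) <- names(counts)
  if (quota == 0) return(out)
  pool <- rep.int(seq_along(counts), counts)
  draw <- pool[sample.int(length(pool), quota)]
  tab <- tabulate(draw, nbins = length(counts))
  out[] <- tab
  out
}

#' Paired resampling replicates of range-point shifts
#'
#' For each of `R` replicates, both periods are independently subsampled at
#' every site to the site's quota, the three range points are recomputed for
#' every species, and the paired difference (later minus earlier period) is
#' recorded.  Replicates in which a species vanished from either period's
#' resample are excluded for that species and logged.  Substream seeds are
#' derived per (replicate, period, site), so increasing `R` never changes a
#' replicate with a smaller index.
#'
#' @param dataset a [survey_dataset()].
#' @param species_list species to analyse, typically from
#'   [filter_common_species()]; these also define the site resampling pools.
#' @param R number of replicates (default 100).
#' @param seed master seed.
#' @return Object of class `shift_distribution`: list with `replicates`
#'   (long data frame: `replicate`, `species`, `range_point`, `diff_m`),
#'   `n_valid`, `exclusions`, `quotas`, `species`, `R`, `seed`, `periods`.
#' @export
replicate_shifts <- function(dataset, species_list, R = 100, seed = 1L) {
  stopifnot(inherits(dataset, "survey_dataset"), R >= 1,
            length(species_list) >= 1)
  elev <- dataset$sites$elevation_m
  n_site <- length(elev)
  n_sp <- length(species_list)
  mats <- lapply(dataset$periods, species_site_matrix, dataset = dataset,
                 species = species_list)
  quotas <- site_quotas(dataset, species_list)
  pts <- c("lower", "upper", "centre")

  diffs <- array(NA_real_, dim = c(R, n_sp, 3L),
                 dimnames = list(NULL, species_list, pts))
  excl <- list()
  .with_preserved_rng({
    for (r in seq_len(R)) {
      res <- vector("list", 2L)
      for (p in 1:2) {
        m <- matrix(0L, n_sp, n_site, dimnames = dimnames(mats[[p]]))
        for (j in seq_len(n_site)) {
          set.seed(.substream_seed(seed, r, p, j))
          m[, j] <- resample_site(mats[[p]][, j], quotas$quota[j])
        }
        res[[p]] <- m
      }
      tot1 <- rowSums(res[[1]])
      tot2 <- rowSums(res[[2]])
      for (s in seq_len(n_sp)) {
        if (tot1[s] > 0 && tot2[s] > 0) {
          p1 <- range_points(res[[1]][s, ], elev)
          p2 <- range_points(res[[2]][s, ], elev)
          diffs[r, s, ] <- p2 - p1
        } else {
          gone <- dataset$periods[c(tot1[s] == 0, tot2[s] == 0)]
          excl[[length(excl) + 1L]] <-
            data.frame(replicate = r, species = species_list[s],
                       period = paste(gone, collapse = "+"))
        }
      }
    }
  })

  long <- expand.grid(range_point = pts, species = species_list,
                      replicate = seq_len(R), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, 3:1]
  long$diff_m <- as.vector(aperm(diffs, c(3, 2, 1)))
  long <- long[!is.na(long$diff_m), , drop = FALSE]
  rownames(long) <- NULL

  n_valid <- expand.grid(species = species_list, range_point = pts,
                         stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  n_valid$n_valid <- mapply(function(sp, pt)
    sum(!is.na(diffs[, sp, pt])), n_valid$species, n_valid$range_point)

  structure(list(replicates = long, n_valid = n_valid,
                 exclusions = if (length(excl)) do.call(rbind, excl) else
                   data.frame(replicate = integer(0), species = character(0),
                              period = character(0)),
                 quotas = quotas, species = species_list, R = R,
                 seed = as.integer(seed), periods = dataset$periods),
            class = "shift_distribution")
}

#' @export
print.shift_distribution <- function(x, ...) {
  cat(sprintf("Shift distribution: %d species x 3 range points x %d replicates (%d shift values, %d exclusions), seed %d\n",
              length(x$species), x$R, nrow(x$replicates),
              nrow(x$exclusions), x$seed))
  invisible(x)
}

#' One-sample Student's t test of replicate differences
#'
#' Two-sided test of the mean of the paired replicate differences against
#' zero.  With zero sample variance the test is degenerate: direction is
#' then decided by the mean alone and the p-value is undefined (`NA`).
#'
#' @param diffs numeric vector of differences (n >= 2 for a defined test).
#' @return List: `n`, `mean`, `t_stat`, `p_value`, `degenerate`.
#' @export
one_sample_t <- function(diffs) {
  n <- length(diffs)
  m <- mean(diffs)
  if (n < 2 || stats::sd(diffs) == 0)
    return(list(n = n, mean = m, t_stat = NA_real_, p_value = NA_real_,
                degenerate = TRUE))
  tt <- stats::t.test(diffs, mu = 0)
  list(n = n, mean = m, t_stat = unname(tt$statistic),
       p_value = tt$p.value, degenerate = FALSE)
}

#' Classify a shift direction
#'
#' Sign-based rule with a dead zone: `stasis` when the absolute mean shift
#' does not exceed `epsilon_m`, otherwise `upslope` or `downslope` by sign.
#' Statistical significance is a separate flag, not part of this rule.
#'
#' @param mean_shift_m mean shift in metres (later minus earlier period).
#' @param epsilon_m stasis dead zone in metres (default 0).
#' @return `"upslope"`, `"stasis"` or `"downslope"`.
#' @export
classify_direction <- function(mean_shift_m, epsilon_m = 0) {
  stopifnot(epsilon_m >= 0)
  ifelse(abs(mean_shift_m) <= epsilon_m, "stasis",
         ifelse(mean_shift_m > 0, "upslope", "downslope"))
}

#' Per-species shift tests and direction classes
#'
#' Runs [one_sample_t()] on every species-by-range-point replicate
#' distribution and attaches two direction classifications: `direction`
#' (sign of the mean with the `epsilon_m` dead zone) and `direction_strict`
#' (`stasis` unless the test is significant at `alpha` AND the mean clears
#' the dead zone).  Both are reported because a dead-zone rule and a
#' significance rule can disagree; neither is canonical.
#'
#' @param dist a [replicate_shifts()] result.
#' @param alpha significance level (default 0.05).
#' @param epsilon_m stasis dead zone in metres (default 0).
#' @return Data frame: `species`, `range_point`, `n_valid`, `mean_shift_m`,
#'   `t_stat`, `p_value`, `direction`, `significant`, `direction_strict`.
#' @export
shift_tests <- function(dist, alpha = 0.05, epsilon_m = 0) {
  stopifnot(inherits(dist, "shift_distribution"), alpha > 0, alpha < 1)
  reps <- dist$replicates
  key <- expand.grid(range_point = c("lower", "upper", "centre"),
                     species = dist$species, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)[, 2:1]
  rows <- lapply(seq_len(nrow(key)), function(i) {
    d <- reps$diff_m[reps$species == key$species[i] &
                     reps$range_point == key$range_point[i]]
    tt <- one_sample_t(d)
    sig <- !is.na(tt$p_value) && tt$p_value < alpha
    dir <- classify_direction(tt$mean, epsilon_m)
    data.frame(species = key$species[i], range_point = key$range_point[i],
               n_valid = tt$n, mean_shift_m = tt$mean, t_stat = tt$t_stat,
               p_value = tt$p_value, direction = dir, significant = sig,
               direction_strict = if (sig && dir != "stasis") dir else
                 "stasis")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wilcoxon signed-rank test of species' mean shifts
#'
#' Community-level test of whether the per-species mean shifts at one range
#' point are centred on zero.  Zeros are discarded (classical treatment,
#' default) or retained under Pratt's method.  The Z statistic uses the
#' normal approximation with a tie correction; for n <= 15 non-zero values
#' an exact two-sided p-value by full enumeration of sign assignments is
#' available (discard policy only).
#'
#' @param shifts numeric vector of per-species mean shifts (metres).
#' @param zero_policy `"discard"` or `"pratt"`.
#' @param exact use exact enumeration for the p-value when possible
#'   (default `FALSE`).
#' @param correct apply a 0.5 continuity correction to Z (default `FALSE`).
#' @return List of class `community_test`: `n_species`, `n_used`,
#'   `statistic` (W+, the positive-rank sum), `z_stat`, `p_value`,
#'   `zero_policy`, `method`.
#' @export
community_wilcoxon <- function(shifts, zero_policy = c("discard", "pratt"),
                               exact = FALSE, correct = FALSE) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(length(shifts) >= 1)
  x <- shifts[!is.na(shifts)]
  n_all <- length(x)
  if (zero_policy == "discard") {
    x <- x[x != 0]
    n <- length(x)
    if (n == 0)
      stop(structure(class = c("elevshift_no_data", "error", "condition"),
                     list(message = "all shifts are zero; nothing to rank",
                          call = NULL)))
    r <- rank(abs(x))
    w <- sum(r[x > 0])
    e_w <- n * (n + 1) / 4
    tie <- table(r)
    v_w <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
    ranks_for_exact <- r
  } else {
    n <- length(x)
    z0 <- sum(x == 0)
    r <- rank(abs(x))
    w <- sum(r[x > 0])
    e_w <- (n * (n + 1) - z0 * (z0 + 1)) / 4
    tie <- table(r[x != 0])
    v_w <- (n * (n + 1) * (2 * n + 1) - z0 * (z0 + 1) * (2 * z0 + 1)) / 24 -
      sum(tie^3 - tie) / 48
    ranks_for_exact <- NULL
  }
  cc <- if (correct) sign(w - e_w) * 0.5 else 0
  z <- if (v_w > 0) (w - e_w - cc) / sqrt(v_w) else 0
  method <- "normal approximation"
  if (exact && !is.null(ranks_for_exact) && length(ranks_for_exact) <= 15) {
    p <- .wilcoxon_exact_p(ranks_for_exact, w)
    method <- "exact enumeration"
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(list(n_species = n_all, n_used = n, statistic = w, z_stat = z,
                 p_value = p, zero_policy = zero_policy, method = method),
            class = "community_test")
}

#' @export
print.community_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: n = %d, W+ = %.1f, Z = %.2f, P = %.3g (%s, zeros: %s)\n",
              x$n_species, x$statistic, x$z_stat, x$p_value, x$method,
              x$zero_policy))
  invisible(x)
}

# Exact two-sided p by enumerating all 2^n sign assignments of the observed
# (possibly tied, hence half-integer) ranks: doubled ranks keep the
# distribution on an integer lattice.
.wilcoxon_exact_p <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  dp <- numeric(sum(r2) + 1L)
  dp[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), dp[seq_len(length(dp) - ri)])
    dp <- (dp + shifted) / 2
  }
  w2 <- round(2 * w)
  lo <- sum(dp[seq_len(w2 + 1L)])
  hi <- sum(dp[(w2 + 1L):length(dp)])
  min(1, 2 * min(lo, hi))
}

#' Direction counts and shift-magnitude summaries
#'
#' Per range point, counts the species in each direction class and, among
#' upslope and downslope movers, the mean and standard error of the absolute
#' mean shift.  Single-member groups have an undefined SE (`NA`).
#'
#' @param results data frame from [shift_tests()].
#' @param which direction column to summarize: `"direction"` (default) or
#'   `"direction_strict"`.
#' @return Data frame: `range_point`, `direction`, `n_species`,
#'   `mean_abs_shift_m`, `se_abs_shift_m`.
#' @export
direction_summary <- function(results, which = "direction") {
  stopifnot(nrow(results) >= 1, which %in% c("direction", "direction_strict"))
  dirs <- c("upslope", "stasis", "downslope")
  out <- expand.grid(direction = dirs,
                     range_point = unique(results$range_point),
                     stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)[, 2:1]
  out$n_species <- NA_integer_
  out$mean_abs_shift_m <- NA_real_
  out$se_abs_shift_m <- NA_real_
  for (i in seq_len(nrow(out))) {
    sub <- results[results$range_point == out$range_point[i] &
                   results[[which]] == out$direction[i], , drop = FALSE]
    out$n_species[i] <- nrow(sub)
    if (nrow(sub) && out$direction[i] != "stasis") {
      mag <- abs(sub$mean_shift_m)
      out$mean_abs_shift_m[i] <- mean(mag)
      if (nrow(sub) > 1)
        out$se_abs_shift_m[i] <- stats::sd(mag) / sqrt(nrow(sub))
    }
  }
  out
}
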