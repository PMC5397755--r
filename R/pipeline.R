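# End-to-end orchestration: simulate / shifts / traits, CSV outputs, and a
# plain-text run log recording the seed, per-site quotas and every
# replicate exclusion, so n_valid is auditable.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis.  Values given here are defaults a
#' config file or caller can override.
#'
#' @param sites,captures,traits input CSV paths (`traits` may be `NULL`
#'   when only the shift stage is run).
#' @param outdir directory for output tables and the run log.
#' @param periods the two period labels, earlier first.
#' @param R resampling replicates (default 100).
#' @param seed master seed (default 1).
#' @param min_captures commonness threshold per period (default 5).
#' @param alpha significance level (default 0.05).
#' @param epsilon_m stasis dead zone in metres (default 0).
#' @param delta_max AICc confidence-set width (default 2).
#' @param zero_policy Wilcoxon zero handling: `"discard"` or `"pratt"`.
#' @param averaging `"full"` or `"conditional"` model averaging.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sites, captures, traits = NULL, outdir = ".",
                            periods = c("historical", "modern"), R = 100,
                            seed = 1L, min_captures = 5, alpha = 0.05,
                            epsilon_m = 0, delta_max = 2,
                            zero_policy = "discard", averaging = "full") {
  stopifnot(R >= 1, alpha > 0, alpha < 1, delta_max > 0, epsilon_m >= 0,
            min_captures >= 1)
  structure(list(sites = sites, captures = captures, traits = traits,
                 outdir = outdir, periods = periods, R = as.integer(R),
                 seed = as.integer(seed), min_captures = min_captures,
                 alpha = alpha, epsilon_m = epsilon_m, delta_max = delta_max,
                 zero_policy = zero_policy, averaging = averaging),
            class = "pipeline_config")
}

.log_lines <- function(path, lines) {
  con <- file(path, open = "a", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
}

#' Run the range-shift stage of the pipeline
#'
#' Reads the survey, applies the commonness filter, runs the paired
#' resampling engine, tests per-species shifts, runs the community-level
#' Wilcoxon tests per range point and writes `shifts.csv`,
#' `community_tests.csv`, `replicate_shifts.csv` and `run.log` to the
#' configured output directory.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the shift distribution, the test table,
#'   community tests and direction summaries.
#' @export
run_shifts <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "run.log")
  if (file.exists(log_path)) unlink(log_path)
  dataset <- read_survey(config$sites, config$captures, config$periods)
  common <- filter_common_species(dataset, config$min_captures)
  if (!length(common))
    stop(structure(class = c("elevshift_empty_result", "error", "condition"),
                   list(message = sprintf(
                     "no species has >= %d captures in both periods",
                     config$min_captures), call = NULL)))
  dist <- replicate_shifts(dataset, common, R = config$R, seed = config$seed)
  results <- shift_tests(dist, alpha = config$alpha,
                         epsilon_m = config$epsilon_m)
  comm <- lapply(c("lower", "upper", "centre"), function(pt) {
    sub <- results[results$range_point == pt, ]
    ct <- community_wilcoxon(sub$mean_shift_m,
                             zero_policy = config$zero_policy)
    data.frame(range_point = pt, n_species = ct$n_species,
               z_stat = ct$z_stat, p_value = ct$p_value,
               zero_policy = ct$zero_policy)
  })
  comm <- do.call(rbind, comm)
  summaries <- direction_summary(results)

  utils::write.csv(results, file.path(config$outdir, "shifts.csv"),
                   row.names = FALSE)
  utils::write.csv(comm, file.path(config$outdir, "community_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(dist$replicates,
                   file.path(config$outdir, "replicate_shifts.csv"),
                   row.names = FALSE)
  .log_lines(log_path, c(
    sprintf("seed: %d", config$seed),
    sprintf("replicates: %d", config$R),
    sprintf("species analysed (%d): %s", length(common),
            paste(common, collapse = ", ")),
    "site quotas:",
    sprintf("  site %s: %s = %d, %s = %d, quota = %d",
            dist$quotas$site_id,
            config$periods[1], dist$quotas[[2]],
            config$periods[2], dist$quotas[[3]],
            dist$quotas$quota),
    sprintf("replicate exclusions: %d", nrow(dist$exclusions)),
    if (nrow(dist$exclusions))
      sprintf("  replicate %d: %s absent from %s",
              dist$exclusions$replicate, dist$exclusions$species,
              dist$exclusions$period) else character(0)))
  invisible(list(dataset = dataset, species = common, distribution = dist,
                 shifts = results, community = comm, summary = summaries))
}

#' Run the trait-regression stage of the pipeline
#'
#' The response is each species' mean centre shift (downslope shifts
#' negative).  Fits all non-empty trait subsets, ranks them by AICc and
#' writes `models.csv` and `averaged.csv`.
#'
#' @param config a [pipeline_config()] with a `traits` path.
#' @param shifts data frame from [shift_tests()], or `NULL` to read
#'   `shifts.csv` from the output directory.
#' @return Invisibly, the [trait_model_selection()] result.
#' @export
run_traits <- function(config, shifts = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$traits))
    stop("pipeline_config has no traits path", call. = FALSE)
  tr <- read_traits(config$traits)
  if (is.null(shifts))
    shifts <- utils::read.csv(file.path(config$outdir, "shifts.csv"))
  centre <- shifts[shifts$range_point == "centre", , drop = FALSE]
  m <- match(centre$species, tr$species)
  if (anyNA(m))
    stop("traits table missing species: ",
         paste(centre$species[is.na(m)], collapse = ", "), call. = FALSE)
  predictors <- data.frame(body = tr$body_mass_g[m],
                           habitat = tr$habitat_breadth[m],
                           diet = tr$diet_omnivore[m],
                           activity = tr$activity_facultative[m])
  n <- nrow(centre)
  k_max <- ncol(predictors) + 2L
  if (n - k_max - 1 <= 0)
    stop(sprintf(
      "too few species (%d) to fit the full %d-trait model (need > %d)",
      n, ncol(predictors), k_max + 1), call. = FALSE)
  sel <- trait_model_selection(centre$mean_shift_m, predictors,
                               delta_max = config$delta_max,
                               method = config$averaging)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(sel$table),
                   file.path(config$outdir, "models.csv"), row.names = FALSE)
  utils::write.csv(sel$averaged, file.path(config$outdir, "averaged.csv"),
                   row.names = FALSE)
  invisible(sel)
}

#' Read a simulation configuration from a YAML file
#'
#' Expected keys: `seed`, `count_model`, `sites` (list of records following
#' the sites schema) and `species` (list of [species_profile()] records).
#' Missing `sites` fall back to the packaged eight reference sites.
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$species)) stop("config has no 'species' list", call. = FALSE)
  profiles <- do.call(rbind, lapply(y$species, as.data.frame))
  sites <- if (is.null(y$sites)) wolong_sites() else
    do.call(rbind, lapply(y$sites, as.data.frame))
  simulation_config(sites, profiles,
                    seed = if (is.null(y$seed)) 1L else y$seed,
                    count_model = if (is.null(y$count_model)) "poisson" else
                      y$count_model)
}

#' Simulate a survey and write it to disk
#'
#' Wraps [generate_survey()]; writes `sites.csv`, `captures.csv` and a
#' `simulation_meta.yaml` sidecar recording the seed, count model and
#' species profiles so every simulated dataset is reproducible.
#'
#' @param config a [simulation_config()] or path to a YAML config file.
#' @param outdir output directory.
#' @return Invisibly, the generated [survey_dataset()].
#' @export
simulate_survey <- function(config, outdir) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "sim_config"))
  ds <- generate_survey(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_survey(ds, file.path(outdir, "sites.csv"),
               file.path(outdir, "captures.csv"))
  meta <- list(seed = config$seed, count_model = config$count_model,
               periods = as.list(config$periods),
               species = lapply(seq_len(nrow(config$profiles)), function(i)
                 as.list(config$profiles[i, ])))
  yaml::write_yaml(meta, file.path(outdir, "simulation_meta.yaml"))
  invisible(ds)
}
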