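# Input table schemas (comma-separated UTF-8 with a header row):
#   sites:    site_id, elevation_m, vegetation, trap_nights_hist, trap_nights_mod
#   captures: period, site_id, species, count
#   traits:   species, body_mass_g, habitat_breadth, diet_omnivore, activity_facultative

.required_cols <- list(
  sites    = c("site_id", "elevation_m", "vegetation",
               "trap_nights_hist", "trap_nights_mod"),
  captures = c("period", "site_id", "species", "count"),
  traits   = c("species", "body_mass_g", "habitat_breadth",
               "diet_omnivore", "activity_facultative")
)

.check_cols <- function(df, what, path = NULL) {
  missing <- setdiff(.required_cols[[what]], names(df))
  if (length(missing)) {
    stop(sprintf("%s table%s is missing required column(s): %s",
                 what, if (is.null(path)) "" else paste0(" '", path, "'"),
                 paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  invisible(df)
}

.parse_numeric <- function(x, column, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad)) {
    stop(sprintf("non-numeric value '%s' in column '%s' of %s table (row %d)",
                 x[bad[1]], column, what, bad[1]), call. = FALSE)
  }
  if (anyNA(out)) {
    stop(sprintf("missing value in column '%s' of %s table (row %d)",
                 column, what, which(is.na(out))[1]), call. = FALSE)
  }
  out
}

#' Assemble a validated two-period survey dataset
#'
#' Bundles a site table and a capture table into a `survey_dataset`, the
#' substrate of all range-shift computations, after checking referential
#' integrity and the invariants each table must satisfy.
#'
#' @param sites data frame with columns `site_id`, `elevation_m`,
#'   `vegetation`, `trap_nights_hist`, `trap_nights_mod`.  Trap-night columns
#'   map, in order, to the two labels in `periods`.
#' @param captures data frame with columns `period`, `site_id`, `species`,
#'   `count`.  May have zero rows.
#' @param periods character of length 2: the earlier and later period label,
#'   in that order.  Declared, never inferred from the data.
#' @return An object of class `survey_dataset`: a list with elements
#'   `sites` (ordered by elevation), `captures` and `periods`.
#' @examples
#' sites <- data.frame(site_id = c("a", "b"), elevation_m = c(1000, 2000),
#'                     vegetation = "forest", trap_nights_hist = 100,
#'                     trap_nights_mod = 120)
#' caps <- data.frame(period = "historical", site_id = "a",
#'                    species = "sp1", count = 4)
#' survey_dataset(sites, caps)
#' @export
survey_dataset <- function(sites, captures,
                           periods = c("historical", "modern")) {
  if (length(periods) != 2L || anyDuplicated(periods))
    stop("'periods' must be two distinct labels", call. = FALSE)
  sites <- .check_cols(as.data.frame(sites), "sites")
  captures <- .check_cols(as.data.frame(captures), "captures")

  sites$site_id <- as.character(sites$site_id)
  sites$elevation_m <- .parse_numeric(sites$elevation_m, "elevation_m", "sites")
  for (col in c("trap_nights_hist", "trap_nights_mod"))
    sites[[col]] <- .parse_numeric(sites[[col]], col, "sites")

  if (nrow(sites) < 2L)
    stop("a survey needs at least 2 sites", call. = FALSE)
  if (anyDuplicated(sites$site_id))
    stop("duplicate site_id in sites table: ",
         sites$site_id[duplicated(sites$site_id)][1], call. = FALSE)
  if (any(sites$elevation_m <= 0))
    stop("site elevations must be positive", call. = FALSE)
  if (any(sites$trap_nights_hist <= 0) || any(sites$trap_nights_mod <= 0))
    stop("trap-nights must be positive in both periods", call. = FALSE)
  sites <- sites[order(sites$elevation_m), , drop = FALSE]
  if (any(diff(sites$elevation_m) <= 0))
    stop("site elevations must be distinct", call. = FALSE)
  rownames(sites) <- NULL

  captures$period <- as.character(captures$period)
  captures$site_id <- as.character(captures$site_id)
  captures$species <- as.character(captures$species)
  if (nrow(captures)) {
    captures$count <- .parse_numeric(captures$count, "count", "captures")
    if (any(captures$count < 0) || any(captures$count != round(captures$count)))
      stop("capture counts must be non-negative integers", call. = FALSE)
    unknown <- setdiff(captures$period, periods)
    if (length(unknown))
      stop("capture table uses period label(s) not declared in 'periods': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    orphan <- setdiff(captures$site_id, sites$site_id)
    if (length(orphan))
      stop("capture table references unknown site_id(s): ",
           paste(orphan, collapse = ", "), call. = FALSE)
    key <- paste(captures$period, captures$site_id, captures$species, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (period, site_id, species) row in captures: ",
           gsub("\r", "/", key[duplicated(key)][1]), call. = FALSE)
  } else {
    captures$count <- numeric(0)
  }
  rownames(captures) <- NULL

  structure(list(sites = sites, captures = captures, periods = periods),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("Two-period survey: %d sites (%.0f-%.0f m), %d species, periods '%s' vs '%s'\n",
              nrow(x$sites), min(x$sites$elevation_m), max(x$sites$elevation_m),
              length(unique(x$captures$species)), x$periods[1], x$periods[2]))
  for (p in x$periods) {
    cat(sprintf("  %-12s %5d individuals\n", p,
                sum(x$captures$count[x$captures$period == p])))
  }
  invisible(x)
}

#' Read a survey from delimited text files
#'
#' @param sites_path,captures_path paths to CSV files following the sites and
#'   captures schemas (see [survey_dataset()]).
#' @inheritParams survey_dataset
#' @return A validated [survey_dataset()].
#' @export
read_survey <- function(sites_path, captures_path,
                        periods = c("historical", "modern")) {
  for (p in c(sites_path, captures_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  sites <- utils::read.csv(sites_path, colClasses = "character",
                           check.names = TRUE)
  .check_cols(sites, "sites", sites_path)
  captures <- utils::read.csv(captures_path, colClasses = "character")
  .check_cols(captures, "captures", captures_path)
  survey_dataset(sites, captures, periods)
}

#' Write a survey to delimited text files
#'
#' Inverse of [read_survey()]: writes the two tables so that reading them back
#' reproduces counts and elevations exactly.
#'
#' @param dataset a [survey_dataset()].
#' @param sites_path,captures_path output CSV paths.
#' @return Invisibly, the dataset.
#' @export
write_survey <- function(dataset, sites_path, captures_path) {
  stopifnot(inherits(dataset, "survey_dataset"))
  utils::write.csv(dataset$sites, sites_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$captures, captures_path, row.names = FALSE,
                   quote = FALSE)
  invisible(dataset)
}

#' Read a species trait table
#'
#' @param path CSV file with columns `species`, `body_mass_g`,
#'   `habitat_breadth`, `diet_omnivore`, `activity_facultative`.  Diet is
#'   coded 0 for herbivores or carnivores and 1 for omnivores; activity is 0
#'   for obligately diurnal or nocturnal species and 1 for facultatively
#'   diurnal ones.
#' @return Validated data frame of traits, one row per species.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tr <- utils::read.csv(path, colClasses = "character")
  .check_cols(tr, "traits", path)
  tr$species <- as.character(tr$species)
  tr$body_mass_g <- .parse_numeric(tr$body_mass_g, "body_mass_g", "traits")
  tr$habitat_breadth <- .parse_numeric(tr$habitat_breadth, "habitat_breadth",
                                       "traits")
  tr$diet_omnivore <- .parse_numeric(tr$diet_omnivore, "diet_omnivore",
                                     "traits")
  tr$activity_facultative <- .parse_numeric(tr$activity_facultative,
                                            "activity_facultative", "traits")
  if (anyDuplicated(tr$species))
    stop("duplicate species in traits table", call. = FALSE)
  if (any(tr$body_mass_g <= 0))
    stop("body_mass_g must be positive", call. = FALSE)
  if (any(tr$habitat_breadth < 1))
    stop("habitat_breadth must be >= 1", call. = FALSE)
  if (!all(tr$diet_omnivore %in% 0:1) || !all(tr$activity_facultative %in% 0:1))
    stop("diet_omnivore and activity_facultative must be 0 or 1", call. = FALSE)
  tr
}

#' Trap-night effort accounting
#'
#' Summarizes sampling effort per site and per period, and the per-site
#' absolute differences in effort between the two periods.  The standard
#' error of the mean difference uses the sample standard deviation (n - 1)
#' divided by the square root of the number of sites.
#'
#' @param x a [survey_dataset()] or a sites data frame.
#' @return A list of class `effort_summary`: `per_site` (site, elevation,
#'   trap-nights per period, absolute difference), `total` (named by period),
#'   `mean_abs_diff_tn`, `se_abs_diff_tn`, `max_abs_diff_tn`, and, when
#'   captures are available, `individuals` (total per period).
#' @export
effort_summary <- function(x) {
  if (inherits(x, "survey_dataset")) {
    sites <- x$sites
    periods <- x$periods
    individuals <- vapply(periods, function(p)
      sum(x$captures$count[x$captures$period == p]), numeric(1))
  } else {
    sites <- .check_cols(as.data.frame(x), "sites")
    periods <- c("historical", "modern")
    individuals <- NULL
  }
  d <- abs(sites$trap_nights_hist - sites$trap_nights_mod)
  per_site <- data.frame(site_id = sites$site_id,
                         elevation_m = sites$elevation_m,
                         trap_nights_hist = sites$trap_nights_hist,
                         trap_nights_mod = sites$trap_nights_mod,
                         abs_diff_tn = d)
  total <- c(sum(sites$trap_nights_hist), sum(sites$trap_nights_mod))
  names(total) <- periods
  n <- nrow(sites)
  out <- list(per_site = per_site, total = total,
              mean_abs_diff_tn = mean(d),
              se_abs_diff_tn = if (n > 1) stats::sd(d) / sqrt(n) else 0,
              max_abs_diff_tn = max(d),
              individuals = individuals)
  class(out) <- "effort_summary"
  out
}

#' @export
print.effort_summary <- function(x, ...) {
  cat("Sampling effort (trap-nights):\n")
  for (p in names(x$total))
    cat(sprintf("  %-12s %6d total\n", p, as.integer(x$total[p])))
  cat(sprintf("  per-site |difference|: mean %.1f, SE %.1f, max %d\n",
              x$mean_abs_diff_tn, x$se_abs_diff_tn,
              as.integer(x$max_abs_diff_tn)))
  if (!is.null(x$individuals)) {
    cat("Individuals captured:\n")
    for (p in names(x$individuals))
      cat(sprintf("  %-12s %6d\n", p, as.integer(x$individuals[p])))
  }
  invisible(x)
}

#' Species meeting the commonness threshold in both periods
#'
#' A species is retained when its total count reaches `min_captures` in each
#' of the two periods.  The result is ordered by the historical
#' abundance-weighted range centre, ascending — the order used when plotting
#' species along the gradient.
#'
#' @param dataset a [survey_dataset()].
#' @param min_captures minimum total captures required in each period
#'   (default 5).
#' @return Character vector of species identifiers (possibly empty).
#' @export
filter_common_species <- function(dataset, min_captures = 5) {
  stopifnot(inherits(dataset, "survey_dataset"), min_captures >= 1)
  caps <- dataset$captures
  if (!nrow(caps)) return(character(0))
  tot <- tapply(caps$count, list(caps$species, caps$period), sum)
  for (p in dataset$periods)
    if (!p %in% colnames(tot)) {
      tot <- cbind(tot, 0)
      colnames(tot)[ncol(tot)] <- p
    }
  tot[is.na(tot)] <- 0
  keep <- rownames(tot)[tot[, dataset$periods[1]] >= min_captures &
                        tot[, dataset$periods[2]] >= min_captures]
  if (!length(keep)) return(character(0))
  hist_mat <- species_site_matrix(dataset, dataset$periods[1], keep)
  centres <- as.numeric(hist_mat %*% dataset$sites$elevation_m) /
    rowSums(hist_mat)
  keep[order(centres)]
}

#' Counts of each species at each site in one period
#'
#' @param dataset a [survey_dataset()].
#' @param period one of the dataset's two period labels.
#' @param species species to include (default: all observed in the dataset).
#' @return Integer matrix, species in rows, sites in columns (ordered by
#'   elevation as in `dataset$sites`).
#' @export
species_site_matrix <- function(dataset, period, species = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (!period %in% dataset$periods)
    stop("unknown period label: ", period, call. = FALSE)
  if (is.null(species)) species <- sort(unique(dataset$captures$species))
  m <- matrix(0, nrow = length(species), ncol = nrow(dataset$sites),
              dimnames = list(species, dataset$sites$site_id))
  caps <- dataset$captures
  caps <- caps[caps$period == period & caps$species %in% species, ,
               drop = FALSE]
  if (nrow(caps))
    m[cbind(match(caps$species, species),
            match(caps$site_id, dataset$sites$site_id))] <- caps$count
  m
}

#' Packaged reference site and capture-total tables
#'
#' `wolong_sites()` returns the eight sampling sites of the Wolong Nature
#' Reserve rodent resurvey (1550-3500 m) with trap-nights for the 1986
#' (historical) and 2014-2015 (modern) surveys.  `wolong_site_totals()`
#' returns the per-site capture totals of both periods: all species and the
#' eleven common species retained for range-shift analysis, with species
#' richness alongside.  Per-species-per-site counts were never published, so
#' these tables support effort accounting and total checks only.
#'
#' @return A data frame.
#' @export
wolong_sites <- function() {
  utils::read.csv(system.file("extdata", "wolong_sites.csv",
                              package = "elevshift"))
}

#' @rdname wolong_sites
#' @export
wolong_site_totals <- function() {
  utils::read.csv(system.file("extdata", "wolong_site_totals.csv",
                              package = "elevshift"))
}
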