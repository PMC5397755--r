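# Builders for small in-memory surveys used across the suite.

tiny_sites <- function(n = 3, elev = seq(1000, by = 1000, length.out = n),
                       tn_hist = rep(100, n), tn_mod = rep(100, n)) {
  data.frame(site_id = paste0("s", seq_len(n)), elevation_m = elev,
             vegetation = "forest", trap_nights_hist = tn_hist,
             trap_nights_mod = tn_mod)
}

# counts_hist / counts_mod: species x site matrices (dimnames required)
matrix_dataset <- function(counts_hist, counts_mod, sites = NULL) {
  if (is.null(sites)) sites <- tiny_sites(ncol(counts_hist))
  to_long <- function(m, period) {
    idx <- which(m > 0, arr.ind = TRUE)
    data.frame(period = period, site_id = colnames(m)[idx[, 2]],
               species = rownames(m)[idx[, 1]], count = m[idx])
  }
  caps <- rbind(to_long(counts_hist, "historical"),
                to_long(counts_mod, "modern"))
  survey_dataset(sites, caps)
}

named_matrix <- function(data, species, sites) {
  matrix(data, nrow = length(species), byrow = TRUE,
         dimnames = list(species, sites))
}

# Independent oracle: per-species range points by explicit loops, no reuse
# of package internals.
oracle_range_points <- function(counts, elevations) {
  occ <- which(counts > 0)
  lower <- Inf; upper <- -Inf; wsum <- 0; tot <- 0
  for (i in occ) {
    if (elevations[i] < lower) lower <- elevations[i]
    if (elevations[i] > upper) upper <- elevations[i]
  }
  for (i in seq_along(counts)) {
    wsum <- wsum + elevations[i] * counts[i]
    tot <- tot + counts[i]
  }
  c(lower = lower, upper = upper, centre = wsum / tot)
}
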