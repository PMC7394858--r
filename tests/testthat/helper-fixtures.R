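# In-code builders for small datasets used across the tests.

metals <- metal_levels()

# A concentration tibble from a site -> matrix (rows = records) map.
make_ds <- function(compartment, site_values) {
  rows <- lapply(names(site_values), function(s) {
    m <- site_values[[s]]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    colnames(m) <- metals
    tbl <- tibble::tibble(
      record_id = sprintf("%s-%s-%03d", compartment, s, seq_len(nrow(m))),
      site = s,
      compartment = compartment
    )
    for (j in metals) tbl[[j]] <- m[, j]
    tbl
  })
  dplyr::bind_rows(rows)
}

# Summary row(s) straight from metal means (bypasses site_means).
make_summary <- function(compartment, site_means_map, n = 5L) {
  rows <- lapply(names(site_means_map), function(s) {
    v <- site_means_map[[s]]
    names(v) <- metals
    tbl <- tibble::tibble(site = s, compartment = compartment, n = n)
    for (j in metals) tbl[[j]] <- v[[j]]
    tbl
  })
  dplyr::bind_rows(rows)
}

# Long-format stomach table: stomachs is a named list animal_id -> named
# numeric vector of category masses (zero-length vector = empty stomach).
make_stomachs <- function(stomachs, site = "PAZ") {
  rows <- lapply(names(stomachs), function(id) {
    v <- stomachs[[id]]
    if (length(v) == 0) {
      return(tibble::tibble(animal_id = id, site = site,
                            category = NA_character_, wet_mass_g = NA_real_))
    }
    tibble::tibble(animal_id = id, site = site,
                   category = names(v), wet_mass_g = unname(v))
  })
  dplyr::bind_rows(rows)
}

rand_positive_matrix <- function(n, scale = 50) {
  matrix(stats::rlnorm(n * length(metals), log(scale), 0.5), nrow = n)
}
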