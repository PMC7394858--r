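# Readers/writers for the tidy concentration tables.
# Schemas (CSV, header row, decimal point):
#   soil: site,Pb,Cu,Ni,Zn,Cd
#   prey: site,taxon,group,Pb,Cu,Ni,Zn,Cd
#   tail: site,length_cm,weight_g,svl_cm,sex,Pb,Cu,Ni,Zn,Cd

meta_columns <- function(compartment) {
  switch(compartment,
    tail = c("length_cm", "weight_g", "svl_cm", "sex"),
    prey = c("taxon", "group"),
    soil = character(0)
  )
}

#' Read a concentration table
#'
#' Reads one compartment's CSV of per-sample metal concentrations and
#' validates it: all five metal columns must be present, every concentration
#' must parse as a non-negative number, and site codes must be known.
#' Unparseable numeric cells are an error, never silently dropped.
#'
#' @param path Path to a CSV file.
#' @param compartment One of `"tail"`, `"prey"`, `"soil"`; selects the
#'   expected metadata columns (biometrics for tails, taxon/group for prey).
#' @param sites Valid site codes; defaults to [site_levels()].
#' @return A tibble with columns `record_id`, `site`, `compartment`, the
#'   compartment's metadata columns, and one column per metal (mg/kg).
#' @export
#' @examples
#' path <- system.file("extdata", "soils.csv", package = "lizmet")
#' soils <- read_concentration_csv(path, "soil")
#' nrow(soils)  # 28
read_concentration_csv <- function(path,
                                   compartment = c("tail", "prey", "soil"),
                                   sites = site_levels()) {
  compartment <- match.arg(compartment)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  metals <- metal_levels()
  dat <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(c("site", metals), names(dat))
  if (length(missing_cols) > 0) {
    stop("format error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(dat) == 0) {
    out <- tibble::tibble(record_id = character(0), site = character(0),
                          compartment = character(0))
    for (mc in meta_columns(compartment)) out[[mc]] <- character(0)
    for (m in metals) out[[m]] <- numeric(0)
    return(out)
  }
  bad_site <- setdiff(unique(dat$site), sites)
  if (length(bad_site) > 0) {
    stop("validation error in ", path, ": unknown site code(s) ",
         paste(bad_site, collapse = ", "), "; valid codes are ",
         paste(sites, collapse = ", "), call. = FALSE)
  }
  parse_num <- function(col, what) {
    x <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(x) & !is.na(col) | is.na(col))
    if (length(bad) > 0) {
      stop("validation error in ", path, ": unparseable or missing ", what,
           " value in row(s) ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
    }
    x
  }
  conc <- lapply(metals, function(m) parse_num(dat[[m]], m))
  names(conc) <- metals
  neg <- which(Reduce(`|`, lapply(conc, function(x) x < 0)))
  if (length(neg) > 0) {
    stop("validation error in ", path, ": negative concentration in row(s) ",
         paste(neg, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    record_id = sprintf("%s-%s-%03d", compartment, dat$site, seq_len(nrow(dat))),
    site = dat$site,
    compartment = compartment
  )
  for (mc in meta_columns(compartment)) {
    if (!mc %in% names(dat)) {
      stop("format error in ", path, ": missing column ", mc, call. = FALSE)
    }
    if (mc %in% c("length_cm", "weight_g", "svl_cm")) {
      v <- parse_num(dat[[mc]], mc)
      if (any(v < 0)) stop("validation error in ", path, ": negative ", mc, call. = FALSE)
      out[[mc]] <- v
    } else if (mc == "sex") {
      v <- tolower(dat[[mc]])
      bad <- setdiff(unique(v), c("male", "female", "unknown"))
      if (length(bad) > 0) {
        stop("validation error in ", path, ": unknown sex value(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      out[[mc]] <- v
    } else {
      out[[mc]] <- dat[[mc]]
    }
  }
  for (m in metals) out[[m]] <- conc[[m]]
  out
}

#' Load the bundled Atacama survey dataset
#'
#' Returns the packaged coastal Atacama Desert concentration survey: 72
#' lizard-tail records (30 PAZ, 22 PAL, 20 CAL), 30 putative-prey records
#' and 28 soil records across the three sites, as printed in the source
#' survey's raw-data table.
#'
#' @return Named list of tibbles with elements `tail`, `prey` and `soil`,
#'   each as returned by [read_concentration_csv()].
#' @export
#' @examples
#' fx <- load_fixture()
#' table(fx$tail$site)
load_fixture <- function() {
  files <- c(tail = "tails.csv", prey = "preys.csv", soil = "soils.csv")
  out <- lapply(names(files), function(cmp) {
    path <- system.file("extdata", files[[cmp]], package = "lizmet")
    if (!nzchar(path) || !file.exists(path)) {
      stop("corrupted installation: bundled fixture ", files[[cmp]],
           " not found", call. = FALSE)
    }
    read_concentration_csv(path, cmp)
  })
  names(out) <- names(files)
  out
}

#' Write an index result or site summary to CSV
#'
#' Renders a result table with deterministic ordering: metals in the fixed
#' enumeration order (Pb, Cu, Ni, Zn, Cd) and sites in reporting order
#' (PAZ, PAL, CAL). Values are rounded only in the rendered file, never in
#' memory; with `digits = NULL` (the default) full precision is written and
#' a read-back reproduces the values to better than 12 significant digits.
#'
#' @param x A `metal_ratio` result ([bioaccumulation_factor()],
#'   [trophic_transfer_factor()]), a `risk_index` result
#'   ([ecological_risk()]), or a site summary ([site_means()]).
#' @param path Output file path.
#' @param digits Number of decimal places for the rendered file, or `NULL`
#'   for full precision.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path, digits = NULL) {
  wide <- result_table(x)
  if (!is.null(digits)) {
    num <- vapply(wide, is.numeric, logical(1))
    wide[num] <- lapply(wide[num], function(col) {
      formatC(col, format = "f", digits = digits)
    })
  }
  tryCatch(
    readr::write_csv(wide, path, progress = FALSE),
    error = function(e) stop("cannot write ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  invisible(path)
}

# Canonical wide rendering of a result object (sites x metals, site-ordered).
result_table <- function(x) {
  if (inherits(x, "metal_ratio")) {
    wide <- tidyr::pivot_wider(
      dplyr::select(x, "site", "metal", "ratio"),
      names_from = "metal", values_from = "ratio"
    )
    return(order_sites(wide)[, c("site", metal_levels()), drop = FALSE])
  }
  order_sites(x)
}

order_sites <- function(tbl) {
  lev <- c(intersect(site_levels(), tbl$site), setdiff(sort(unique(tbl$site)), site_levels()))
  tbl[order(match(tbl$site, lev)), , drop = FALSE]
}

#' Read a stomach-content table
#'
#' Long-format CSV with columns `animal_id,site,category,wet_mass_g`; one
#' row per prey category found in one stomach. An empty stomach is a row
#' whose `category` is empty/NA (it still counts toward the number of
#' stomachs examined).
#'
#' @param path Path to a CSV file.
#' @param sites Valid site codes; defaults to [site_levels()].
#' @return Tibble with columns `animal_id`, `site`, `category`,
#'   `wet_mass_g`.
#' @export
read_stomach_csv <- function(path, sites = site_levels()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- readr::read_csv(path, col_types = readr::cols(
    animal_id = readr::col_character(),
    site = readr::col_character(),
    category = readr::col_character(),
    wet_mass_g = readr::col_double()
  ), progress = FALSE)
  missing_cols <- setdiff(c("animal_id", "site", "category", "wet_mass_g"), names(dat))
  if (length(missing_cols) > 0) {
    stop("format error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_site <- setdiff(unique(dat$site), sites)
  if (length(bad_site) > 0) {
    stop("validation error in ", path, ": unknown site code(s) ",
         paste(bad_site, collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(dat$wet_mass_g) & dat$wet_mass_g < 0)) {
    stop("validation error in ", path, ": negative wet mass", call. = FALSE)
  }
  dat$category[!is.na(dat$category) & dat$category == ""] <- NA_character_
  dat
}
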