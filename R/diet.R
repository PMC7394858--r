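# Stomach-content diet composition: frequency of occurrence (FO) and
# percentage contribution by mass (%M) per prey category.
#
# Stomach tables are long-format tibbles: animal_id, site, category,
# wet_mass_g (one row per category found in one stomach, blotted wet mass
# in grams). An empty stomach is one row with category = NA; it counts as
# an examined stomach but contributes no items.

stomach_ids <- function(stomachs) unique(stomachs$animal_id)

# Collapse duplicate categories within a stomach (masses pre-summed per
# category by definition) and drop empty-stomach marker rows.
stomach_items <- function(stomachs) {
  items <- stomachs[!is.na(stomachs$category), , drop = FALSE]
  items |>
    dplyr::group_by(.data$animal_id, .data$site, .data$category) |>
    dplyr::summarise(wet_mass_g = sum(.data$wet_mass_g), .groups = "drop")
}

#' Frequency of occurrence of prey categories
#'
#' FO of a category is the percentage of examined stomachs in which the
#' category appears: `100 * n_stomachs_containing / n_stomachs`.
#'
#' @param stomachs Long-format stomach-content tibble (see
#'   [read_stomach_csv()]).
#' @param categories Categories to report; defaults to those observed.
#' @return Tibble with columns `category`, `n_stomachs`, `fo` (percent).
#' @export
#' @examples
#' st <- tibble::tibble(
#'   animal_id = c("a", "a", "b", "c", "d"),
#'   site = "PAZ",
#'   category = c("Amphipod", "Flowers", "Amphipod", NA, "Sand"),
#'   wet_mass_g = c(0.4, 0.1, 0.2, NA, 0.05)
#' )
#' frequency_of_occurrence(st)  # Amphipod in 2 of 4 stomachs -> 50%
frequency_of_occurrence <- function(stomachs, categories = NULL) {
  if (is.null(stomachs) || nrow(stomachs) == 0) {
    stop("no stomachs supplied", call. = FALSE)
  }
  n <- length(stomach_ids(stomachs))
  items <- stomach_items(stomachs)
  if (is.null(categories)) categories <- sort(unique(items$category))
  counts <- vapply(categories, function(cat) {
    length(unique(items$animal_id[items$category == cat]))
  }, integer(1))
  tibble::tibble(category = categories, n_stomachs = n,
                 fo = unname(100 * counts / n))
}

#' Percentage contribution by mass of prey categories
#'
#' With the default `method = "pooled"` (the standard Hyslop-style gravimetric
#' index), masses are pooled over all supplied stomachs before normalising:
#' `%M(c) = 100 * total mass of c / total mass of everything`. With
#' `method = "mean_of_stomachs"` each stomach is first converted to
#' per-stomach percentages and those are averaged over stomachs with
#' positive content mass; both variants sum to 100 over categories.
#'
#' @inheritParams frequency_of_occurrence
#' @param method `"pooled"` (default) or `"mean_of_stomachs"`.
#' @return Tibble with columns `category`, `pct_mass` (percent).
#' @export
percent_mass <- function(stomachs, categories = NULL,
                         method = c("pooled", "mean_of_stomachs")) {
  method <- match.arg(method)
  if (is.null(stomachs) || nrow(stomachs) == 0) {
    stop("no stomachs supplied", call. = FALSE)
  }
  items <- stomach_items(stomachs)
  if (nrow(items) == 0 || sum(items$wet_mass_g, na.rm = TRUE) <= 0) {
    stop("undefined mass proportions: total wet mass is zero", call. = FALSE)
  }
  if (anyNA(items$wet_mass_g)) {
    stop("missing wet mass for a non-empty stomach item", call. = FALSE)
  }
  if (is.null(categories)) categories <- sort(unique(items$category))
  if (method == "pooled") {
    total <- sum(items$wet_mass_g)
    mass <- vapply(categories, function(cat) {
      sum(items$wet_mass_g[items$category == cat])
    }, numeric(1))
    pct <- 100 * mass / total
  } else {
    per_stomach <- items |>
      dplyr::group_by(.data$animal_id) |>
      dplyr::mutate(pct = 100 * .data$wet_mass_g / sum(.data$wet_mass_g)) |>
      dplyr::ungroup()
    n_used <- length(unique(per_stomach$animal_id))
    pct <- vapply(categories, function(cat) {
      sum(per_stomach$pct[per_stomach$category == cat]) / n_used
    }, numeric(1))
  }
  tibble::tibble(category = categories, pct_mass = unname(pct))
}

#' Diet summary per site
#'
#' Combines [frequency_of_occurrence()] and [percent_mass()] into one table,
#' optionally per site. The category universe is the union of observed
#' categories and a fixed protocol list ([stomach_prey_categories()]);
#' categories absent from every stomach report FO = 0 and %M = 0.
#'
#' @inheritParams percent_mass
#' @param by_site If `TRUE` (default) summarise each site separately.
#' @param categories Category universe; defaults to the union of
#'   [stomach_prey_categories()] and the observed categories.
#' @return Tibble with columns `site` (or `"all"`), `n_stomachs`,
#'   `category`, `fo`, `pct_mass`.
#' @export
diet_summary <- function(stomachs, by_site = TRUE, categories = NULL,
                         method = c("pooled", "mean_of_stomachs")) {
  method <- match.arg(method)
  if (is.null(stomachs) || nrow(stomachs) == 0) {
    stop("no stomachs supplied", call. = FALSE)
  }
  if (is.null(categories)) {
    observed <- sort(unique(stomachs$category[!is.na(stomachs$category)]))
    categories <- union(stomach_prey_categories(), observed)
  }
  groups <- if (by_site) split(stomachs, stomachs$site) else list(all = stomachs)
  rows <- lapply(names(groups), function(s) {
    g <- groups[[s]]
    fo <- frequency_of_occurrence(g, categories = categories)
    pm <- percent_mass(g, categories = categories, method = method)
    tibble::tibble(site = s, n_stomachs = fo$n_stomachs,
                   category = categories, fo = fo$fo, pct_mass = pm$pct_mass)
  })
  dplyr::bind_rows(rows)
}
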