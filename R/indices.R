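# Scoring core: site aggregation, BAF, TTF, Er/RI and risk classification.
#
# All indices work on per-site arithmetic means of the raw per-sample
# concentrations (no trimming, no log transform):
#   BAF(m) = mean tail concentration / mean soil concentration
#   TTF(m) = mean tail concentration / mean prey concentration
#   Er(m)  = Tr(m) * Ci(m) / Cr(m),  RI = sum over metals of Er(m)
# with Ci the site soil mean, Cr the background value and Tr the toxic
# response factor.

#' Configuration for the ecological risk index
#'
#' Bundles the tunable constants of the risk computation: the toxic response
#' factors \eqn{T_r}, the background concentration set \eqn{C_r}, and the
#' risk-class boundaries.
#'
#' Class boundaries are half-open on the left: RI in \[0,150) is Low Risk,
#' \[150,300) Moderate, \[300,600) Considerable and \[600,Inf) High under
#' the defaults.
#'
#' @param toxic_response Named numeric vector of \eqn{T_r} per metal;
#'   defaults to [toxic_response_factors()].
#' @param background_set Name of a built-in background set (see
#'   [background_values()]), or a named numeric vector of \eqn{C_r} values
#'   (mg/kg) per metal.
#' @param class_bounds Strictly increasing numeric thresholds between risk
#'   classes.
#' @param class_labels Labels, one more than `class_bounds`.
#' @return An object of class `index_config`.
#' @export
#' @examples
#' index_config(background_set = "cenma2014")
index_config <- function(toxic_response = toxic_response_factors(),
                         background_set = "alloway1995",
                         class_bounds = c(150, 300, 600),
                         class_labels = c("Low Risk", "Moderate Risk",
                                          "Considerable Risk", "High Risk")) {
  metals <- metal_levels()
  if (is.character(background_set)) {
    background <- background_values(background_set)
    background_name <- background_set
  } else {
    background <- background_set
    background_name <- "custom"
  }
  missing_tr <- setdiff(metals, names(toxic_response))
  if (length(missing_tr) > 0) {
    stop("configuration error: toxic_response missing metal(s) ",
         paste(missing_tr, collapse = ", "), call. = FALSE)
  }
  missing_cr <- setdiff(metals, names(background))
  if (length(missing_cr) > 0) {
    stop("configuration error: background set missing metal(s) ",
         paste(missing_cr, collapse = ", "), call. = FALSE)
  }
  toxic_response <- toxic_response[metals]
  background <- background[metals]
  if (any(!is.finite(toxic_response)) || any(toxic_response <= 0)) {
    stop("configuration error: toxic response factors must be positive",
         call. = FALSE)
  }
  if (any(!is.finite(background)) || any(background <= 0)) {
    stop("configuration error: background concentrations must be positive",
         call. = FALSE)
  }
  if (is.unsorted(class_bounds, strictly = TRUE)) {
    stop("configuration error: class_bounds must be strictly increasing",
         call. = FALSE)
  }
  if (length(class_labels) != length(class_bounds) + 1) {
    stop("configuration error: need exactly length(class_bounds) + 1 labels",
         call. = FALSE)
  }
  structure(
    list(toxic_response = toxic_response, background = background,
         background_set = background_name, class_bounds = class_bounds,
         class_labels = class_labels),
    class = "index_config"
  )
}

#' @export
print.index_config <- function(x, ...) {
  cat("Ecological risk index configuration\n")
  cat("  background set:", x$background_set, "\n")
  cat("  Tr:", paste(names(x$toxic_response), x$toxic_response,
                     sep = "=", collapse = ", "), "\n")
  cat("  Cr:", paste(names(x$background), x$background,
                     sep = "=", collapse = ", "), "(mg/kg)\n")
  cat("  classes:", paste(x$class_labels, collapse = " | "),
      "at", paste(x$class_bounds, collapse = ", "), "\n")
  invisible(x)
}

#' Per-site mean concentrations
#'
#' Aggregates a concentration table to one row per site: the arithmetic mean
#' of each metal over all records of that site (no trimming, no log
#' transform), plus the sample count.
#'
#' @param ds Concentration tibble from [read_concentration_csv()] or
#'   [generate_dataset()].
#' @param sites Optional site codes to require; an error names any requested
#'   site that has no records. Defaults to the sites present in `ds`.
#' @return Tibble with columns `site`, `compartment`, `n` and one mean per
#'   metal (mg/kg), sites in reporting order.
#' @export
#' @examples
#' fx <- load_fixture()
#' site_means(fx$soil)
site_means <- function(ds, sites = NULL) {
  if (nrow(ds) == 0) stop("no records to aggregate", call. = FALSE)
  if (!is.null(sites)) {
    absent <- setdiff(sites, unique(ds$site))
    if (length(absent) > 0) {
      stop("no records for site(s): ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    ds <- ds[ds$site %in% sites, , drop = FALSE]
  }
  out <- ds |>
    dplyr::group_by(.data$site, .data$compartment) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(metal_levels()), mean),
      .groups = "drop"
    )
  order_sites(out)
}

# Shared core of BAF and TTF: element-wise ratio of two site-mean tables.
ratio_index <- function(numerator, denominator, kind,
                        num_compartment, den_compartment) {
  for (tbl in list(numerator, denominator)) {
    need <- c("site", "compartment", metal_levels())
    if (!all(need %in% names(tbl))) {
      stop(kind, ": inputs must be site summaries from site_means()",
           call. = FALSE)
    }
  }
  if (!all(numerator$compartment == num_compartment)) {
    stop(kind, ": numerator summary must be of compartment '",
         num_compartment, "'", call. = FALSE)
  }
  if (!all(denominator$compartment == den_compartment)) {
    stop(kind, ": denominator summary must be of compartment '",
         den_compartment, "'", call. = FALSE)
  }
  common <- intersect(numerator$site, denominator$site)
  if (length(common) == 0) stop(kind, ": no site in common", call. = FALSE)
  metals <- metal_levels()
  rows <- lapply(common, function(s) {
    num <- numerator[numerator$site == s, metals]
    den <- denominator[denominator$site == s, metals]
    zero <- metals[as.numeric(den) <= 0]
    if (length(zero) > 0) {
      stop(kind, ": zero ", den_compartment, " mean for metal ",
           paste(zero, collapse = ", "), " at site ", s, call. = FALSE)
    }
    tibble::tibble(
      site = s,
      metal = factor(metals, levels = metals),
      ratio = as.numeric(num) / as.numeric(den)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$exceeds <- out$ratio > 1
  out <- order_sites(out)
  class(out) <- c("metal_ratio", class(out))
  attr(out, "kind") <- kind
  out
}

#' Bioaccumulation factor (BAF)
#'
#' Ratio of the mean metal concentration in lizard-tail tissue to the mean
#' concentration in soil, per site and metal. A value greater than 1 implies
#' bioaccumulation with respect to the reference environmental matrix; the
#' `exceeds` flag marks exactly those cells.
#'
#' @param biota Site summary of tail records ([site_means()]).
#' @param soil Site summary of soil records.
#' @return A `metal_ratio` tibble: `site`, `metal`, `ratio`, `exceeds`.
#' @export
#' @examples
#' fx <- load_fixture()
#' bioaccumulation_factor(site_means(fx$tail), site_means(fx$soil))
bioaccumulation_factor <- function(biota, soil) {
  ratio_index(biota, soil, "BAF", "tail", "soil")
}

#' Trophic transfer factor (TTF)
#'
#' Ratio of the mean metal concentration in the consumer's tissue (lizard
#' tail) to the mean concentration in its food (pooled putative prey), per
#' site and metal. A TTF above 1 indicates a possibility of biomagnification
#' up the food chain; below 1, biomagnification is unlikely.
#'
#' Prey means pool all putative-prey records of the site with equal weight;
#' to weight prey groups by observed diet composition, pass `weights` as a
#' named vector of relative weights per prey `group`.
#'
#' @param tissue Site summary of tail records.
#' @param food Site summary of prey records, or (when `weights` is given)
#'   the raw prey concentration table.
#' @param weights Optional named numeric vector of diet weights per prey
#'   group; `NULL` (default) pools all prey records with equal weight.
#' @return A `metal_ratio` tibble: `site`, `metal`, `ratio`, `exceeds`.
#' @export
trophic_transfer_factor <- function(tissue, food, weights = NULL) {
  if (!is.null(weights)) {
    if (!"group" %in% names(food)) {
      stop("TTF: weighted variant needs raw prey records with a 'group' column",
           call. = FALSE)
    }
    food <- weighted_prey_means(food, weights)
  }
  ratio_index(tissue, food, "TTF", "tail", "prey")
}

# Diet-weighted prey means: weight each prey group's mean by its diet share.
weighted_prey_means <- function(prey, weights) {
  metals <- metal_levels()
  by_group <- prey |>
    dplyr::group_by(.data$site, .data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     dplyr::across(dplyr::all_of(metals), mean),
                     .groups = "drop")
  rows <- lapply(unique(by_group$site), function(s) {
    g <- by_group[by_group$site == s, , drop = FALSE]
    w <- weights[g$group]
    w[is.na(w)] <- 0
    if (sum(w) <= 0) {
      stop("TTF: diet weights give zero total weight at site ", s,
           call. = FALSE)
    }
    w <- w / sum(w)
    out <- tibble::tibble(site = s, compartment = "prey", n = sum(g$n))
    for (m in metals) out[[m]] <- sum(w * g[[m]])
    out
  })
  dplyr::bind_rows(rows)
}

#' @export
print.metal_ratio <- function(x, ...) {
  cat(attr(x, "kind"), "per site (values > 1 flagged):\n")
  print(result_table(x), ...)
  invisible(x)
}

#' Potential ecological risk index (RI)
#'
#' Hakanson's composite index of soil contamination. For each metal the
#' individual potential ecological risk factor is
#' \deqn{E_r = T_r \times C_i / C_r} with \eqn{T_r} the toxic response
#' factor, \eqn{C_i} the measured site soil mean and \eqn{C_r} the
#' background value; the composite index \eqn{RI = \sum_m E_r(m)} over the
#' five metals is classified against fixed thresholds (see
#' [classify_risk()]).
#'
#' @param soil Site summary of soil records ([site_means()]).
#' @param config An [index_config()].
#' @return A `risk_index` tibble with columns `site`, `Er_Pb` ... `Er_Cd`,
#'   `RI` and `risk_class`.
#' @export
#' @examples
#' fx <- load_fixture()
#' ecological_risk(site_means(fx$soil), index_config())
ecological_risk <- function(soil, config = index_config()) {
  if (!inherits(config, "index_config")) {
    stop("config must be an index_config object", call. = FALSE)
  }
  need <- c("site", "compartment", metal_levels())
  if (!all(need %in% names(soil))) {
    stop("RI: input must be a site summary from site_means()", call. = FALSE)
  }
  if (!all(soil$compartment == "soil")) {
    stop("RI: summary must be of compartment 'soil'", call. = FALSE)
  }
  metals <- metal_levels()
  er <- vapply(metals, function(m) {
    config$toxic_response[[m]] * soil[[m]] / config$background[[m]]
  }, numeric(nrow(soil)))
  er <- matrix(er, nrow = nrow(soil),
               dimnames = list(NULL, paste0("Er_", metals)))
  out <- tibble::tibble(site = soil$site)
  for (j in colnames(er)) out[[j]] <- unname(er[, j])
  out$RI <- rowSums(er)
  out$risk_class <- classify_risk(out$RI, config)
  out <- order_sites(out)
  class(out) <- c("risk_index", class(out))
  attr(out, "background_set") <- config$background_set
  out
}

#' @export
print.risk_index <- function(x, ...) {
  cat("Potential ecological risk (background set:",
      attr(x, "background_set"), ")\n")
  NextMethod()
}

#' Classify a risk index value
#'
#' Maps RI values to risk-class labels using half-open intervals: with the
#' default bounds, RI in \[0,150) is "Low Risk", \[150,300) "Moderate Risk",
#' \[300,600) "Considerable Risk" and 600 or more "High Risk". A boundary
#' value belongs to the class above it.
#'
#' @param ri Numeric vector of non-negative RI values.
#' @param config An [index_config()] carrying the bounds and labels.
#' @return Character vector of class labels.
#' @export
#' @examples
#' classify_risk(c(0, 149.9, 150, 296.8, 600), index_config())
classify_risk <- function(ri, config = index_config()) {
  if (any(!is.finite(ri)) || any(ri < 0)) {
    stop("RI must be finite and non-negative", call. = FALSE)
  }
  config$class_labels[findInterval(ri, config$class_bounds) + 1]
}

#' Run the full index pipeline
#'
#' Composes [site_means()] with the three index computations: BAF from tails
#' vs soils, TTF from tails vs pooled prey, and RI from soils. This is the
#' pipeline behind the survey's published index tables.
#'
#' @param datasets Named list with concentration tibbles `tail`, `prey` and
#'   `soil`, as returned by [load_fixture()] or [generate_dataset()].
#' @param config An [index_config()].
#' @return List with elements `BAF`, `TTF` (`metal_ratio` tibbles) and `RI`
#'   (`risk_index` tibble).
#' @export
#' @examples
#' res <- run_full_analysis(load_fixture())
#' res$RI
run_full_analysis <- function(datasets, config = index_config()) {
  need <- c("tail", "prey", "soil")
  missing_cmp <- setdiff(need, names(datasets))
  if (length(missing_cmp) > 0) {
    stop("datasets must contain compartment(s): ",
         paste(missing_cmp, collapse = ", "), call. = FALSE)
  }
  tail_means <- site_means(datasets$tail)
  prey_means <- site_means(datasets$prey)
  soil_means <- site_means(datasets$soil)
  list(
    BAF = bioaccumulation_factor(tail_means, soil_means),
    TTF = trophic_transfer_factor(tail_means, prey_means),
    RI = ecological_risk(soil_means, config)
  )
}
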