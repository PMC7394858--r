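# Site-comparison battery for concentration data.
#
# Decision tree (conventional a priori / a posteriori scheme):
#   1. a priori checks: Shapiro-Wilk normality per site group and
#      Brown-Forsythe (median-centred Levene) homogeneity of variance;
#   2. if every group passes normality and variances are homogeneous at
#      `alpha`, the omnibus mean test is one-way ANOVA with Tukey HSD
#      post hoc; otherwise Kruskal-Wallis with Dunn's rank post hoc and
#      Holm adjustment.

#' Compare metal concentrations between sites
#'
#' Runs the assumption-gated site-comparison battery for one metal in one
#' compartment: per-group Shapiro-Wilk and Levene (Brown-Forsythe) checks,
#' then either one-way ANOVA + Tukey HSD (assumptions met) or
#' Kruskal-Wallis + Dunn with Holm adjustment. The decision path taken is
#' recorded in the report.
#'
#' @param ds Concentration tibble (one compartment).
#' @param metal One of [metal_levels()].
#' @param alpha Significance level used both for the assumption gate and
#'   reported decisions; default 0.05.
#' @return A `site_comparison` object: list with `metal`, `compartment`,
#'   `group_n`, `assumptions` (tibble of checks), `omnibus` (list),
#'   `posthoc` (tibble, one row per unordered site pair), `adjustment`
#'   and `path` (`"anova"` or `"kruskal"`).
#' @export
#' @examples
#' fx <- load_fixture()
#' compare_sites(fx$tail, "Pb")
compare_sites <- function(ds, metal, alpha = 0.05) {
  stopifnot(metal %in% metal_levels())
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  values <- ds[[metal]]
  groups <- factor(ds$site)
  n_by <- table(groups)
  if (length(n_by) < 2) {
    stop("need at least two sites to compare", call. = FALSE)
  }
  small <- names(n_by)[n_by < 3]
  if (length(small) > 0) {
    stop("insufficient records (< 3) for site group(s): ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  if (stats::var(values) == 0) {
    stop("degenerate input: zero variance across all records", call. = FALSE)
  }

  shapiro <- lapply(levels(groups), function(g) {
    x <- values[groups == g]
    res <- tryCatch(stats::shapiro.test(x),
                    error = function(e) list(statistic = NA_real_, p.value = 0))
    tibble::tibble(check = "shapiro_wilk", group = g,
                   statistic = unname(res$statistic), p = res$p.value)
  })
  lev <- car::leveneTest(values ~ groups, center = stats::median)
  assumptions <- dplyr::bind_rows(
    dplyr::bind_rows(shapiro),
    tibble::tibble(check = "levene_brown_forsythe", group = "all",
                   statistic = lev[1, "F value"], p = lev[1, "Pr(>F)"])
  )
  normal_ok <- all(assumptions$p[assumptions$check == "shapiro_wilk"] > alpha)
  homosced_ok <- assumptions$p[assumptions$check == "levene_brown_forsythe"] > alpha

  if (normal_ok && homosced_ok) {
    path <- "anova"
    fit <- stats::aov(values ~ groups)
    anova_tab <- summary(fit)[[1]]
    omnibus <- list(method = "one-way ANOVA",
                    statistic = anova_tab[1, "F value"],
                    df = unname(anova_tab[, "Df"]),
                    p = anova_tab[1, "Pr(>F)"])
    tk <- stats::TukeyHSD(fit)$groups
    pairs <- rownames(tk)
    posthoc <- tibble::tibble(
      pair = pairs,
      statistic = tk[, "diff"],
      p_adj = tk[, "p adj"]
    )
    adjustment <- "tukey"
  } else {
    path <- "kruskal"
    kw <- stats::kruskal.test(values, groups)
    omnibus <- list(method = "Kruskal-Wallis",
                    statistic = unname(kw$statistic),
                    df = unname(kw$parameter),
                    p = kw$p.value)
    posthoc <- dunn_posthoc(values, groups, p_adjust = "holm")
    adjustment <- "holm"
  }
  structure(
    list(metal = metal,
         compartment = if ("compartment" %in% names(ds)) unique(ds$compartment) else NA_character_,
         alpha = alpha,
         group_n = as.integer(n_by),
         sites = names(n_by),
         assumptions = assumptions,
         omnibus = omnibus,
         posthoc = posthoc,
         adjustment = adjustment,
         path = path),
    class = "site_comparison"
  )
}

#' Dunn's post-hoc rank test
#'
#' Pairwise z-statistics on mean ranks after a Kruskal-Wallis omnibus test,
#' with the usual tie correction; two-sided p-values adjusted by
#' `p_adjust` (Holm by default).
#'
#' @param values Numeric response vector.
#' @param groups Factor of group labels, same length.
#' @param p_adjust Adjustment method passed to [stats::p.adjust()].
#' @return Tibble with one row per unordered group pair: `pair`,
#'   `statistic` (z), `p`, `p_adj`.
#' @export
dunn_posthoc <- function(values, groups, p_adjust = "holm") {
  groups <- factor(groups)
  n_total <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, groups, mean)
  n_by <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n_total - 1))
  lev <- levels(groups)
  combs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(combs))
  pair <- character(ncol(combs))
  for (k in seq_len(ncol(combs))) {
    i <- combs[1, k]; j <- combs[2, k]
    se <- sqrt((n_total * (n_total + 1) / 12 - tie_term) *
                 (1 / n_by[[i]] + 1 / n_by[[j]]))
    z[k] <- (mean_rank[[i]] - mean_rank[[j]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
    pair[k] <- paste(j, i, sep = "-")
  }
  tibble::tibble(pair = pair, statistic = z, p = p,
                 p_adj = stats::p.adjust(p, method = p_adjust))
}

#' @export
print.site_comparison <- function(x, ...) {
  cat("Site comparison:", x$metal, "in", x$compartment, "\n")
  cat("  groups:", paste(sprintf("%s (n=%d)", x$sites, x$group_n),
                         collapse = ", "), "\n")
  cat("  path:", if (x$path == "anova") "ANOVA + Tukey HSD"
      else "Kruskal-Wallis + Dunn (Holm)", "\n")
  cat(sprintf("  omnibus: %s statistic = %.4g, p = %.4g\n",
              x$omnibus$method, x$omnibus$statistic, x$omnibus$p))
  cat("  post hoc:\n")
  print(x$posthoc, ...)
  invisible(x)
}

#' Site-comparison battery over compartments and metals
#'
#' Runs [compare_sites()] for every compartment x metal combination and
#' reports omnibus p-values both raw and Holm-adjusted within each
#' compartment's five-metal family.
#'
#' @param datasets Named list of concentration tibbles keyed by compartment
#'   (any subset of tail/prey/soil), or a single tibble.
#' @param alpha Significance level, default 0.05.
#' @return List with `reports` (named list of `site_comparison` objects,
#'   names like `"tail.Pb"`) and `summary` (tibble: `compartment`, `metal`,
#'   `path`, `method`, `statistic`, `p`, `p_holm`).
#' @export
#' @examples
#' fx <- load_fixture()
#' batch_compare(fx["tail"])$summary
batch_compare <- function(datasets, alpha = 0.05) {
  if (is.data.frame(datasets)) {
    cmp <- unique(datasets$compartment)
    datasets <- stats::setNames(list(datasets), cmp[1])
  }
  reports <- list()
  rows <- list()
  for (cmp in names(datasets)) {
    family_p <- numeric(0)
    for (m in metal_levels()) {
      rep <- compare_sites(datasets[[cmp]], m, alpha = alpha)
      reports[[paste(cmp, m, sep = ".")]] <- rep
      family_p[m] <- rep$omnibus$p
      rows[[paste(cmp, m)]] <- tibble::tibble(
        compartment = cmp, metal = m, path = rep$path,
        method = rep$omnibus$method,
        statistic = rep$omnibus$statistic, p = rep$omnibus$p
      )
    }
    adj <- stats::p.adjust(family_p, method = "holm")
    for (m in metal_levels()) {
      rows[[paste(cmp, m)]]$p_holm <- adj[[m]]
    }
  }
  list(reports = reports, summary = dplyr::bind_rows(rows))
}
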