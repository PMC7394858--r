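#' Metals quantified by the survey
#'
#' The five heavy metals measured in every compartment, in the fixed column
#' order used by all matrix-shaped outputs (Pb, Cu, Ni, Zn, Cd).
#'
#' @return Character vector of length five.
#' @export
#' @examples
#' metal_levels()
metal_levels <- function() {
  c("Pb", "Cu", "Ni", "Zn", "Cd")
}

#' Survey site codes
#'
#' The three coastal Atacama sites, in reporting order: Parque Nacional Pan
#' de Azucar (PAZ, reference site), Caleta Palitos (PAL, legacy mine-tailing
#' discharge) and Puerto de Caldera (CAL, active industrial port).
#'
#' @return Character vector of site codes.
#' @export
site_levels <- function() {
  c("PAZ", "PAL", "CAL")
}

#' Sample compartments
#'
#' @return Character vector: `"tail"` (lizard tail tissue), `"prey"`
#'   (putative prey items) and `"soil"`.
#' @export
compartment_levels <- function() {
  c("tail", "prey", "soil")
}

#' Toxic response factors for the ecological risk index
#'
#' Metal-specific toxicity weights \eqn{T_r} used by the Hakanson potential
#' ecological risk index: 30 for Cd, 5 for Cu, Ni and Pb, and 1 for Zn.
#'
#' @return Named numeric vector over [metal_levels()].
#' @seealso [ecological_risk()], [index_config()]
#' @export
toxic_response_factors <- function() {
  c(Pb = 5, Cu = 5, Ni = 5, Zn = 1, Cd = 30)
}

#' Background soil concentration sets
#'
#' Reference ("background") soil concentrations \eqn{C_r} in mg/kg against
#' which measured soil concentrations are contrasted in the risk index.
#' Two built-in sets are available: `"alloway1995"`, background values of
#' world soils (the default used for the bundled survey), and `"cenma2014"`,
#' a regional Chilean reference set.
#'
#' @param set Character, one of `"alloway1995"` or `"cenma2014"`.
#' @return Named numeric vector (mg/kg) over [metal_levels()].
#' @export
#' @examples
#' background_values("alloway1995")
background_values <- function(set = c("alloway1995", "cenma2014")) {
  set <- match.arg(set)
  switch(set,
    alloway1995 = c(Pb = 32, Cu = 18.5, Ni = 20, Zn = 64, Cd = 1),
    cenma2014   = c(Pb = 12.7, Cu = 91.6, Ni = 41.7, Zn = 75.9, Cd = 1.2)
  )
}

#' Published index tables for the bundled survey
#'
#' The site-by-metal BAF and TTF tables and the site RI table as printed in
#' the original survey report, embedded so that [reproduce_tables()] can
#' compare a fresh computation against them without any external resource.
#'
#' @return A list with elements `baf` and `ttf` (tibbles: `site` plus one
#'   column per metal) and `ri` (tibble: `site`, `RI`, `risk_class`).
#' @seealso [reproduce_tables()]
#' @export
printed_reference_tables <- function() {
  baf <- tibble::tribble(
    ~site,  ~Pb,  ~Cu,  ~Ni,  ~Zn,  ~Cd,
    "PAZ", 3.71, 1.72, 0.90, 2.26, 0.18,
    "PAL", 5.56, 2.82, 1.33, 5.03, 0.25,
    "CAL", 4.23, 1.23, 0.49, 2.36, 0.24
  )
  ttf <- tibble::tribble(
    ~site,  ~Pb,  ~Cu,  ~Ni,  ~Zn,  ~Cd,
    "PAZ", 1.66, 1.63, 1.62, 0.99, 0.19,
    "PAL", 2.22, 2.59, 2.93, 3.49, 0.38,
    "CAL", 0.91, 1.24, 1.76, 1.08, 1.79
  )
  ri <- tibble::tibble(
    site = c("PAZ", "PAL", "CAL"),
    RI = c(296.8, 285.6, 290.6),
    risk_class = rep("Moderate Risk", 3)
  )
  list(baf = baf, ttf = ttf, ri = ri)
}

#' Prey categories of the stomach-content protocol
#'
#' The fixed list of prey-item categories scored in the stomach-content
#' analysis; [diet_summary()] reports these even when absent from every
#' stomach (FO and %M of zero), unioned with whatever categories the data
#' contain.
#'
#' @return Character vector of category labels.
#' @export
stomach_prey_categories <- function() {
  c(
    "Amphipod", "Decapod", "Echinolittorina sp.", "Ulva sp.", "Porphyra sp.",
    "UID Insecta", "UID Lepidoptera", "UID Diptera", "UID Coleoptera",
    "Tenebrionidae", "Microlophus atacamensis", "Flowers", "Fish", "Sand"
  )
}
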