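test_that("frequency of occurrence is a direct stomach count", {
  # present in 1 of 4 stomachs -> 25%
  st <- make_stomachs(list(
    a = c(Amphipod = 0.5),
    b = c(Flowers = 0.2),
    c = c(Flowers = 0.1, Sand = 0.05),
    d = character(0)  # empty stomach still counts as examined
  ))
  st$wet_mass_g[is.na(st$wet_mass_g) & !is.na(st$category)] <- 0
  fo <- frequency_of_occurrence(st)
  expect_equal(fo$fo[fo$category == "Amphipod"], 25)
  expect_equal(fo$fo[fo$category == "Flowers"], 50)
  expect_equal(unique(fo$n_stomachs), 4)

  # present in all of 10 stomachs -> 100%
  all10 <- make_stomachs(stats::setNames(
    replicate(10, c(Decapod = 0.3), simplify = FALSE), paste0("s", 1:10)))
  expect_equal(frequency_of_occurrence(all10)$fo, 100)

  expect_error(frequency_of_occurrence(make_stomachs(list())), "no stomachs")
})

test_that("percent mass pools masses before normalising and sums to 100", {
  st <- make_stomachs(list(a = c(Algae = 3), b = c(Flowers = 1)))
  pm <- percent_mass(st)
  expect_equal(pm$pct_mass[pm$category == "Algae"], 75)
  expect_equal(pm$pct_mass[pm$category == "Flowers"], 25)

  single <- make_stomachs(list(a = c(Sand = 0.123)))
  expect_equal(percent_mass(single)$pct_mass, 100)

  zero <- make_stomachs(list(a = c(Sand = 0)))
  expect_error(percent_mass(zero), "zero")
})

test_that("random synthetic stomachs match a brute-force summation oracle", {
  set.seed(14)
  cats <- c("Amphipod", "Decapod", "Ulva sp.", "Flowers", "Sand")
  for (rep in 1:10) {
    stomachs <- lapply(1:8, function(i) {
      picked <- sample(cats, sample(1:4, 1))
      stats::setNames(round(stats::runif(length(picked), 0.001, 2), 3), picked)
    })
    names(stomachs) <- paste0("an", 1:8)
    st <- make_stomachs(stomachs)
    pm <- percent_mass(st)
    expect_equal(sum(pm$pct_mass), 100, tolerance = 1e-9)
    # oracle: accumulate masses by hand over the list structure
    total <- sum(unlist(stomachs))
    for (cat in unique(pm$category)) {
      hand <- 100 * sum(unlist(lapply(stomachs, function(v) sum(v[names(v) == cat]))),
                        na.rm = TRUE) / total
      expect_equal(pm$pct_mass[pm$category == cat], hand, tolerance = 1e-9)
    }
    # FO oracle: count stomach membership by hand
    fo <- frequency_of_occurrence(st)
    for (cat in fo$category) {
      hand <- 100 * sum(vapply(stomachs, function(v) cat %in% names(v),
                               logical(1))) / length(stomachs)
      expect_equal(fo$fo[fo$category == cat], hand)
    }
  }
})

test_that("FO is invariant to mass rescaling; empty stomachs dilute FO only", {
  set.seed(9)
  stomachs <- list(a = c(Amphipod = 0.4, Flowers = 0.1),
                   b = c(Amphipod = 0.2), c = c(Sand = 0.6))
  st <- make_stomachs(stomachs)
  fo1 <- frequency_of_occurrence(st)
  pm1 <- percent_mass(st)
  st_scaled <- st
  st_scaled$wet_mass_g <- st_scaled$wet_mass_g * 1000
  expect_equal(frequency_of_occurrence(st_scaled)$fo, fo1$fo)
  expect_equal(percent_mass(st_scaled)$pct_mass, pm1$pct_mass)

  with_empty <- dplyr::bind_rows(st, make_stomachs(list(zz = character(0))))
  fo2 <- frequency_of_occurrence(with_empty)
  expect_true(all(fo2$fo <= fo1$fo))
  expect_true(all(fo2$fo[fo1$fo > 0] < fo1$fo[fo1$fo > 0]))
  expect_equal(percent_mass(with_empty)$pct_mass, pm1$pct_mass)
})

test_that("diet summary composes FO and %M per site over the protocol categories", {
  # cohort mirroring the slaughtered-animal split: 10 CAL, 10 PAZ, 7 PAL
  set.seed(27)
  cats <- c("Amphipod", "Decapod", "Ulva sp.", "Flowers")
  build_site <- function(site, n) {
    stomachs <- lapply(seq_len(n), function(i) {
      picked <- sample(cats, sample(1:3, 1))
      stats::setNames(stats::runif(length(picked), 0.01, 1), picked)
    })
    names(stomachs) <- paste0(site, seq_len(n))
    make_stomachs(stomachs, site = site)
  }
  st <- dplyr::bind_rows(build_site("CAL", 10), build_site("PAZ", 10),
                         build_site("PAL", 7))
  smry <- diet_summary(st, by_site = TRUE)
  expect_equal(sort(unique(smry$site)), c("CAL", "PAL", "PAZ"))
  expect_equal(unique(smry$n_stomachs[smry$site == "PAL"]), 7)
  # per-site values equal composing the two base operations on the subset
  for (s in c("CAL", "PAZ", "PAL")) {
    sub <- st[st$site == s, ]
    cats_all <- sort(unique(smry$category))
    fo <- frequency_of_occurrence(sub, categories = cats_all)
    pm <- percent_mass(sub, categories = cats_all)
    got <- smry[smry$site == s, ]
    got <- got[order(got$category), ]
    expect_equal(got$fo, fo$fo[order(fo$category)])
    expect_equal(got$pct_mass, pm$pct_mass[order(pm$category)])
    expect_equal(sum(got$pct_mass), 100, tolerance = 1e-9)
  }
  # protocol categories absent from every stomach report zeroes
  expect_true(all(c("Porphyra sp.", "Fish") %in% smry$category))
  expect_equal(unique(smry$fo[smry$category == "Fish"]), 0)
  expect_equal(unique(smry$pct_mass[smry$category == "Fish"]), 0)
})

test_that("per-stomach averaging variant also yields a 100% composition", {
  st <- make_stomachs(list(a = c(Algae = 3, Sand = 1), b = c(Algae = 1)))
  pm <- percent_mass(st, method = "mean_of_stomachs")
  expect_equal(sum(pm$pct_mass), 100, tolerance = 1e-9)
  # stomach a: 75/25, stomach b: 100/0 -> means 87.5 / 12.5
  expect_equal(pm$pct_mass[pm$category == "Algae"], 87.5)
  expect_equal(pm$pct_mass[pm$category == "Sand"], 12.5)
})

test_that("duplicate categories within a stomach are pre-summed", {
  st <- tibble::tibble(animal_id = c("a", "a"), site = "PAZ",
                       category = "Amphipod", wet_mass_g = c(0.2, 0.3))
  fo <- frequency_of_occurrence(st)
  expect_equal(fo$fo, 100)
  pm <- percent_mass(st)
  expect_equal(pm$pct_mass, 100)
})
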