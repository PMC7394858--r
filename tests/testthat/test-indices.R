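test_that("site means are plain arithmetic means per site", {
  fx <- load_fixture()
  sm <- site_means(fx$soil)
  # hand-summed oracle: the eight PAZ soil Pb values
  paz_pb <- fx$soil$Pb[fx$soil$site == "PAZ"]
  expect_equal(sum(paz_pb), 124.91)
  expect_equal(sm$Pb[sm$site == "PAZ"], 124.91 / 8)
  expect_equal(sm$n, c(8L, 12L, 8L))
  expect_equal(sm$site, c("PAZ", "PAL", "CAL"))

  # single-record site: means equal the record
  one <- make_ds("soil", list(PAZ = c(1, 2, 3, 4, 5)))
  sm1 <- site_means(one)
  expect_equal(as.numeric(sm1[1, metals]), c(1, 2, 3, 4, 5))

  # duplicating every record leaves means unchanged
  dup <- dplyr::bind_rows(fx$soil, fx$soil)
  dup$record_id <- paste0(dup$record_id, seq_len(nrow(dup)))
  sm2 <- site_means(dup)
  expect_equal(sm2[metals], sm[metals])
  expect_equal(sm2$n, sm$n * 2L)

  expect_error(site_means(fx$soil, sites = c("PAZ", "XXX")), "XXX")
})

test_that("BAF is biota mean over soil mean with exceedance at ratio > 1", {
  biota <- make_summary("tail", list(PAZ = c(10, 4, 2, 8, 0.5)))
  soil <- make_summary("soil", list(PAZ = c(5, 4, 4, 2, 1)))
  baf <- bioaccumulation_factor(biota, soil)
  expect_s3_class(baf, "metal_ratio")
  expect_equal(baf$ratio, c(2, 1, 0.5, 4, 0.5))
  expect_equal(baf$exceeds, c(TRUE, FALSE, FALSE, TRUE, FALSE))

  # biota identical to soil: every ratio exactly 1, nothing flagged
  same <- make_summary("tail", list(PAZ = c(5, 4, 4, 2, 1)))
  ident <- bioaccumulation_factor(same, soil)
  expect_equal(ident$ratio, rep(1, 5))
  expect_false(any(ident$exceeds))

  zero_soil <- make_summary("soil", list(PAZ = c(0, 4, 4, 2, 1)))
  expect_error(bioaccumulation_factor(biota, zero_soil), "Pb.*PAZ")
  expect_error(bioaccumulation_factor(soil, soil), "compartment 'tail'")
})

test_that("TTF mirrors BAF against prey means, with optional diet weighting", {
  tissue <- make_summary("tail", list(CAL = c(9, 6, 3, 12, 1)))
  food <- make_summary("prey", list(CAL = c(3, 6, 6, 4, 5)))
  ttf <- trophic_transfer_factor(tissue, food)
  expect_equal(ttf$ratio, c(3, 1, 0.5, 3, 0.2))
  expect_equal(ttf$exceeds, ttf$ratio > 1)

  # weighted variant: all weight on one group equals ratio vs that group
  prey_raw <- make_ds("prey", list(CAL = rbind(c(2, 2, 2, 2, 2),
                                               c(10, 10, 10, 10, 10))))
  prey_raw$group <- c("Algae", "Crustacea")
  w_only_algae <- c(Algae = 1, Crustacea = 0)
  ttf_w <- trophic_transfer_factor(tissue, prey_raw, weights = w_only_algae)
  expect_equal(ttf_w$ratio, as.numeric(tissue[1, metals]) / 2)

  # equal weights on equal-sized groups equal the pooled mean here
  ttf_eq <- trophic_transfer_factor(tissue, prey_raw,
                                    weights = c(Algae = 1, Crustacea = 1))
  expect_equal(ttf_eq$ratio, as.numeric(tissue[1, metals]) / 6)
})

test_that("Er and RI follow the Hakanson formula", {
  cfg <- index_config()
  # Ci equal to Cr for every metal forces Er = Tr, so RI = 30+5+5+5+1 = 46
  soil <- make_summary("soil", list(PAZ = unname(background_values()[metals])))
  ri <- ecological_risk(soil, cfg)
  expect_equal(as.numeric(ri[1, paste0("Er_", metals)]),
               unname(toxic_response_factors()[metals]))
  expect_equal(ri$RI, 46)
  expect_equal(ri$risk_class, "Low Risk")

  # direct substitution: Cd with Ci = 5, Cr = 1, Tr = 30 gives Er = 150
  soil2 <- make_summary("soil", list(PAZ = c(32, 18.5, 20, 64, 5)))
  ri2 <- ecological_risk(soil2, cfg)
  expect_equal(ri2$Er_Cd, 30 * 5 / 1)

  # RI equals the sum of its Er components to 1e-9 relative
  set.seed(11)
  for (i in 1:20) {
    s <- make_summary("soil", list(PAZ = stats::runif(5, 0.1, 100)))
    r <- ecological_risk(s, cfg)
    expect_equal(r$RI, sum(r[1, paste0("Er_", metals)]), tolerance = 1e-9)
  }

  expect_error(ecological_risk(make_summary("tail", list(PAZ = 1:5)), cfg),
               "soil")
  expect_error(index_config(toxic_response = c(Pb = 5)), "missing metal")
  expect_error(index_config(class_bounds = c(300, 150, 600)), "increasing")
})

test_that("per-sample brute-force RI agrees with RI of the site mean", {
  # linearity oracle: mean over samples of per-sample RI == RI of the mean
  cfg <- index_config()
  set.seed(7)
  vals <- rand_positive_matrix(25)
  ds <- make_ds("soil", list(PAL = vals))
  ri_of_mean <- ecological_risk(site_means(ds), cfg)$RI
  per_sample <- apply(vals, 1, function(row) {
    sum(cfg$toxic_response[metals] * row / cfg$background[metals])
  })
  expect_equal(ri_of_mean, mean(per_sample), tolerance = 1e-9)
})

test_that("risk classification uses half-open intervals and is monotone", {
  cfg <- index_config()
  expect_equal(classify_risk(296.8, cfg), "Moderate Risk")
  expect_equal(classify_risk(0, cfg), "Low Risk")
  expect_equal(classify_risk(600, cfg), "High Risk")
  expect_equal(classify_risk(c(149.999, 150), cfg),
               c("Low Risk", "Moderate Risk"))
  expect_error(classify_risk(-1, cfg), "non-negative")

  # monotone in RI with respect to the ordered labels
  set.seed(3)
  x <- sort(stats::runif(200, 0, 1000))
  cls <- classify_risk(x, cfg)
  rank_of <- match(cls, cfg$class_labels)
  expect_true(all(diff(rank_of) >= 0))
})

test_that("scaling one metal in tails scales BAF and TTF and leaves RI unchanged", {
  fx <- load_fixture()
  k <- 3.7
  scaled <- fx
  scaled$tail$Cu <- scaled$tail$Cu * k
  base <- run_full_analysis(fx)
  res <- run_full_analysis(scaled)
  pick <- function(r, m) r$ratio[as.character(r$metal) == m]
  expect_equal(pick(res$BAF, "Cu"), pick(base$BAF, "Cu") * k)
  expect_equal(pick(res$TTF, "Cu"), pick(base$TTF, "Cu") * k)
  expect_equal(pick(res$BAF, "Pb"), pick(base$BAF, "Pb"))
  expect_equal(res$RI$RI, base$RI$RI)
})

test_that("exceedance flags are exactly ratio > 1 on randomised summaries", {
  set.seed(21)
  for (i in 1:25) {
    b <- make_summary("tail", list(PAZ = stats::runif(5, 0.5, 2)))
    s <- make_summary("soil", list(PAZ = stats::runif(5, 0.5, 2)))
    r <- bioaccumulation_factor(b, s)
    expect_identical(r$exceeds, r$ratio > 1)
  }
})

test_that("full pipeline is order-invariant and respects site restriction", {
  fx <- load_fixture()
  base <- run_full_analysis(fx)
  set.seed(5)
  shuffled <- lapply(fx, function(d) d[sample(nrow(d)), , drop = FALSE])
  res <- run_full_analysis(shuffled)
  expect_equal(res$BAF$ratio, base$BAF$ratio)
  expect_equal(res$TTF$ratio, base$TTF$ratio)
  expect_equal(res$RI$RI, base$RI$RI)

  one_site <- lapply(fx, function(d) d[d$site == "CAL", , drop = FALSE])
  res1 <- run_full_analysis(one_site)
  expect_equal(unique(res1$BAF$site), "CAL")
  expect_equal(res1$RI$site, "CAL")
  expect_equal(res1$BAF$ratio,
               base$BAF$ratio[base$BAF$site == "CAL"])

  expect_error(run_full_analysis(fx[c("tail", "soil")]), "prey")
})
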