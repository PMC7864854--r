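test_that("GDP kernel weights decay with log-GDP distance and respect borders", {
  regions <- data.frame(
    region_id = c("A1", "A2", "A3", "B1"),
    country_id = c("A", "A", "A", "B"),
    gdp_pc = c(exp(10), exp(10), exp(10.5), exp(10)),
    stringsAsFactors = FALSE)
  h <- 0.5
  w <- gdp_kernel_weights(regions, h)
  expect_equal(unname(diag(w)), rep(0, 4))
  expect_equal(unname(w["A1", "B1"]), 0)   # never across countries
  expect_equal(unname(w["B1", "A1"]), 0)
  expect_equal(unname(rowSums(w)[1:3]), rep(1, 3))
  expect_equal(unname(rowSums(w)["B1"]), 0)  # single-region country

  # log-GDP gap exactly h: pre-normalisation weight e^{-1/2}; with the
  # equal-GDP neighbour at weight 1 the normalised value is known
  e <- exp(-0.5)
  expect_equal(unname(w["A1", "A2"]), 1 / (1 + e), tolerance = 1e-12)
  expect_equal(unname(w["A1", "A3"]), e / (1 + e), tolerance = 1e-12)

  # symmetry of the unnormalised kernel: ratios agree across rows
  expect_equal(unname(w["A3", "A1"]), unname(w["A3", "A2"]))

  # flat-kernel limit: huge h makes all within-country weights equal
  wflat <- gdp_kernel_weights(regions, 1e6)
  expect_equal(unname(wflat["A1", c("A2", "A3")]), c(0.5, 0.5),
               tolerance = 1e-9)
  expect_error(gdp_kernel_weights(regions, 0), "h > 0")
})

test_that("reference rate is the stated mix of borrowing sources", {
  # homogeneous fixed point: every cell at rate mu -> m = mu everywhere
  regions <- data.frame(region_id = paste0("R", 1:3), country_id = "C",
                        gdp_pc = exp(c(10, 10.2, 9.8)),
                        stringsAsFactors = FALSE)
  grid <- expand.grid(education = c("low", "medium", "high"),
                      region_id = regions$region_id, stringsAsFactors = FALSE)
  cells <- data.frame(country_id = "C", region_id = grid$region_id,
                      education = grid$education, n_women = 100L,
                      total_children = 180L, n_unknown = 0L,
                      stringsAsFactors = FALSE)
  w <- gdp_kernel_weights(regions, 0.3)
  m <- reference_rate(cells, regions, w)
  expect_equal(m, rep(1.8, 9), tolerance = 1e-12)

  # pure cross-region borrowing: size-weighted mean of equal-GDP donors
  regions2 <- data.frame(region_id = c("R1", "R2", "R3"), country_id = "C",
                         gdp_pc = exp(10), stringsAsFactors = FALSE)
  cells2 <- data.frame(
    country_id = "C", region_id = c("R1", "R2", "R3"),
    education = "high",
    n_women = c(50L, 100L, 300L),
    total_children = c(100L, 150L, 750L),  # CFRs 2.0, 1.5, 2.5
    n_unknown = 0L, stringsAsFactors = FALSE)
  w2 <- gdp_kernel_weights(regions2, 0.3)
  p <- eb_params(mix_weights = c(region = 1, education = 0))
  full2 <- regfert:::complete_cells(cells2, regions2)
  m2 <- reference_rate(full2, regions2, w2, p)
  i <- which(full2$region_id == "R1" & full2$education == "high")
  expect_equal(m2[i], (100 * 1.5 + 300 * 2.5) / 400, tolerance = 1e-12)

  # with no same-education donors the education source takes all the weight
  lone_reg <- data.frame(region_id = "R1", country_id = "C",
                         gdp_pc = exp(10), stringsAsFactors = FALSE)
  lone <- data.frame(country_id = "C", region_id = "R1",
                     education = c("low", "medium", "high"),
                     n_women = c(100L, 100L, 0L),
                     total_children = c(200L, 160L, 0L),
                     n_unknown = 0L, stringsAsFactors = FALSE)
  wl <- gdp_kernel_weights(lone_reg, 0.3)
  ml <- reference_rate(lone, lone_reg, wl)
  # high cell: pooled other-education rate 1.8; country-level ratio falls
  # back to 1 because the high group has no data anywhere
  expect_equal(ml[3], 1.8, tolerance = 1e-12)

  # a dataset with no data at all cannot be smoothed
  none <- lone; none$n_women <- 0L; none$total_children <- 0L
  expect_warning(mn <- reference_rate(none, lone_reg, wl), "cannot be smoothed")
  expect_true(all(is.na(mn)))
})

test_that("smoothing matches a brute-force recomputation on random cells", {
  toy <- toy_dataset(seed = 7)
  p <- eb_params()
  est <- smooth_table(toy$cells, toy$regions, p)
  oracle <- brute_force_eb(toy$cells, toy$regions, p)
  expect_equal(est$cfr, oracle$cfr, tolerance = 1e-10)
})

test_that("method-of-moments prior strength tracks heterogeneity", {
  # homogeneity: identical raw CFRs, large N -> upper cap
  hom <- data.frame(country_id = "C", region_id = paste0("R", 1:6),
                    education = "high", n_women = 1000L,
                    total_children = 1800L, n_unknown = 0L,
                    stringsAsFactors = FALSE)
  expect_equal(estimate_nu(hom), 1e6)

  # huge heterogeneity -> near the lower cap
  het <- hom
  het$total_children <- c(100L, 8000L, 300L, 9000L, 200L, 7000L)
  expect_lt(estimate_nu(het), 5)

  expect_warning(estimate_nu(hom[1, ]), "fewer than 2")

  # Monte-Carlo calibration: cell rates drawn Gamma(shape k, mean m_bar)
  # imply nu = k / m_bar; the moment estimator recovers it within 25%
  set.seed(17)
  k <- 60; m_bar <- 1.8; n_cells <- 60; N <- 1000L
  nu_true <- k / m_bar
  nu_hat <- replicate(200, {
    rates <- rgamma(n_cells, shape = k, rate = k / m_bar)
    cells <- data.frame(country_id = "C",
                        region_id = paste0("R", seq_len(n_cells)),
                        education = "high", n_women = N,
                        total_children = rpois(n_cells, N * rates),
                        n_unknown = 0L, stringsAsFactors = FALSE)
    estimate_nu(cells)
  })
  expect_lt(abs(mean(nu_hat) - nu_true) / nu_true, 0.25)
})

test_that("conjugate posterior update and its limits are exact", {
  # arithmetic of the update
  post <- eb_posterior(B = 30, N = 20, m = 1.8, nu = 10)
  expect_equal(post$mean, (30 + 18) / (20 + 10))

  # no-prior limit: nu -> 0 gives the raw CFR
  expect_equal(eb_posterior(30, 20, 1.8, 1e-9)$mean, 1.5, tolerance = 1e-9)

  # no-data limit: N = 0 gives the reference rate
  expect_equal(eb_posterior(0, 0, 1.8, 25)$mean, 1.8)

  # interval endpoints agree with numerical integration of the density
  post2 <- eb_posterior(B = 87, N = 53, m = 1.7, nu = 12)
  a <- post2$shape_a; b <- post2$rate_b
  expect_equal(post2$ci_low, quadrature_gamma_quantile(0.025, a, b),
               tolerance = 1e-6)
  expect_equal(post2$ci_high, quadrature_gamma_quantile(0.975, a, b),
               tolerance = 1e-6)
})

test_that("smoothing shrinks toward the reference, less so for larger cells", {
  regions <- data.frame(region_id = paste0("R", 1:4), country_id = "C",
                        gdp_pc = exp(c(9.8, 10, 10.1, 10.3)),
                        stringsAsFactors = FALSE)
  set.seed(23)
  grid <- expand.grid(education = c("low", "medium", "high"),
                      region_id = regions$region_id, stringsAsFactors = FALSE)
  n <- sample(c(30L, 5000L), nrow(grid), replace = TRUE)
  cells <- data.frame(country_id = "C", region_id = grid$region_id,
                      education = grid$education, n_women = n,
                      total_children = rpois(nrow(grid), n * 1.8),
                      n_unknown = 0L, stringsAsFactors = FALSE)
  est <- smooth_table(cells, regions)
  m <- attr(est, "reference_rate")
  raw <- raw_cfr(cells)
  key <- paste(est$region_id, est$education)
  raw_aligned <- raw$cfr[match(key, paste(raw$region_id, raw$education))]
  # shrinkage bounds: EB strictly between raw and m (or equal when raw == m)
  for (i in seq_along(key)) {
    lo <- min(raw_aligned[i], m[i]); hi <- max(raw_aligned[i], m[i])
    expect_gte(est$cfr[i], lo - 1e-12)
    expect_lte(est$cfr[i], hi + 1e-12)
  }

  # two cells identical except N: the smaller sits closer to m
  regions2 <- data.frame(region_id = paste0("R", 1:3), country_id = "C",
                         gdp_pc = exp(10), stringsAsFactors = FALSE)
  cells2 <- data.frame(
    country_id = "C", region_id = c("R1", "R2", "R3"),
    education = "high",
    n_women = c(50L, 5000L, 1000L),
    total_children = c(110L, 11000L, 1500L),  # R1, R2 raw 2.2; donor 1.5
    n_unknown = 0L, stringsAsFactors = FALSE)
  est2 <- smooth_table(cells2, regions2,
                       eb_params(mix_weights = c(region = 1, education = 0),
                                 prior_strength_nu = 100))
  e_small <- est2$cfr[est2$region_id == "R1" & est2$education == "high"]
  e_big <- est2$cfr[est2$region_id == "R2" & est2$education == "high"]
  expect_lt(abs(e_big - 2.2), abs(e_small - 2.2))

  # empty cells still get an estimate equal to their reference rate
  cells3 <- cells[!(cells$region_id == "R2" & cells$education == "high"), ]
  est3 <- smooth_table(cells3, regions)
  m3 <- attr(est3, "reference_rate")
  i0 <- which(est3$region_id == "R2" & est3$education == "high")
  expect_equal(est3$cfr[i0], m3[i0])
})

test_that("shrinkage vanishes for register-sized cells", {
  cfg <- synthetic_config(n_countries = 2, regions_per_country = 4,
                          women_per_region = 400000, seed = 13)
  md <- generate_microdata(generate_regions(cfg), cfg)
  cells <- aggregate_microdata(md)
  regions <- generate_regions(cfg)
  est <- smooth_table(cells, regions)
  raw <- raw_cfr(cells)
  key <- paste(est$region_id, est$education)
  raw_aligned <- raw$cfr[match(key, paste(raw$region_id, raw$education))]
  expect_lt(max(abs(est$cfr - raw_aligned)), 0.01)
})

test_that("full smoothing matches the brute-force oracle on a 3x4x3 toy", {
  toy <- toy_dataset(seed = 101)
  for (p in list(eb_params(),
                 eb_params(bandwidth_h = 0.2,
                           mix_weights = c(region = 0.5, education = 0.5)),
                 eb_params(prior_strength_nu = 40))) {
    est <- smooth_table(toy$cells, toy$regions, p)
    oracle <- brute_force_eb(toy$cells, toy$regions, p)
    expect_equal(est$cfr, oracle$cfr, tolerance = 1e-10)
    expect_equal(est$ci_low, oracle$ci_low, tolerance = 1e-10)
    expect_equal(est$ci_high, oracle$ci_high, tolerance = 1e-10)
  }
})
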