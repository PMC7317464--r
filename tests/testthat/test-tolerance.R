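test_that("the BRI and rank transforms match their definitions and domains", {
  expect_equal(host_tolerance_from_bri(100), 0)
  expect_equal(host_tolerance_from_bri(0), 1)
  expect_equal(host_tolerance_from_bri(37.5), 0.625)
  expect_equal(symbiont_tolerance_from_rank(100), 1)
  expect_equal(symbiont_tolerance_from_rank(0), 0)
  expect_equal(symbiont_tolerance_from_rank(25), 0.5)
  expect_error(host_tolerance_from_bri(101), class = "coralnet_domain_error")
  expect_error(host_tolerance_from_bri(-1), class = "coralnet_domain_error")
  expect_error(symbiont_tolerance_from_rank(150), class = "coralnet_domain_error")
})

test_that("both transforms are monotone and land in [0, 1]", {
  withr::with_seed(3, {
    bri <- sort(runif(50, 0, 100))
    rank <- sort(runif(50, 0, 100))
  })
  th <- host_tolerance_from_bri(bri)
  ts <- symbiont_tolerance_from_rank(rank)
  expect_true(all(diff(th) <= 0))  # higher BRI -> lower host tolerance
  expect_true(all(diff(ts) >= 0))  # higher rank -> higher symbiont tolerance
  expect_true(all(th >= 0 & th <= 1))
  expect_true(all(ts >= 0 & ts <= 1))
})

test_that("host imputation draws from the congener normal and clamps", {
  tab <- tibble::tibble(species = "Coral listed", bri_mean = 40, bri_sd = 10)
  withr::with_seed(21, {
    draws <- impute_host_tolerance("Coral unlisted", tab, n = 10000)
  })
  expect_true(all(draws$tolerance >= 0 & draws$tolerance <= 1))
  # E[1 - BRI/100] with BRI ~ N(40, 10) (clamping negligible) = 0.60
  expect_lt(abs(mean(draws$tolerance) - 0.60), 0.01)
  # sd = 0 donor is deterministic
  tab0 <- tibble::tibble(species = "Coral listed", bri_mean = 30, bri_sd = 0)
  expect_equal(unique(impute_host_tolerance("Coral unlisted", tab0, n = 50)$tolerance),
               0.7)
  # a donor far below zero clamps to BRI 0 -> tolerance 1
  tabneg <- tibble::tibble(species = "Coral listed", bri_mean = -500, bri_sd = 0)
  expect_warning(out <- impute_host_tolerance("Coral x", tabneg, n = 3), NA)
  expect_equal(out$tolerance, c(1, 1, 1))
})

test_that("closest-relative resolution prefers congeners, then family, then global", {
  tab <- tibble::tibble(
    species = c("Acropora listed", "Porites other"),
    family = c("Acroporidae", "Poritidae"),
    bri_mean = c(20, 80), bri_sd = c(0, 0))
  # congener present
  expect_equal(impute_host_tolerance("Acropora new", tab)$tolerance, 0.8)
  # no congener, confamilial present
  expect_equal(impute_host_tolerance("Goniopora new", tab,
                                     family = "Poritidae")$tolerance, 0.2)
  # fallback disabled -> imputation error naming the species
  expect_error(impute_host_tolerance("Goniopora new", tab, family = "Mussidae",
                                     global_fallback = FALSE),
               "Goniopora new", class = "coralnet_imputation_error")
})

test_that("symbiont class imputation respects the mixing proportions", {
  cm <- default_class_model()
  withr::with_seed(8, {
    draws <- impute_symbiont_tolerance("Durusdinium", cm, n = 10000)
  })
  freq <- table(draws$class) / 10000
  target <- cm$proportions[cm$proportions$genus == "Durusdinium", ]
  for (cl in c("high", "medium", "low")) {
    expect_lt(abs(freq[[cl]] - target[[cl]]), 0.02)
  }
  expect_true(all(draws$tolerance >= 0 & draws$tolerance <= 1))
  # a 100%-high point-mass model is deterministic: sqrt(81)/10 = 0.9
  cm_point <- list(
    classes = tibble::tibble(class = "high", mean = 81, sd = 0),
    proportions = tibble::tibble(genus = "unknown", high = 1))
  expect_equal(impute_symbiont_tolerance("Cladocopium", cm_point, n = 5)$tolerance,
               rep(0.9, 5))
})

test_that("bad class models are configuration errors", {
  cm <- default_class_model()
  cm$classes <- cm$classes[0, ]
  expect_error(impute_symbiont_tolerance("Cladocopium", cm),
               class = "coralnet_configuration_error")
  cm2 <- default_class_model()
  cm2$proportions$high <- cm2$proportions$high + 0.5
  expect_error(impute_symbiont_tolerance("Cladocopium", cm2),
               class = "coralnet_configuration_error")
})

test_that("measured tolerances are replicate-invariant, imputed ones are redrawn", {
  b <- synth_bundle("single-subregion", seed = 2, n_hosts = 30,
                    n_symbionts = 15, n_links = 60,
                    unlisted_host_frac = 0.4, unlisted_sym_frac = 0.4)
  plan <- bundle_network(b)
  r1 <- coralnet:::with_substream(101, realize_tolerances(plan))
  r2 <- coralnet:::with_substream(202, realize_tolerances(plan))
  meas_h <- plan$hosts$tol_source == "measured"
  meas_s <- plan$symbionts$tol_source == "measured"
  expect_true(any(meas_h) && any(!meas_h) && any(meas_s) && any(!meas_s))
  expect_identical(r1$hosts$tolerance[meas_h], r2$hosts$tolerance[meas_h])
  expect_identical(r1$symbionts$tolerance[meas_s], r2$symbionts$tolerance[meas_s])
  expect_false(identical(r1$symbionts$tolerance[!meas_s],
                         r2$symbionts$tolerance[!meas_s]))
  expect_false(identical(r1$hosts$tolerance[!meas_h], r2$hosts$tolerance[!meas_h]))
  # all realized tolerances respect the unit interval
  for (r in list(r1, r2)) {
    expect_true(all(node_tolerances(r)$tolerance >= 0 &
                      node_tolerances(r)$tolerance <= 1))
  }
})

test_that("host_impute_once freezes imputed host tolerances across replicates", {
  b <- synth_bundle("single-subregion", seed = 2, n_hosts = 30,
                    n_symbionts = 15, n_links = 60,
                    unlisted_host_frac = 0.4, unlisted_sym_frac = 0)
  records <- filter_records(b$records, known_subregions = b$env$subregion)
  net <- build_network(records, env = b$env)
  plan <- coralnet:::with_substream(
    7, tolerance_plan(net, b$host_table, b$symbiont_table, host_impute_once = TRUE))
  r1 <- coralnet:::with_substream(101, realize_tolerances(plan))
  r2 <- coralnet:::with_substream(202, realize_tolerances(plan))
  expect_identical(r1$hosts$tolerance, r2$hosts$tolerance)
})
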