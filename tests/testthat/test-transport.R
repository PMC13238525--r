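test_that("travel time sums length over velocity along the flow path", {
  chain <- as_reach_network(tibble::tibble(
    reach_id = c("H", "O"), downstream_id = c("O", NA),
    length_m = c(1000, 2000), width_m = 5, slope = 0, elevation_m = 0,
    source_area_m2 = 1))
  h <- tibble::tibble(reach_id = c("H", "O"), discharge = 1, velocity = 1)
  expect_equal(travel_time(chain, h, "H", "H"), 1000)
  expect_equal(travel_time(chain, h, "H", "O"), 3000)
  expect_error(travel_time(chain, h, "O", "H"), "not downstream")
})

test_that("travel time is additive over intermediate reaches", {
  net <- as_reach_network(random_tree(40, 3))
  h <- reach_hydraulics(net)
  heads <- net$reaches$reach_id[!(net$reaches$reach_id %in%
                                    net$reaches$downstream_id)]
  for (hw in heads[1:5]) {
    path <- downstream_path(net, hw)
    if (length(path) < 3) next
    b <- path[ceiling(length(path) / 2)]
    c <- path[length(path)]
    # oracle: per-reach sum along the path
    v <- h$velocity[match(path, h$reach_id)]
    len <- net$reaches$length_m[match(path, net$reaches$reach_id)]
    expect_equal(travel_time(net, h, hw, c), sum(len / v), tolerance = 1e-12)
    expect_equal(travel_time(net, h, hw, c),
                 travel_time(net, h, hw, b) +
                   travel_time(net, h, b, c) -
                   travel_time(net, h, b, b),
                 tolerance = 1e-9)
  }
})

test_that("confluence concentration matches the hand-computed Y-network case", {
  net <- hand_net()
  h <- hand_hydraulics()
  prod <- matrix(c(1, 1, 0), ncol = 1, dimnames = list(NULL, "t1"))
  conc <- forward_concentration(net, h, tau = 1000, production = prod)
  expect_equal(conc$concentration[conc$reach_id == "C"], exp(-1),
               tolerance = 1e-9)
})

test_that("mass is conserved without decay and zero production gives zero", {
  for (seed in 1:5) {
    net <- as_reach_network(random_tree(30, seed))
    q <- rep(1, 30)
    routed <- route_discharge(net, q, method = "sum")
    h <- tibble::tibble(reach_id = routed$reach_id,
                        discharge = routed$discharge, velocity = 1)
    prod <- matrix(stats::runif(30), ncol = 1)
    conc <- forward_concentration(net, h, tau = 1e18, production = prod)
    outflux <- conc$concentration[conc$reach_id == net$outlet_id] *
      routed$discharge[routed$reach_id == net$outlet_id]
    expect_equal(outflux, sum(prod * net$reaches$source_area_m2),
                 tolerance = 1e-9)
    zero <- forward_concentration(net, h, tau = 1000,
                                  production = matrix(0, 30, 1))
    expect_true(all(zero$concentration == 0))
  }
})

test_that("the forward model is linear in production and monotone in tau", {
  for (seed in 1:20) {
    n <- sample(10:40, 1)
    net <- as_reach_network(random_tree(n, seed + 100))
    h <- reach_hydraulics(net)
    p1 <- matrix(stats::runif(n), ncol = 1)
    p2 <- matrix(stats::runif(n), ncol = 1)
    a <- stats::runif(1, 0.1, 3)
    c1 <- forward_concentration(net, h, 5000, p1)$concentration
    c2 <- forward_concentration(net, h, 5000, p2)$concentration
    c12 <- forward_concentration(net, h, 5000, p1 + a * p2)$concentration
    expect_equal(c12, c1 + a * c2, tolerance = 1e-9)
  }
  net <- as_reach_network(random_tree(25, 7))
  h <- reach_hydraulics(net)
  p <- matrix(stats::runif(25), ncol = 1)
  slow <- forward_concentration(net, h, 50000, p)$concentration
  fast <- forward_concentration(net, h, 500, p)$concentration
  expect_true(all(fast <= slow + 1e-12))
})

test_that("read prediction is a nonnegative linear map", {
  net <- hand_net()
  conc <- forward_concentration(net, hand_hydraulics(), 1000,
                                matrix(1, 3, 1))
  expect_true(all(predict_reads(conc, 0)$expected_reads == 0))
  expect_equal(predict_reads(conc, 1)$expected_reads, conc$concentration)
  expect_equal(predict_reads(conc, 4)$expected_reads,
               2 * predict_reads(conc, 2)$expected_reads)
})

test_that("presence thresholding is monotone and honours detection-derived cutoffs", {
  conc <- tibble::tibble(
    reach_id = rep(c("A", "B", "C"), 2),
    taxon_id = rep(c("t1", "t2"), each = 3),
    concentration = c(0.5, 0.2, 0.05, 1, 0, 2))
  p0 <- presence_field(conc, threshold = 1e-12)
  expect_equal(sum(p0$presence), sum(conc$concentration > 0))
  phigh <- presence_field(conc, threshold = 10)
  expect_false(any(phigh$presence))
  pmid <- presence_field(conc, threshold = 0.3)
  expect_true(all(pmid$presence <= p0$presence))
  # derived per-taxon threshold: min predicted concentration at detected sites
  obs <- tibble::tibble(site_id = c("s1", "s2"), taxon_id = "t1",
                        value = c(3, 0))
  sites <- tibble::tibble(site_id = c("s1", "s2"), reach_id = c("B", "C"))
  pd <- presence_field(conc, observed = obs, sites = sites)
  t1 <- pd[pd$taxon_id == "t1", ]
  expect_equal(t1$presence, c(TRUE, TRUE, FALSE))  # threshold = 0.2 from s1/B
  expect_false(any(pd$presence[pd$taxon_id == "t2"]))  # never detected
})

# small self-consistent calibration scenario
calib_fixture <- function(n = 30, n_sites = 12, tau_true = 8000, seed = 5,
                          sigma = 0) {
  net <- as_reach_network(random_tree(n, seed))
  h <- reach_hydraulics(net)
  set.seed(seed)
  w <- matrix(stats::runif(2 * n, 0.2, 1), n, 2,
              dimnames = list(NULL, c("t1", "t2")))
  conc <- forward_concentration(net, h, tau_true, 1e-4 * w)
  sites <- tibble::tibble(site_id = sprintf("s%02d", seq_len(n_sites)),
                          reach_id = sample(net$reaches$reach_id, n_sites))
  obs <- dplyr::inner_join(sites, conc, by = "reach_id")
  obs$value <- 1e5 * obs$concentration * exp(stats::rnorm(nrow(obs), 0, sigma))
  list(net = net, h = h, w = w,
       observed = obs[, c("site_id", "taxon_id", "value")], sites = sites,
       tau_true = tau_true)
}

test_that("calibration recovers tau from noise-free self-generated data", {
  fx <- calib_fixture()
  fit <- calibrate(fx$net, fx$h, fx$observed, fx$sites, weights = fx$w,
                   n_starts = 4, seed = 1)
  expect_lt(abs(fit$tau - fx$tau_true) / fx$tau_true, 0.01)
  expect_false(fit$degenerate)
  # invariant: reported objective equals the loss recomputed from residuals
  expect_equal(fit$objective, sum(fit$residuals$residual^2), tolerance = 1e-6)
})

test_that("underdetermined and all-zero calibrations are reported, not hidden", {
  single <- as_reach_network(tibble::tibble(
    reach_id = "A", downstream_id = NA, length_m = 1000, width_m = 7.2,
    slope = 0, elevation_m = 0, source_area_m2 = 1))
  h <- reach_hydraulics(single)
  obs <- tibble::tibble(site_id = "s1", taxon_id = "t1", value = 10)
  sites <- tibble::tibble(site_id = "s1", reach_id = "A")
  expect_warning(fit <- calibrate(single, h, obs, sites, n_starts = 2),
                 "degenerate")
  expect_true(fit$degenerate)

  fx <- calib_fixture()
  obs2 <- fx$observed
  obs2$value[obs2$taxon_id == "t2"] <- 0
  expect_warning(fit2 <- calibrate(fx$net, fx$h, obs2, fx$sites,
                                   weights = fx$w, n_starts = 2),
                 "all-zero")
  expect_identical(fit2$skipped_taxa, "t2")
  expect_false("t2" %in% fit2$production$taxon_id)
})

test_that("leave-one-out validation separates signal from noise", {
  fx <- calib_fixture(n = 20, n_sites = 8)
  loo <- loo_crossvalidate(fx$net, fx$h, fx$observed, fx$sites,
                           weights = fx$w, n_starts = 2, seed = 1)
  expect_gt(loo$r, 0.99)
  # pure noise: held-out correlation should not be significantly positive
  set.seed(9)
  noise <- fx$observed
  noise$value <- stats::rexp(nrow(noise), 1)
  loo_n <- loo_crossvalidate(fx$net, fx$h, noise, fx$sites,
                             weights = fx$w, n_starts = 2, seed = 1)
  expect_false(!is.na(loo_n$p_value) && loo_n$p_value < 0.05 && loo_n$r > 0)
  # too few sites for a refit
  two <- fx$observed[fx$observed$site_id %in% c("s01", "s02"), ]
  expect_error(loo_crossvalidate(fx$net, fx$h, two, fx$sites), "3 sites")
})
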