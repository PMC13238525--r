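test_that("standardization centres, scales, and rejects constants", {
  expect_equal(standardize_series(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize_series(stats::rnorm(50, 10, 3))
  expect_equal(standardize_series(z), z, tolerance = 1e-12)
  expect_error(standardize_series(rep(2, 10)), "constant")
  expect_error(standardize_series(c(1, NA, 3)), "finite")
})

test_that("delay embedding builds lagged coordinate vectors", {
  e <- embed_series(c(1, 2, 3, 4), E = 2, tau_lag = 1)
  expect_equal(unname(e[, 1]), c(2, 3, 4))
  expect_equal(unname(e[, 2]), c(1, 2, 3))
  x <- stats::rnorm(20)
  e1 <- embed_series(x, E = 1)
  expect_equal(as.numeric(e1), x)
  expect_error(embed_series(stats::rnorm(5), E = 3, tau_lag = 2), "too short")
})

test_that("simplex prediction is exact on matches and skilled on structure", {
  # exact query match takes the matched point's value
  x <- c(1, 5, 2, 4, 3, 1, 5, 2, 4, 3, 1, 5, 2, 4, 3)
  sp <- simplex_project(x, E = 2)
  expect_gt(sp$rho, 0.999)  # repeating cycle fully in library
  xs <- sin(2 * pi * (1:200) / 20)
  expect_gt(simplex_project(xs, E = 2)$rho, 0.99)
  set.seed(1)
  noise <- standardize_series(stats::rnorm(200))
  expect_lt(abs(simplex_project(noise, E = 2)$rho), 0.3)
  expect_error(simplex_project(stats::rnorm(6), E = 5), "not enough|too short")
})

test_that("C++ neighbour search matches the exhaustive pure-R oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(15:30, 1)
    E <- sample(1:2, 1)
    x <- stats::rnorm(n)
    pts <- embed_series(x, E)
    y <- stats::rnorm(nrow(pts))
    # full library with leave-one-out exclusion
    pred_cpp <- riverweb:::cpp_simplex_predict(pts, y, pts, seq_len(nrow(pts)))
    pred_oracle <- vapply(seq_len(nrow(pts)), function(i)
      oracle_simplex(pts, y, pts[i, ], self = i), numeric(1))
    expect_equal(pred_cpp, pred_oracle, tolerance = 1e-12)
    # exact-match query with no exclusion returns the stored value
    pred_self <- riverweb:::cpp_simplex_predict(pts, y, pts[3, , drop = FALSE],
                                                0L)
    expect_equal(pred_self, y[3], tolerance = 1e-12)
  }
})

test_that("embedding dimension selection favours low-dimensional maps", {
  logi <- function(n, x0 = 0.4) {
    v <- numeric(n); v[1] <- x0
    for (t in seq_len(n - 1)) v[t + 1] <- 3.8 * v[t] * (1 - v[t])
    v
  }
  E <- select_E(standardize_series(logi(200)))
  expect_true(E %in% 1:3)
  expect_lte(as.integer(select_E(sin(2 * pi * (1:100) / 25))), 3)
  expect_warning(select_E(stats::rnorm(12), E_max = 10), "truncated")
})

test_that("cross mapping recovers the direction and asymmetry of forcing", {
  cl <- coupled_logistic()
  xy <- ccm(cl$x, cl$y, E = 2, seed = 1)   # recovers y -> x (weak, 0.02)
  yx <- ccm(cl$y, cl$x, E = 2, seed = 1)   # recovers x -> y (strong, 0.1)
  expect_true(xy$convergent)
  expect_true(yx$convergent)
  expect_gt(yx$rho_max, xy$rho_max)  # stronger forcing, better recovery
  expect_true(all(diff(xy$skill_curve$lib_size) > 0))
  expect_true(all(abs(xy$skill_curve$rho) <= 1))

  set.seed(2)
  a <- stats::rnorm(200); b <- stats::rnorm(200)
  indep <- ccm(a, b, E = 2, seed = 2)
  expect_false(indep$convergent)

  self <- ccm(cl$x, cl$x, E = 2, seed = 1)
  expect_gt(self$rho_max, 0.95)
  expect_true(self$convergent)

  expect_warning(ccm(cl$x[1:60], cl$y[1:60], E = 2,
                     lib_sizes = c(10, 200), seed = 1), "truncated")
})

test_that("cross-map skill is stable across library-draw seeds", {
  cl <- coupled_logistic()
  rhos <- vapply(1:10, function(s)
    ccm(cl$y, cl$x, E = 2, seed = s, n_samples = 50)$rho_max, numeric(1))
  expect_lt(stats::sd(rhos), 0.05)
})

test_that("surrogate test detects coupling and respects the null", {
  cl <- coupled_logistic()
  st <- surrogate_test(cl$y, cl$x, E = 2, seed = 1)
  expect_lte(st$p_value, 0.05)
  expect_error(surrogate_test(cl$x, cl$y, E = 2, n_surrogates = 0), "n_surrogates")
  # type-I behaviour on independent noise
  ps <- vapply(1:30, function(s) {
    set.seed(s + 500)
    a <- stats::rnorm(120); b <- stats::rnorm(120)
    surrogate_test(a, b, E = 2, n_surrogates = 60, seed = s)$p_value
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

# tri-trophic coupled map: fish forces zooplankton forces algae
tri_trophic <- function(n_keep = 200, burn = 100, seed = 1) {
  set.seed(seed)
  n <- n_keep + burn
  a <- z <- f <- numeric(n)
  a[1] <- 0.4; z[1] <- 0.3; f[1] <- 0.2
  for (t in seq_len(n - 1)) {
    a[t + 1] <- a[t] * (3.8 - 3.8 * a[t] - 0.35 * z[t])
    z[t + 1] <- z[t] * (3.6 - 3.6 * z[t] + 0.15 * a[t] - 0.35 * f[t])
    f[t + 1] <- f[t] * (3.7 - 3.7 * f[t] + 0.15 * z[t])
  }
  keep <- (burn + 1):n
  list(a = a[keep], z = z[keep], f = f[keep])
}

test_that("link inference recovers a known tri-trophic chain", {
  tt <- tri_trophic(seed = 1)
  sites <- sprintf("s%03d", seq_along(tt$a))
  abund <- tibble::tibble(
    site_id = rep(sites, 3),
    taxon_id = rep(c("alg1", "zoo1", "fish1"), each = length(sites)),
    value = c(tt$a, tt$z, tt$f))
  taxa <- tibble::tibble(taxon_id = c("alg1", "zoo1", "fish1"),
                         trophic_group = c("algae", "zooplankton", "fish"))
  order <- tibble::tibble(site_id = sites,
                          distance_km = rev(seq_along(sites)))
  links <- infer_links(abund, taxa, order, E_max = 3, n_samples = 50,
                       n_surrogates = 60, seed = 1)
  expect_true(any(links$consumer == "zoo1" & links$resource == "alg1"))
  expect_true(any(links$consumer == "fish1" & links$resource == "zoo1"))
  # orientation is rank-forced: no resource->consumer reversals can appear
  rank <- c(alg1 = 2, zoo1 = 3, fish1 = 4)
  expect_true(all(rank[links$consumer] > rank[links$resource]))
})

test_that("same-group non-fish pairs are never tested and type-I is controlled", {
  set.seed(3)
  n_sites <- 80
  sites <- sprintf("s%03d", seq_len(n_sites))
  taxa <- tibble::tibble(
    taxon_id = sprintf("t%02d", 1:10),
    trophic_group = rep(c("algae", "zooplankton"), each = 5))
  abund <- tibble::tibble(
    site_id = rep(sites, 10),
    taxon_id = rep(taxa$taxon_id, each = n_sites),
    value = stats::rlnorm(n_sites * 10))
  order <- tibble::tibble(site_id = sites, distance_km = rev(seq_len(n_sites)))
  links <- infer_links(abund, taxa, order, E_max = 3, n_samples = 30,
                       n_surrogates = 40, seed = 3)
  # only cross-group pairs are eligible: 5 * 5 unordered, both directions
  expect_equal(attr(links, "tested"), 50)
  # independent taxa: retained links within the binomial 99% bound at alpha
  expect_lte(nrow(links), stats::qbinom(0.99, 25, 0.05))
  # unknown trophic group is a metadata error
  bad <- taxa; bad$trophic_group[1] <- "virus"
  expect_error(infer_links(abund, bad, order), "unknown trophic")
})
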