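#' Generate a random dendritic river network
#'
#' Builds a random binary confluence tree: headwater reaches are merged
#' pairwise at random until a single outlet remains, giving 2n - 1 reaches
#' for n headwaters. Widths grow downstream with accumulated headwater
#' count following the hydraulic-geometry relation W = a_w * h^b_w
#' (log-normally perturbed), slopes decay downstream, and elevations
#' accumulate upstream from the outlet.
#'
#' @param n_headwaters Number of headwater reaches (>= 1).
#' @param mean_reach_length_m Mean reach length in metres.
#' @param seed Integer seed; identical seeds give identical networks.
#' @param params [hydraulic_params()] used for the width scaling.
#' @return A `reach_network` with 2 * n_headwaters - 1 reaches.
#' @export
make_network <- function(n_headwaters, mean_reach_length_m = 2000, seed = 1,
                         params = hydraulic_params()) {
  stopifnot(n_headwaters >= 1)
  set.seed(seed)
  n_total <- 2 * n_headwaters - 1
  ids <- sprintf("r%04d", seq_len(n_total))
  downstream <- rep(NA_character_, n_total)
  hw_count <- rep(1, n_total)
  active <- seq_len(n_headwaters)
  nxt <- n_headwaters + 1L
  while (length(active) > 1) {
    pick <- sample(length(active), 2)
    a <- active[pick[1]]; b <- active[pick[2]]
    downstream[c(a, b)] <- ids[nxt]
    hw_count[nxt] <- hw_count[a] + hw_count[b]
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  length_m <- stats::rlnorm(n_total, log(mean_reach_length_m) - 0.3^2 / 2, 0.3)
  width_m <- params$a_w * hw_count^params$b_w * stats::rlnorm(n_total, 0, 0.1)
  slope <- 0.05 * hw_count^(-0.4) * stats::rlnorm(n_total, 0, 0.2)
  source_area_m2 <- length_m * 400 * stats::rlnorm(n_total, 0, 0.3)
  net <- as_reach_network(tibble::tibble(
    reach_id = ids, downstream_id = downstream,
    length_m = length_m, width_m = width_m, slope = slope,
    elevation_m = 0, source_area_m2 = source_area_m2))
  elev <- numeric(n_total)
  for (i in rev(net$order_down)) {  # outlet first
    d <- net$down_idx[i]
    elev[i] <- if (is.na(d)) 100 else elev[d] + net$reaches$length_m[i] * net$reaches$slope[i]
  }
  net$reaches$elevation_m <- elev
  net
}

#' Generate per-reach environmental covariates
#'
#' Precipitation is a smooth, elevation-correlated field inside
#' `precip_range`; the human footprint follows the requested spatial
#' pattern, clipped to its defined \[0, 50\] range.
#'
#' @param net A `reach_network`.
#' @param precip_range Annual precipitation range, mm/yr.
#' @param hfp_pattern One of `"downstream_increasing"` (pressure peaks near
#'   the outlet), `"downstream_decreasing"`, `"uniform"`, `"random"`.
#' @param hfp_max Upper level of the footprint field (<= 50).
#' @param seed Integer seed.
#' @return Tibble `reach_id`, `precip`, `hfp`.
#' @export
make_covariates <- function(net, precip_range = c(300, 1000),
                            hfp_pattern = c("downstream_increasing",
                                            "downstream_decreasing",
                                            "uniform", "random"),
                            hfp_max = 40, seed = 1) {
  hfp_pattern <- match.arg(hfp_pattern)
  stopifnot(hfp_max <= 50, hfp_max >= 0)
  set.seed(seed)
  n <- nrow(net$reaches)
  elev <- net$reaches$elevation_m
  e01 <- if (diff(range(elev)) > 0) (elev - min(elev)) / diff(range(elev)) else rep(0.5, n)
  precip <- precip_range[1] + diff(precip_range) *
    pmin(pmax(e01 + stats::rnorm(n, 0, 0.05), 0), 1)
  dist <- distance_to_outlet(net)$distance_km
  d01 <- if (diff(range(dist)) > 0) (dist - min(dist)) / diff(range(dist)) else rep(0.5, n)
  hfp <- switch(hfp_pattern,
    downstream_increasing = hfp_max * (1 - d01) + stats::rnorm(n, 0, hfp_max * 0.05),
    downstream_decreasing = hfp_max * d01 + stats::rnorm(n, 0, hfp_max * 0.05),
    uniform = rep(hfp_max / 2, n),
    random = stats::runif(n, 0, hfp_max))
  tibble::tibble(reach_id = net$reaches$reach_id,
                 precip = precip,
                 hfp = pmin(pmax(hfp, 0), 50))
}

default_taxon_groups <- function(n_taxa) {
  groups <- c("fish", "zooplankton", "algae", "bacteria")
  stopifnot(all(names(n_taxa) %in% groups))
  guilds <- c("large invertebrate predator", "omnivore", "large herbivore",
              "small herbivore", "mixotroph")
  taxa <- purrr::imap_dfr(as.list(n_taxa), function(k, g) {
    tibble::tibble(
      taxon_id = sprintf("%s%02d", substr(g, 1, 3), seq_len(k)),
      trophic_group = g,
      guild = if (g == "fish") rep_len(guilds, k) else NA_character_)
  })
  taxa
}

#' Simulate a multi-trophic community with a known interaction matrix
#'
#' Discrete-time Ricker dynamics on every reach,
#' N_{t+1} = N_t exp(r (1 - N_t / K) + sum_j s_j N_j), with interaction
#' coefficients positive for a consumer's gain from its resources and
#' negative for a resource's loss to its consumers, plus downstream
#' advective dispersal of a fixed fraction of each population. The final
#' snapshot across reaches forms the spatially ordered "sites x taxa"
#' table the causal-inference stage consumes (a space-for-time design).
#'
#' @param net A `reach_network`.
#' @param n_taxa Named counts per group, e.g.
#'   `c(fish = 8, zooplankton = 8, algae = 8, bacteria = 8)`.
#' @param interaction_density Probability that an eligible cross-group
#'   pair (consumer group ranked above resource group) interacts.
#' @param strength_range Range of interaction magnitudes; the resource's
#'   loss coefficient is drawn from it, the consumer's gain is half that.
#' @param dispersal Fraction of each population advected to the
#'   downstream reach per step.
#' @param n_steps Simulation steps (burn-in included).
#' @param seed Integer seed.
#' @param covariates Optional [make_covariates()] table; when supplied,
#'   carrying capacity on each reach is reduced by
#'   `hfp_effect * (hfp / max(hfp)) * (trophic rank / 4)`, so anthropogenic
#'   pressure suppresses higher trophic levels (fish) hardest, floored at
#'   K = 0.05.
#' @param hfp_effect Strength of footprint suppression of K in \[0, 1\].
#' @return A list: `abundance` (long tibble `reach_id`, `taxon_id`,
#'   `value`), `taxa` metadata, `truth` (signed consumer -> resource
#'   interaction tibble).
#' @export
make_community <- function(net, n_taxa = c(fish = 8, zooplankton = 8,
                                           algae = 8, bacteria = 8),
                           interaction_density = 0.15,
                           strength_range = c(0.05, 0.15),
                           dispersal = 0.1, n_steps = 200, seed = 1,
                           covariates = NULL, hfp_effect = 0) {
  set.seed(seed)
  taxa <- default_taxon_groups(n_taxa)
  Tn <- nrow(taxa)
  rank <- trophic_rank(taxa$trophic_group)

  S <- matrix(0, Tn, Tn, dimnames = list(taxa$taxon_id, taxa$taxon_id))
  truth <- list()
  for (i in seq_len(Tn)) {
    for (j in seq_len(Tn)) {
      if (rank[i] > rank[j] && stats::runif(1) < interaction_density) {
        u <- stats::runif(1, strength_range[1], strength_range[2])
        S[i, j] <- u / 2   # consumer i gains from resource j
        S[j, i] <- -u      # resource j suffers from consumer i
        truth[[length(truth) + 1]] <- tibble::tibble(
          consumer = taxa$taxon_id[i], resource = taxa$taxon_id[j],
          strength = u)
      }
    }
  }
  truth <- if (length(truth) > 0) dplyr::bind_rows(truth) else
    tibble::tibble(consumer = character(), resource = character(),
                   strength = numeric())

  n <- nrow(net$reaches)
  r_i <- stats::runif(Tn, 2.6, 3.2)
  K <- matrix(1, n, Tn)
  if (!is.null(covariates) && hfp_effect > 0) {
    hfp <- covariates$hfp[match(net$reaches$reach_id, covariates$reach_id)]
    if (max(hfp) > 0) {
      K <- pmax(1 - hfp_effect * outer(hfp / max(hfp), rank / 4), 0.05)
    }
  }
  N <- matrix(stats::runif(n * Tn, 0.2, 1), n, Tn)
  down <- net$down_idx
  has_down <- !is.na(down)
  for (step in seq_len(n_steps)) {
    growth <- sweep(N / K, 2, -r_i, "*") + matrix(r_i, n, Tn, byrow = TRUE) +
      N %*% t(S)
    N <- N * exp(growth)
    if (any(!is.finite(N)) || any(N > 1e6)) {
      stop("community dynamics diverged; use smaller interaction strengths",
           call. = FALSE)
    }
    # downstream advective dispersal
    moved <- dispersal * N
    N <- N - moved
    inflow <- matrix(0, n, Tn)
    idx <- which(has_down)
    for (g in split(idx, down[idx])) {
      tgt <- down[g[1]]
      inflow[tgt, ] <- colSums(moved[g, , drop = FALSE])
    }
    N <- N + inflow
  }
  abundance <- tibble::tibble(
    reach_id = rep(net$reaches$reach_id, times = Tn),
    taxon_id = rep(taxa$taxon_id, each = n),
    value = as.vector(N))
  list(abundance = abundance, taxa = taxa, truth = truth,
       interaction_matrix = S)
}

#' Generate observed eDNA reads from a community under known transport
#'
#' Production on each reach is proportional to local abundance; the
#' forward transport model with the true decay constant produces
#' concentrations; observation sites are placed at random reaches
#' stratified by distance-to-outlet quartile; reads are Poisson draws of
#' `capture * concentration` after log-normal perturbation.
#'
#' @param abundance Long tibble `reach_id`, `taxon_id`, `value`.
#' @param net A `reach_network`.
#' @param hydraulics Table from [reach_hydraulics()].
#' @param tau_true True decay time constant, seconds.
#' @param capture Counts per unit concentration.
#' @param noise_sigma Log-normal observation noise SD.
#' @param n_sites Number of observation sites (<= number of reaches).
#' @param seed Integer seed.
#' @param base_rate Per-area production per unit abundance.
#' @return A list: `observed` (`site_id`, `taxon_id`, `value` reads),
#'   `sites` (`site_id`, `reach_id`), `concentration` (full field),
#'   `weights` (production weight matrix used), `truth` (tau, capture,
#'   base_rate).
#' @export
make_edna <- function(abundance, net, hydraulics, tau_true = 36000,
                      capture = 1e4, noise_sigma = 0.3, n_sites = 40,
                      seed = 1, base_rate = 1e-6) {
  n <- nrow(net$reaches)
  if (n_sites > n) stop("n_sites exceeds the number of reaches", call. = FALSE)
  set.seed(seed)
  wide <- tidyr::pivot_wider(abundance, id_cols = "reach_id",
                             names_from = "taxon_id", values_from = "value",
                             values_fill = 0)
  wide <- wide[match(net$reaches$reach_id, wide$reach_id), ]
  w <- as.matrix(wide[-1])
  w[is.na(w)] <- 0
  conc <- forward_concentration(net, hydraulics, tau_true, base_rate * w)

  dist <- distance_to_outlet(net)$distance_km
  quart <- cut(dist, stats::quantile(dist, 0:4 / 4), include.lowest = TRUE,
               labels = FALSE)
  per_q <- diff(round(seq(0, n_sites, length.out = 5)))
  site_rows <- unlist(lapply(1:4, function(q) {
    pool <- which(quart == q)
    sample(pool, min(per_q[q], length(pool)))
  }))
  extra <- n_sites - length(site_rows)
  if (extra > 0) {
    site_rows <- c(site_rows, sample(setdiff(seq_len(n), site_rows), extra))
  }
  sites <- tibble::tibble(site_id = sprintf("s%03d", seq_along(site_rows)),
                          reach_id = net$reaches$reach_id[site_rows])
  obs <- dplyr::inner_join(sites, conc, by = "reach_id")
  lam <- capture * obs$concentration *
    exp(stats::rnorm(nrow(obs), 0, noise_sigma))
  obs$value <- stats::rpois(nrow(obs), lam)
  list(observed = obs[, c("site_id", "taxon_id", "value")],
       sites = sites,
       concentration = conc,
       weights = w,
       truth = list(tau = tau_true, capture = capture, base_rate = base_rate,
                    noise_sigma = noise_sigma))
}

#' Fully parameterized synthetic basin scenarios
#'
#' `han_like` emulates a humid, low-pressure basin: ~1435 reaches, 77 taxa
#' (30 fish, 22 zooplankton, 14 algae, 11 bacteria), 44 observation sites,
#' precipitation near 1000 mm/yr, human footprint increasing downstream so
#' carrying capacity (and hence community richness) declines toward the
#' outlet. `wei_like` emulates an arid, high-pressure basin: ~931 reaches,
#' 63 taxa (26/14/14/9), 33 sites, precipitation near 300 mm/yr, footprint
#' decreasing downstream (pressure concentrated upstream) so richness
#' rises toward the outlet.
#'
#' @param name `"han_like"` or `"wei_like"`.
#' @param seed Integer seed; the whole scenario is reproducible from it.
#' @param n_headwaters Override the network size (useful for fast tests).
#' @param n_steps Community simulation steps.
#' @return A list of class `edna_scenario`: `net`, `covariates`, `taxa`,
#'   `community` truth, `abundance` (reach level), `observed` site reads,
#'   `sites`, `hydraulics`, transport `truth`, and the `params` used.
#' @export
scenario_preset <- function(name = c("han_like", "wei_like"), seed = 1,
                            n_headwaters = NULL, n_steps = 150) {
  name <- match.arg(name)
  p <- if (name == "han_like") {
    list(n_headwaters = 718,
         n_taxa = c(fish = 30, zooplankton = 22, algae = 14, bacteria = 11),
         n_sites = 44, precip_range = c(700, 1200),
         hfp_pattern = "downstream_increasing", hfp_max = 25,
         hfp_effect = 0.9)
  } else {
    list(n_headwaters = 466,
         n_taxa = c(fish = 26, zooplankton = 14, algae = 14, bacteria = 9),
         n_sites = 33, precip_range = c(250, 450),
         hfp_pattern = "downstream_decreasing", hfp_max = 40,
         hfp_effect = 0.9)
  }
  if (!is.null(n_headwaters)) p$n_headwaters <- n_headwaters
  hp <- hydraulic_params()
  net <- make_network(p$n_headwaters, seed = seed)
  cov <- make_covariates(net, precip_range = p$precip_range,
                         hfp_pattern = p$hfp_pattern, hfp_max = p$hfp_max,
                         seed = seed + 1)
  comm <- make_community(net, n_taxa = p$n_taxa, interaction_density = 0.15,
                         strength_range = c(0.05, 0.15), dispersal = 0.02,
                         n_steps = n_steps, seed = seed + 2,
                         covariates = cov, hfp_effect = p$hfp_effect)
  hyd <- reach_hydraulics(net, hp)
  edna <- make_edna(comm$abundance, net, hyd, tau_true = 3600,
                    capture = 200, noise_sigma = 0.3,
                    n_sites = min(p$n_sites, nrow(net$reaches)),
                    seed = seed + 3)
  structure(list(name = name, seed = seed,
                 net = net, covariates = cov, taxa = comm$taxa,
                 truth = comm$truth,
                 interaction_matrix = comm$interaction_matrix,
                 abundance = comm$abundance,
                 observed = edna$observed, sites = edna$sites,
                 hydraulics = hyd,
                 transport_truth = edna$truth,
                 params = p),
            class = "edna_scenario")
}

#' @export
print.edna_scenario <- function(x, ...) {
  cat("<edna_scenario> ", x$name, ": ", nrow(x$net$reaches), " reaches, ",
      nrow(x$taxa), " taxa, ", nrow(x$sites), " sites, seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Write a scenario to disk as the pipeline's CSV formats
#'
#' Writes `network.csv`, `covariates.csv`, `taxa.csv`, `sites.csv`,
#' `observed.csv`, and a `truth.json` sidecar with the generating
#' parameters and interaction truth.
#'
#' @param scenario An `edna_scenario`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(scenario$net, file.path(dir, "network.csv"))
  readr::write_csv(scenario$covariates, file.path(dir, "covariates.csv"))
  readr::write_csv(scenario$taxa, file.path(dir, "taxa.csv"))
  readr::write_csv(scenario$sites, file.path(dir, "sites.csv"))
  readr::write_csv(scenario$observed, file.path(dir, "observed.csv"))
  jsonlite::write_json(
    list(name = scenario$name, seed = scenario$seed,
         transport = scenario$transport_truth,
         interactions = scenario$truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
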