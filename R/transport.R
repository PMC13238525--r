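#' Advective travel time between two reaches
#'
#' Travel time is the sum of `length / velocity` over the flow path,
#' inclusive of both endpoints: eDNA shed anywhere in the source reach is
#' treated as traversing that reach's full length, and the destination
#' reach's own traversal is included. Under this convention the self-to-self
#' travel time of a reach is its own length over its velocity.
#'
#' @param net A `reach_network`.
#' @param hydraulics Per-reach hydraulics table from [reach_hydraulics()]
#'   (needs `reach_id`, `velocity`).
#' @param from,to Reach ids; `to` must lie on the downstream path of `from`.
#' @return Travel time in seconds.
#' @export
travel_time <- function(net, hydraulics, from, to) {
  path <- downstream_path(net, from)
  k <- match(as.character(to), path)
  if (is.na(k)) {
    stop("reach ", to, " is not downstream of ", from, call. = FALSE)
  }
  seg <- path[seq_len(k)]
  i <- resolve_reach(net, seg)
  v <- hydraulics$velocity[match(seg, hydraulics$reach_id)]
  sum(net$reaches$length_m[i] / v)
}

# core sweep: emission (n_reach x n_taxa) mass/time -> concentration matrix.
# F_j = D_j * (emission_j + sum_upstream F), C_j = F_j / Q_j, with
# D_j = exp(-(L_j / v_j) / tau) the decay across reach j itself.
forward_conc_matrix <- function(net, velocity, discharge, tau, emission) {
  emission <- as.matrix(emission)
  n <- nrow(net$reaches)
  stopifnot(nrow(emission) == n, tau > 0)
  decay <- exp(-(net$reaches$length_m / velocity) / tau)
  flux <- matrix(0, n, ncol(emission))
  for (i in net$order_down) {
    up <- net$children[[i]]
    inflow <- if (length(up) == 1) flux[up, ] else if (length(up) > 1)
      colSums(flux[up, , drop = FALSE]) else 0
    flux[i, ] <- decay[i] * (emission[i, ] + inflow)
  }
  sweep(flux, 1, discharge, "/")
}

#' Forward eDNA concentration field on a river network
#'
#' Steady-state advection with first-order decay and confluence dilution:
#' every reach emits eDNA at rate `production * source_area`, the emitted
#' mass flux decays exponentially with travel time (time constant `tau`)
#' as it is carried downstream, fluxes add at confluences, and
#' concentration at a reach is the accumulated decayed flux divided by that
#' reach's discharge. Computed in one upstream-to-downstream sweep (linear
#' in the number of reaches).
#'
#' @param net A `reach_network`.
#' @param hydraulics Table from [reach_hydraulics()] (`reach_id`,
#'   `discharge`, `velocity`).
#' @param tau Decay time constant in seconds (> 0).
#' @param production Per-area production rates: a data frame `reach_id`,
#'   `taxon_id`, `rate`, or a matrix (reaches x taxa, reach-table order),
#'   or a single vector for one taxon. Units mass / m^2 / s, >= 0.
#' @return A tibble `reach_id`, `taxon_id`, `concentration` (mass / m^3).
#' @export
forward_concentration <- function(net, hydraulics, tau, production) {
  h <- hydraulics[match(net$reaches$reach_id, hydraulics$reach_id), ]
  if (anyNA(h$discharge)) stop("discharge missing for some reaches", call. = FALSE)
  prod_m <- production_matrix(net, production)
  if (any(prod_m < 0)) stop("production rates must be >= 0", call. = FALSE)
  emission <- prod_m * net$reaches$source_area_m2
  conc <- forward_conc_matrix(net, h$velocity, h$discharge, tau, emission)
  tibble::tibble(
    reach_id = rep(net$reaches$reach_id, times = ncol(conc)),
    taxon_id = rep(colnames(prod_m), each = nrow(conc)),
    concentration = as.vector(conc))
}

production_matrix <- function(net, production) {
  n <- nrow(net$reaches)
  if (is.data.frame(production)) {
    stopifnot(all(c("reach_id", "taxon_id", "rate") %in% names(production)))
    taxa <- unique(as.character(production$taxon_id))
    m <- matrix(0, n, length(taxa), dimnames = list(net$reaches$reach_id, taxa))
    ri <- resolve_reach(net, production$reach_id)
    m[cbind(ri, match(as.character(production$taxon_id), taxa))] <- production$rate
    m
  } else {
    m <- as.matrix(production)
    stopifnot(nrow(m) == n)
    if (is.null(colnames(m))) colnames(m) <- paste0("taxon", seq_len(ncol(m)))
    m
  }
}

#' Expected read counts from a concentration field
#'
#' Reads are modelled as proportional to concentration with a single
#' capture/sequencing scaling coefficient.
#'
#' @param conc Concentration tibble from [forward_concentration()].
#' @param scaling Counts per unit concentration (>= 0).
#' @return The input tibble with an `expected_reads` column.
#' @export
predict_reads <- function(conc, scaling) {
  stopifnot(scaling >= 0)
  dplyr::mutate(conc, expected_reads = scaling * .data$concentration)
}

#' Presence/absence field from predicted concentrations
#'
#' A taxon is called present on a reach when its predicted concentration
#' reaches a per-taxon detection threshold. By default the threshold is the
#' minimum concentration predicted at any site where the taxon was actually
#' detected, i.e. the weakest signal that demonstrably produced a
#' detection.
#'
#' @param conc Tibble `reach_id`, `taxon_id`, `concentration`.
#' @param threshold Either a single number, a data frame `taxon_id`,
#'   `threshold`, or `NULL` to derive thresholds from `observed`/`sites`.
#' @param observed Site observations `site_id`, `taxon_id`, `value` (used
#'   when `threshold` is `NULL`).
#' @param sites Site-to-reach mapping `site_id`, `reach_id`.
#' @return Tibble `reach_id`, `taxon_id`, `concentration`, `presence`.
#' @export
presence_field <- function(conc, threshold = NULL, observed = NULL, sites = NULL) {
  if (is.null(threshold)) {
    if (is.null(observed) || is.null(sites)) {
      stop("supply either threshold or observed + sites", call. = FALSE)
    }
    det <- dplyr::filter(observed, .data$value > 0)
    det <- dplyr::inner_join(det, sites, by = "site_id")
    det <- dplyr::inner_join(det, conc, by = c("reach_id", "taxon_id"))
    thr <- dplyr::summarise(dplyr::group_by(det, .data$taxon_id),
                            threshold = min(.data$concentration), .groups = "drop")
  } else if (is.data.frame(threshold)) {
    thr <- threshold
  } else {
    thr <- tibble::tibble(taxon_id = unique(conc$taxon_id), threshold = threshold)
  }
  out <- dplyr::left_join(conc, thr, by = "taxon_id")
  # taxa never detected anywhere get an infinite threshold: absent everywhere
  out$threshold[is.na(out$threshold)] <- Inf
  out$presence <- out$concentration >= out$threshold
  dplyr::select(out, "reach_id", "taxon_id", "concentration", "presence")
}

# predicted concentrations at observation sites for unit per-taxon scale:
# U[s, t] for emission weights w[, t] * source_area, production scale 1
unit_site_conc <- function(net, h, tau, weights, site_rows) {
  emission <- weights * net$reaches$source_area_m2
  conc <- forward_conc_matrix(net, h$velocity, h$discharge, tau, emission)
  conc[site_rows, , drop = FALSE]
}

#' Calibrate decay and production parameters against observed eDNA data
#'
#' Fits the decay time constant `tau` (shared across taxa) and a per-taxon
#' production scale by minimising the sum of squared differences between
#' log-transformed predicted and observed values (pseudocount `epsilon` on
#' both sides). The optimisation is multi-start bounded quasi-Newton over
#' log tau, with the per-taxon log production scale profiled out at each
#' tau by one-dimensional minimisation (the forward map is linear in
#' production, so the conditional problem is smooth and univariate); the
#' best of `n_starts` starts is returned.
#'
#' @param net A `reach_network`.
#' @param hydraulics Table from [reach_hydraulics()].
#' @param observed Tibble `site_id`, `taxon_id`, `value` (reads or
#'   concentrations, >= 0).
#' @param sites Site-to-reach mapping `site_id`, `reach_id`.
#' @param weights Optional per-reach x per-taxon production weights (matrix
#'   in reach-table order with taxon columns, or data frame `reach_id`,
#'   `taxon_id`, `rate`); production for taxon t on reach i is
#'   `scale_t * weights[i, t]`. Default: constant weight 1 (spatially
#'   uniform production per taxon).
#' @param tau_bounds Bounds on tau in seconds.
#' @param n_starts Number of seeded starting points for log tau.
#' @param pseudocount Epsilon added inside the logs.
#' @param seed Integer seed for the start draws.
#' @return An object of class `edna_calibration`: fitted `tau`, per-taxon
#'   `production` scales, `objective`, per-observation `residuals`
#'   (log-scale), `degenerate` flag (underdetermined fits are reported, not
#'   hidden), and skipped all-zero taxa.
#' @export
calibrate <- function(net, hydraulics, observed, sites, weights = NULL,
                      tau_bounds = c(60, 1e7), n_starts = 10,
                      pseudocount = 1, seed = 1) {
  stopifnot(all(c("site_id", "taxon_id", "value") %in% names(observed)))
  if (any(observed$value < 0)) stop("observed values must be >= 0", call. = FALSE)
  sites <- validate_sites(net, sites)
  h <- hydraulics[match(net$reaches$reach_id, hydraulics$reach_id), ]

  obs <- tidyr::pivot_wider(observed, id_cols = "site_id",
                            names_from = "taxon_id", values_from = "value",
                            values_fill = 0)
  site_ids <- obs$site_id
  obs_m <- as.matrix(obs[-1])
  taxa <- colnames(obs_m)
  site_rows <- resolve_reach(net, sites$reach_id[match(site_ids, sites$site_id)])

  degenerate <- FALSE
  if (length(site_ids) < 5 || nrow(net$reaches) < 2) {
    warning("fewer than 5 observation sites (or a single-reach network): ",
            "tau and production are jointly underdetermined; fit flagged degenerate",
            call. = FALSE)
    degenerate <- TRUE
  }

  zero_taxa <- taxa[colSums(obs_m) == 0]
  if (length(zero_taxa) > 0) {
    warning("calibration skipped for all-zero taxa: ",
            paste(zero_taxa, collapse = ", "), call. = FALSE)
  }
  fit_taxa <- setdiff(taxa, zero_taxa)
  if (length(fit_taxa) == 0) stop("no taxon has nonzero observations", call. = FALSE)
  obs_fit <- obs_m[, fit_taxa, drop = FALSE]

  w <- calibration_weights(net, weights, fit_taxa)
  eps <- pseudocount
  log_obs <- log(obs_fit + eps)

  # conditional objective: best per-taxon log scale at fixed tau
  profile_at_tau <- function(log_tau) {
    u <- unit_site_conc(net, h, exp(log_tau), w, site_rows)
    scales <- numeric(length(fit_taxa))
    total <- 0
    for (t in seq_along(fit_taxa)) {
      ut <- u[, t]
      f <- function(lp) sum((log(exp(lp) * ut + eps) - log_obs[, t])^2)
      o <- stats::optimize(f, interval = c(-40, 40))
      scales[t] <- exp(o$minimum)
      total <- total + o$objective
    }
    list(objective = total, scales = scales)
  }

  set.seed(seed)
  starts <- stats::runif(n_starts, log(tau_bounds[1]), log(tau_bounds[2]))
  best <- NULL
  for (s in starts) {
    opt <- stats::optim(s, function(lt) profile_at_tau(lt)$objective,
                        method = "L-BFGS-B",
                        lower = log(tau_bounds[1]), upper = log(tau_bounds[2]))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  tau_hat <- exp(best$par)
  prof <- profile_at_tau(best$par)

  u <- unit_site_conc(net, h, tau_hat, w, site_rows)
  pred <- sweep(u, 2, prof$scales, "*")
  res <- tibble::tibble(
    site_id = rep(site_ids, times = length(fit_taxa)),
    taxon_id = rep(fit_taxa, each = length(site_ids)),
    observed = as.vector(obs_fit),
    predicted = as.vector(pred),
    residual = as.vector(log(pred + eps) - log_obs))

  structure(list(
    tau = tau_hat,
    production = tibble::tibble(taxon_id = fit_taxa, scale = prof$scales),
    objective = best$value,
    residuals = res,
    degenerate = degenerate,
    skipped_taxa = zero_taxa,
    tau_bounds = tau_bounds,
    pseudocount = eps,
    n_starts = n_starts,
    seed = seed,
    convergence = best$convergence),
    class = "edna_calibration")
}

calibration_weights <- function(net, weights, taxa) {
  n <- nrow(net$reaches)
  if (is.null(weights)) {
    return(matrix(1, n, length(taxa), dimnames = list(NULL, taxa)))
  }
  m <- production_matrix(net, weights)
  missing <- setdiff(taxa, colnames(m))
  if (length(missing) > 0) {
    stop("production weights missing for taxa: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m[, taxa, drop = FALSE]
}

#' @export
print.edna_calibration <- function(x, ...) {
  cat("<edna_calibration> tau =", signif(x$tau, 4), "s, objective =",
      signif(x$objective, 5), "\n")
  if (x$degenerate) cat("  ! degenerate (underdetermined) fit\n")
  if (length(x$skipped_taxa) > 0)
    cat("  skipped all-zero taxa:", length(x$skipped_taxa), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.edna_calibration <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "tau", taxon_id = NA_character_, estimate = x$tau),
    tibble::tibble(term = "production_scale", taxon_id = x$production$taxon_id,
                   estimate = x$production$scale))
}

#' @export
glance.edna_calibration <- function(x, ...) {
  tibble::tibble(tau = x$tau, objective = x$objective,
                 n_obs = nrow(x$residuals),
                 n_taxa = nrow(x$production),
                 degenerate = x$degenerate,
                 convergence = x$convergence)
}

#' Leave-one-out cross-validation of the transport calibration
#'
#' For each observation site the model is refitted without it and the
#' held-out site's values are predicted; reported per-site errors are root
#' mean squared log-scale residuals, and the summary statistic is the
#' Pearson correlation between held-out log predictions and log
#' observations over all site x taxon cells.
#'
#' @inheritParams calibrate
#' @param n_starts Starts per refit (smaller than a full calibration since
#'   each refit is warm territory).
#' @return An object of class `edna_loo`: `per_site` tibble, overall
#'   Pearson `r` and its p-value.
#' @export
loo_crossvalidate <- function(net, hydraulics, observed, sites, weights = NULL,
                              tau_bounds = c(60, 1e7), n_starts = 5,
                              pseudocount = 1, seed = 1) {
  site_ids <- unique(as.character(observed$site_id))
  if (length(site_ids) < 3) {
    stop("leave-one-out cross-validation needs at least 3 sites", call. = FALSE)
  }
  h <- hydraulics
  eps <- pseudocount
  held_pred <- list()
  for (s in site_ids) {
    train <- dplyr::filter(observed, .data$site_id != s)
    fit <- suppressWarnings(
      calibrate(net, h, train, sites, weights = weights, tau_bounds = tau_bounds,
                n_starts = n_starts, pseudocount = eps, seed = seed))
    test <- dplyr::filter(observed, .data$site_id == s,
                          .data$taxon_id %in% fit$production$taxon_id)
    if (nrow(test) == 0) next
    reach <- sites$reach_id[match(s, sites$site_id)]
    w <- calibration_weights(net, weights, fit$production$taxon_id)
    u <- unit_site_conc(net, h[match(net$reaches$reach_id, h$reach_id), ],
                        fit$tau, w, resolve_reach(net, reach))
    pred <- as.vector(u) * fit$production$scale
    held_pred[[s]] <- tibble::tibble(
      site_id = s, taxon_id = fit$production$taxon_id,
      observed = test$value[match(fit$production$taxon_id, test$taxon_id)],
      predicted = pred)
  }
  cells <- dplyr::bind_rows(held_pred)
  cells$observed[is.na(cells$observed)] <- 0
  lo <- log(cells$observed + eps)
  lp <- log(cells$predicted + eps)
  ct <- if (stats::sd(lo) > 0 && stats::sd(lp) > 0) {
    stats::cor.test(lp, lo)
  } else NULL
  per_site <- dplyr::summarise(
    dplyr::group_by(cells, .data$site_id),
    rmse_log = sqrt(mean((log(.data$predicted + eps) - log(.data$observed + eps))^2)),
    .groups = "drop")
  structure(list(per_site = per_site,
                 cells = cells,
                 r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
                 p_value = if (is.null(ct)) NA_real_ else ct$p.value),
            class = "edna_loo")
}

#' @export
print.edna_loo <- function(x, ...) {
  cat("<edna_loo> ", nrow(x$per_site), " sites, held-out Pearson r = ",
      signif(x$r, 3), " (p = ", format.pval(x$p_value), ")\n", sep = "")
  invisible(x)
}

#' Monte-Carlo perturbation of routed discharge
#'
#' Propagates discharge uncertainty by log-normal perturbation of the
#' routed discharge (and the velocity derived from it), one draw per call.
#'
#' @param hydraulics Table from [reach_hydraulics()].
#' @param sigma Log-normal standard deviation.
#' @param params Hydraulic parameters used to re-derive velocity.
#' @param width Channel widths in reach order (needed for velocity).
#' @return A perturbed hydraulics tibble.
#' @export
perturb_discharge <- function(hydraulics, sigma, width, params = hydraulic_params()) {
  q <- hydraulics$discharge * exp(stats::rnorm(nrow(hydraulics), 0, sigma))
  tibble::tibble(reach_id = hydraulics$reach_id,
                 local_discharge = hydraulics$local_discharge,
                 discharge = q,
                 velocity = velocity(q, width, params))
}
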