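#' Standardize an ordered abundance series
#'
#' Centre to mean 0 and scale to unit sample standard deviation (n - 1
#' denominator), the rescaling applied to every series before embedding so
#' that abundances measured on different scales are comparable.
#'
#' @param x Numeric vector with at least 2 finite values.
#' @return The standardized series.
#' @export
standardize_series <- function(x) {
  if (any(!is.finite(x))) stop("series contains non-finite values", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("constant series cannot be standardized", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Delay embedding of an ordered series
#'
#' Takens-style shadow attractor reconstruction: point t is
#' (x_t, x_{t-tau}, ..., x_{t-(E-1)tau}).
#'
#' @param x Numeric series.
#' @param E Embedding dimension (positive integer).
#' @param tau_lag Lag in steps (positive integer).
#' @return A matrix with `length(x) - (E - 1) * tau_lag` rows and `E`
#'   columns; row attribute `times` gives the series index of each point.
#' @export
embed_series <- function(x, E, tau_lag = 1) {
  stopifnot(E >= 1, tau_lag >= 1)
  n <- length(x)
  if (n < E * tau_lag + 2) {
    stop("series too short for E = ", E, ", tau_lag = ", tau_lag,
         " (need length >= ", E * tau_lag + 2, ")", call. = FALSE)
  }
  times <- seq((E - 1) * tau_lag + 1, n)
  pts <- vapply(seq_len(E) - 1L,
                function(lag) x[times - lag * tau_lag],
                numeric(length(times)))
  pts <- matrix(pts, ncol = E)
  attr(pts, "times") <- times
  pts
}

#' Simplex-projection self-prediction
#'
#' Leave-one-out nearest-neighbour forecasting on the delay-embedded
#' series: each embedded point predicts the series `tp` steps ahead from
#' its E + 1 nearest neighbours (itself excluded), weighted by
#' exp(-d/d_1). Skill is the Pearson correlation between predictions and
#' realized values.
#'
#' @param x Numeric series (standardized or raw).
#' @param E Embedding dimension.
#' @param tau_lag Lag in steps.
#' @param tp Prediction horizon in steps (default 1 = one-step-ahead).
#' @return A list: `predictions` tibble (`time`, `observed`, `predicted`)
#'   and `rho`.
#' @export
simplex_project <- function(x, E, tau_lag = 1, tp = 1) {
  pts <- embed_series(x, E, tau_lag)
  times <- attr(pts, "times")
  usable <- which(times + tp <= length(x))
  if (length(usable) < E + 2) {
    stop("not enough points for E = ", E, " (need at least ", E + 2, ")",
         call. = FALSE)
  }
  lib <- pts[usable, , drop = FALSE]
  target <- x[times[usable] + tp]
  pred <- cpp_simplex_predict(lib, target, lib, seq_along(usable))
  ok <- !is.na(pred)
  rho <- if (sum(ok) >= 2 && stats::sd(pred[ok]) > 0 && stats::sd(target[ok]) > 0)
    stats::cor(pred[ok], target[ok]) else NA_real_
  list(predictions = tibble::tibble(time = times[usable] + tp,
                                    observed = target, predicted = pred),
       rho = rho)
}

#' Choose an embedding dimension by simplex self-prediction
#'
#' Scans E = 1..`E_max`, keeping the E that maximizes leave-one-out
#' simplex forecast skill; ties go to the smallest E. The scan range is
#' truncated (with a warning) when the series is too short for large E.
#'
#' @param x Numeric series.
#' @param E_max Largest embedding dimension to consider.
#' @param tau_lag Lag in steps.
#' @return The selected E (integer); attribute `skill` holds the scanned
#'   rho values.
#' @export
select_E <- function(x, E_max = 10, tau_lag = 1) {
  feasible <- which(vapply(seq_len(E_max), function(E) {
    length(x) >= E * tau_lag + 2 &&
      (length(x) - (E - 1) * tau_lag - 1) >= E + 2
  }, logical(1)))
  if (length(feasible) < E_max) {
    warning("E range truncated to 1..", max(feasible),
            " (series too short for larger E)", call. = FALSE)
  }
  rhos <- vapply(feasible, function(E) {
    r <- simplex_project(x, E, tau_lag)$rho
    if (is.na(r)) -Inf else r
  }, numeric(1))
  E <- feasible[which.max(rhos)]  # which.max takes the first (smallest) on ties
  attr(E, "skill") <- stats::setNames(rhos, feasible)
  E
}

#' Convergent cross mapping between two ordered series
#'
#' Cross-maps the delay embedding of `x` to concurrent values of `y`
#' ("x cross-maps y": information about y recoverable from x's
#' reconstructed attractor, the signature that y forces x). For each
#' library size, `n_samples` random libraries are drawn without
#' replacement and the mean Pearson skill recorded; convergence requires
#' the skill to grow from the smallest to the largest library by more than
#' `delta_rho_min` and to exceed `rho_min` at the largest library (a skill
#' already above 0.9 at the smallest library counts as converged, since
#' ceiling-level skill leaves no room for growth).
#'
#' @param x,y Equal-length aligned numeric series (standardized
#'   internally).
#' @param E Embedding dimension for `x` (default: chosen by [select_E()]).
#' @param tau_lag Lag in steps.
#' @param lib_sizes Integer vector of library sizes; default an increasing
#'   grid from E + 4 to the number of embedded points. Sizes beyond the
#'   usable point count are truncated with a warning.
#' @param n_samples Random library draws per size.
#' @param seed Integer seed.
#' @param delta_rho_min,rho_min Convergence thresholds.
#' @return An object of class `ccm_result` with the skill curve,
#'   `rho_max`, and the `convergent` flag.
#' @export
ccm <- function(x, y, E = NULL, tau_lag = 1, lib_sizes = NULL,
                n_samples = 100, seed = 1,
                delta_rho_min = 0.1, rho_min = 0.2) {
  stopifnot(length(x) == length(y))
  x <- standardize_series(x)
  y <- standardize_series(y)
  if (is.null(E)) E <- as.integer(select_E(x, tau_lag = tau_lag))
  pts <- embed_series(x, E, tau_lag)
  times <- attr(pts, "times")
  yt <- y[times]
  P <- nrow(pts)
  if (is.null(lib_sizes)) {
    lib_sizes <- unique(round(seq(min(E + 4, P), P, length.out = 8)))
  }
  if (any(lib_sizes > P)) {
    warning("library sizes above ", P, " usable points truncated", call. = FALSE)
    lib_sizes <- lib_sizes[lib_sizes <= P]
  }
  lib_sizes <- sort(unique(pmax(lib_sizes, E + 2)))
  set.seed(seed)
  rhos <- cpp_ccm_rhos(pts, yt, as.integer(lib_sizes), as.integer(n_samples))
  curve <- tibble::tibble(
    lib_size = lib_sizes,
    rho = colMeans(rhos, na.rm = TRUE),
    rho_sd = apply(rhos, 2, stats::sd, na.rm = TRUE))
  rho_max <- curve$rho[nrow(curve)]
  rho_min_lib <- curve$rho[1]
  # skill already at ceiling at the smallest library cannot grow further;
  # treat near-perfect small-library skill as converged
  structure(list(
    skill_curve = curve,
    rho_max = rho_max,
    convergent = isTRUE(rho_max > rho_min &&
                          ((rho_max - rho_min_lib) > delta_rho_min ||
                             rho_min_lib > 0.9)),
    E = E, tau_lag = tau_lag, n_samples = n_samples, seed = seed,
    p_value = NA_real_,
    direction_label = "x cross-maps y (y forces x)"),
    class = "ccm_result")
}

#' @export
print.ccm_result <- function(x, ...) {
  cat("<ccm_result> E =", x$E, " rho(L_max) =", signif(x$rho_max, 3),
      " convergent:", x$convergent)
  if (!is.na(x$p_value)) cat("  p =", format.pval(x$p_value))
  cat("\n")
  invisible(x)
}

#' @export
tidy.ccm_result <- function(x, ...) x$skill_curve

#' @export
glance.ccm_result <- function(x, ...) {
  tibble::tibble(E = x$E, rho_max = x$rho_max, convergent = x$convergent,
                 p_value = x$p_value)
}

#' Surrogate significance test for cross-map skill
#'
#' Compares the observed full-library cross-map skill of x on y against a
#' null distribution built from cyclic-shift surrogates of y (shifts
#' preserve y's autocorrelation while destroying its alignment with x).
#' p = (1 + #\{rho_null >= rho_obs\}) / (1 + n_surrogates).
#'
#' @inheritParams ccm
#' @param n_surrogates Number of surrogate shifts (> 0).
#' @return A list: `p_value`, `rho_obs`, `rho_null`.
#' @export
surrogate_test <- function(x, y, E, tau_lag = 1, n_surrogates = 100, seed = 1) {
  if (n_surrogates <= 0) stop("n_surrogates must be > 0", call. = FALSE)
  stopifnot(length(x) == length(y))
  x <- standardize_series(x)
  y <- standardize_series(y)
  pts <- embed_series(x, E, tau_lag)
  times <- attr(pts, "times")
  n <- length(y)
  rho_obs <- cpp_xmap_full(pts, y[times])
  set.seed(seed)
  shifts <- sample(seq_len(n - 1), n_surrogates, replace = TRUE)
  rho_null <- vapply(shifts, function(s) {
    ys <- y[((seq_len(n) - 1 + s) %% n) + 1]
    cpp_xmap_full(pts, ys[times])
  }, numeric(1))
  p <- (1 + sum(rho_null >= rho_obs, na.rm = TRUE)) / (1 + n_surrogates)
  list(p_value = p, rho_obs = rho_obs, rho_null = rho_null)
}

trophic_rank <- function(group) {
  unname(c(fish = 4, zooplankton = 3, algae = 2, bacteria = 1)[group])
}

guild_rank <- function(guild) {
  ranks <- c("large invertebrate predator" = 5, "predator" = 5,
             "omnivore" = 4, "large herbivore" = 3, "small herbivore" = 2,
             "herbivore" = 2, "mixotroph" = 1)
  r <- unname(ranks[guild])
  r[is.na(guild) | !(guild %in% names(ranks))] <- NA_real_
  r
}

#' Infer directed trophic links from site-ordered abundance profiles
#'
#' Runs convergent cross mapping over taxon pairs from different trophic
#' groups (optionally also fish-fish pairs, oriented by feeding guild),
#' with sites ordered upstream to outlet so each taxon contributes one
#' spatially ordered profile. A pair yields a link when cross-mapping in
#' either direction is convergent and survives the cyclic-shift surrogate
#' test at level `alpha`; the link is stored consumer -> resource, with
#' the consumer the member of the higher trophic group.
#'
#' @param abund Long tibble `site_id`, `taxon_id`, `value`.
#' @param taxa Tibble `taxon_id`, `trophic_group` (one of fish,
#'   zooplankton, algae, bacteria), optional `guild`.
#' @param site_order Tibble `site_id`, `distance_km` (flow distance to the
#'   outlet); sites are ordered by decreasing distance.
#' @param E_max,tau_lag,lib_sizes,n_samples Passed to [ccm()]/[select_E()].
#' @param alpha Significance level for the surrogate test.
#' @param delta_rho_min,rho_min Convergence thresholds.
#' @param n_surrogates Surrogates per tested direction.
#' @param include_fish_fish Also test fish-fish (intra-trophic) pairs.
#' @param seed Integer seed.
#' @return A tibble of retained links: `consumer`, `resource`, `rho_max`,
#'   `convergent`, `p_value`, `E`, `direction`; attribute `tested` gives
#'   the number of ordered pairs evaluated.
#' @export
infer_links <- function(abund, taxa, site_order,
                        E_max = 6, tau_lag = 1, lib_sizes = NULL,
                        n_samples = 100, alpha = 0.05,
                        delta_rho_min = 0.1, rho_min = 0.2,
                        n_surrogates = 100, include_fish_fish = TRUE,
                        seed = 1) {
  stopifnot(all(c("taxon_id", "trophic_group") %in% names(taxa)))
  unknown <- setdiff(unique(taxa$trophic_group),
                     c("fish", "zooplankton", "algae", "bacteria"))
  if (length(unknown) > 0) {
    stop("unknown trophic group(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ord <- site_order[order(-site_order$distance_km), ]
  wide <- tidyr::pivot_wider(abund, id_cols = "site_id",
                             names_from = "taxon_id", values_from = "value",
                             values_fill = 0)
  wide <- wide[match(ord$site_id, wide$site_id), ]
  wide <- wide[!is.na(wide$site_id), ]
  ids <- intersect(names(wide)[-1], taxa$taxon_id)
  series <- lapply(ids, function(t) {
    v <- wide[[t]]
    if (stats::sd(v) == 0) return(NULL)
    standardize_series(v)
  })
  names(series) <- ids
  keep <- !vapply(series, is.null, logical(1))
  if (any(!keep)) {
    warning("dropping constant series: ", paste(ids[!keep], collapse = ", "),
            call. = FALSE)
  }
  ids <- ids[keep]
  series <- series[keep]
  meta <- taxa[match(ids, taxa$taxon_id), ]
  rank <- trophic_rank(meta$trophic_group)
  grank <- if ("guild" %in% names(meta)) guild_rank(meta$guild) else
    rep(NA_real_, length(ids))

  # embedding dimension cached per source taxon
  Es <- vapply(series, function(s) {
    suppressWarnings(as.integer(select_E(s, E_max = E_max, tau_lag = tau_lag)))
  }, integer(1))

  pairs <- expand.grid(a = seq_along(ids), b = seq_along(ids))
  pairs <- pairs[pairs$a < pairs$b, ]
  cross <- meta$trophic_group[pairs$a] != meta$trophic_group[pairs$b]
  fishfish <- include_fish_fish &
    meta$trophic_group[pairs$a] == "fish" &
    meta$trophic_group[pairs$b] == "fish" &
    !is.na(grank[pairs$a]) & !is.na(grank[pairs$b]) &
    grank[pairs$a] != grank[pairs$b]
  pairs <- pairs[cross | fishfish, ]

  n_tested <- 0L
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$a[k]; b <- pairs$b[k]
    # consumer/resource orientation by trophic (then guild) rank
    if (rank[a] != rank[b]) {
      cons <- if (rank[a] > rank[b]) a else b
    } else if (!is.na(grank[a]) && !is.na(grank[b]) && grank[a] != grank[b]) {
      cons <- if (grank[a] > grank[b]) a else b
    } else next
    resr <- if (cons == a) b else a

    hit <- NULL
    for (dir in list(c(a, b), c(b, a))) {
      n_tested <- n_tested + 1L
      r <- ccm(series[[dir[1]]], series[[dir[2]]], E = Es[dir[1]],
               tau_lag = tau_lag, lib_sizes = lib_sizes,
               n_samples = n_samples, seed = seed,
               delta_rho_min = delta_rho_min, rho_min = rho_min)
      if (!r$convergent) next
      st <- surrogate_test(series[[dir[1]]], series[[dir[2]]], E = Es[dir[1]],
                           tau_lag = tau_lag, n_surrogates = n_surrogates,
                           seed = seed)
      if (st$p_value <= alpha &&
          (is.null(hit) || r$rho_max > hit$rho_max)) {
        hit <- tibble::tibble(
          consumer = ids[cons], resource = ids[resr],
          rho_max = r$rho_max, convergent = TRUE, p_value = st$p_value,
          E = Es[dir[1]],
          direction = paste(ids[dir[1]], "xmap", ids[dir[2]]))
      }
    }
    out[[k]] <- hit
  }
  links <- dplyr::bind_rows(out)
  if (nrow(links) == 0) {
    links <- tibble::tibble(consumer = character(), resource = character(),
                            rho_max = numeric(), convergent = logical(),
                            p_value = numeric(), E = integer(),
                            direction = character())
  }
  attr(links, "tested") <- n_tested
  links
}
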