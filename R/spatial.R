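#' Map food-web metrics over every reach of the network
#'
#' For each reach, the taxa predicted present there induce a local web
#' from the metaweb and its structure metrics are computed. Reaches whose
#' local web is degenerate (fewer than 2 taxa) carry missing metrics; their
#' count is reported in a message and in the `n_degenerate` attribute.
#'
#' @param net A `reach_network`.
#' @param metaweb A `food_web`.
#' @param presence Tibble `reach_id`, `taxon_id`, `presence` (logical),
#'   e.g. from [presence_field()].
#' @param covariates Optional per-reach covariates joined onto the result
#'   (`reach_id` plus any columns).
#' @return A `reach_metrics_field` tibble: one row per reach with
#'   `distance_km`, S, L, link_density, connectance, trophic_length,
#'   community_omnivory and any covariates.
#' @export
map_metrics <- function(net, metaweb, presence, covariates = NULL) {
  stopifnot(all(c("reach_id", "taxon_id", "presence") %in% names(presence)))
  dist <- distance_to_outlet(net)
  pres <- dplyr::filter(presence, .data$presence)
  by_reach <- split(pres$taxon_id, pres$reach_id)
  rows <- lapply(net$reaches$reach_id, function(r) {
    web_metrics(local_web(metaweb, by_reach[[r]] %||% character()))
  })
  out <- dplyr::bind_cols(
    tibble::tibble(reach_id = net$reaches$reach_id,
                   distance_km = dist$distance_km),
    dplyr::bind_rows(rows))
  n_deg <- sum(is.na(out$link_density))
  if (n_deg > 0) {
    message(n_deg, " of ", nrow(out),
            " reaches have degenerate (< 2 taxa) local webs; metrics set to NA")
  }
  if (!is.null(covariates)) {
    out <- dplyr::left_join(out, tibble::as_tibble(covariates), by = "reach_id")
  }
  attr(out, "n_degenerate") <- n_deg
  class(out) <- c("reach_metrics_field", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Upstream-to-outlet gradient of a food-web metric
#'
#' Gaussian identity-link GLM (ordinary least squares) of the metric on
#' flow distance to the outlet, plus the Pearson correlation with its
#' two-sided t-test. Reaches with missing metrics (degenerate webs) are
#' excluded rather than zero-filled. A constant metric has an undefined
#' correlation and is reported as missing with a note.
#'
#' @param field A data frame with `distance_km` and the metric column.
#' @param metric Name of the metric column (string).
#' @return One-row tibble `metric`, `slope`, `intercept`, `r`, `p`, `n`,
#'   `note`.
#' @export
gradient_trend <- function(field, metric) {
  d <- field[stats::complete.cases(field[, c("distance_km", metric)]), ]
  y <- d[[metric]]
  x <- d$distance_km
  if (length(y) < 3 || stats::sd(y) == 0 || stats::sd(x) == 0) {
    return(tibble::tibble(metric = metric, slope = if (length(y) >= 2 &&
             stats::sd(x) > 0) 0 else NA_real_,
           intercept = NA_real_, r = NA_real_, p = NA_real_,
           n = length(y), note = "constant or insufficient data"))
  }
  fit <- stats::glm(y ~ x, family = stats::gaussian())
  ct <- stats::cor.test(x, y)
  tibble::tibble(metric = metric,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = unname(ct$estimate), p = ct$p.value,
                 n = length(y), note = NA_character_)
}

#' Contrast a metric between low- and high-pressure groups
#'
#' Splits observations at the median human footprint and compares the
#' metric between groups with a two-sided Mann-Whitney (Wilcoxon rank-sum)
#' test.
#'
#' @param data Data frame with the metric and footprint columns.
#' @param metric Metric column name (string).
#' @param hfp Footprint column name (default `"hfp"`).
#' @return One-row tibble with group medians, sizes, W statistic and p.
#' @export
pressure_contrast <- function(data, metric, hfp = "hfp") {
  d <- data[stats::complete.cases(data[, c(metric, hfp)]), ]
  grp <- ifelse(d[[hfp]] > stats::median(d[[hfp]]), "high", "low")
  n_low <- sum(grp == "low"); n_high <- sum(grp == "high")
  if (n_low < 3 || n_high < 3) {
    stop("need at least 3 observations per pressure group (got ",
         n_low, " low, ", n_high, " high)", call. = FALSE)
  }
  y_low <- d[[metric]][grp == "low"]
  y_high <- d[[metric]][grp == "high"]
  wt <- suppressWarnings(stats::wilcox.test(y_high, y_low))
  tibble::tibble(metric = metric,
                 median_low = stats::median(y_low),
                 median_high = stats::median(y_high),
                 n_low = n_low, n_high = n_high,
                 W = unname(wt$statistic), p = wt$p.value)
}

#' Spearman correlations between metrics and environmental covariates
#'
#' Pairwise Spearman rank correlations with tie-corrected p-values
#' (missing values deleted pairwise).
#'
#' @param data Data frame holding both sets of columns.
#' @param metrics Character vector of metric column names.
#' @param covariates Character vector of covariate column names.
#' @return Tibble `metric`, `covariate`, `rho`, `p`, `n`.
#' @export
env_correlations <- function(data, metrics, covariates) {
  grid <- expand.grid(metric = metrics, covariate = covariates,
                      stringsAsFactors = FALSE)
  purrr::pmap_dfr(grid, function(metric, covariate) {
    d <- data[stats::complete.cases(data[, c(metric, covariate)]), ]
    if (nrow(d) < 3 || stats::sd(d[[metric]]) == 0 ||
        stats::sd(d[[covariate]]) == 0) {
      return(tibble::tibble(metric = metric, covariate = covariate,
                            rho = NA_real_, p = NA_real_, n = nrow(d)))
    }
    ct <- suppressWarnings(
      stats::cor.test(d[[metric]], d[[covariate]], method = "spearman"))
    tibble::tibble(metric = metric, covariate = covariate,
                   rho = unname(ct$estimate), p = ct$p.value, n = nrow(d))
  })
}
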