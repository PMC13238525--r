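#' Default pipeline configuration
#'
#' Returns the full nested configuration with documented defaults; user
#' configurations are validated strictly against this template (unknown
#' keys are rejected, since silent typos are the main reproducibility
#' hazard).
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    output_dir = NULL,
    input = list(network = NULL, abundance = NULL, sites = NULL,
                 covariates = NULL, taxa = NULL,
                 preset = NULL, preset_headwaters = NULL),
    hydrology = list(a_w = 7.2, b_w = 0.5, a_d = 0.27, b_d = 0.39,
                     gamma = 0, s_min = 1e-4),
    foodweb = list(min_occupancy = 0.5),
    edm = list(E_max = 6, tau_lag = 1, lib_sizes = NULL, n_samples = 30,
               alpha = 0.05, delta_rho_min = 0.1, rho_min = 0.2,
               n_surrogates = 60, include_fish_fish = TRUE),
    transport = list(tau_bounds = c(60, 1e7), n_starts = 6, pseudocount = 1,
                     production_by_abundance = TRUE),
    plspm = list(enabled = FALSE, n_boot = 200),
    spatial = list(metrics = c("L", "link_density", "connectance",
                               "trophic_length", "community_omnivory")))
}

merge_config <- function(user, template = default_config(), path = "") {
  if (is.null(user)) return(template)
  unknown <- setdiff(names(user), names(template))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]]))) {
      template[[k]] <- merge_config(user[[k]], template[[k]],
                                    path = paste0(path, k, "$"))
    } else {
      template[[k]] <- user[[k]]
    }
  }
  template
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path.
#' @return A validated configuration list.
#' @export
read_config <- function(path) {
  merge_config(yaml::read_yaml(path))
}

load_pipeline_inputs <- function(cfg) {
  inp <- cfg$input
  if (!is.null(inp$preset)) {
    sc <- scenario_preset(inp$preset, seed = cfg$seed,
                          n_headwaters = inp$preset_headwaters)
    return(list(net = sc$net, abundance = sc$observed, sites = sc$sites,
                covariates = sc$covariates, taxa = sc$taxa, scenario = sc))
  }
  for (f in c("network", "abundance", "sites", "taxa")) {
    if (is.null(inp[[f]])) stop("config input$", f, " is required", call. = FALSE)
    if (!file.exists(inp[[f]])) stop("input file not found: ", inp[[f]],
                                     call. = FALSE)
  }
  net <- read_network(inp$network)
  abund <- readr::read_csv(inp$abundance, col_types = readr::cols(
    site_id = readr::col_character(), taxon_id = readr::col_character(),
    value = readr::col_double()))
  sites <- readr::read_csv(inp$sites, col_types = readr::cols(
    .default = readr::col_character()))
  taxa <- readr::read_csv(inp$taxa, col_types = readr::cols(
    .default = readr::col_character()))
  cov <- if (!is.null(inp$covariates)) {
    readr::read_csv(inp$covariates, col_types = readr::cols(
      reach_id = readr::col_character(), .default = readr::col_double()))
  }
  list(net = net, abundance = abund, sites = sites, covariates = cov,
       taxa = taxa, scenario = NULL)
}

#' Run the full inference pipeline
#'
#' Executes occupancy filtering, CCM link inference, metaweb assembly and
#' metrics, transport calibration, network-wide presence prediction,
#' per-reach metric mapping, and gradient / pressure / correlation
#' statistics from a single configuration; optionally a PLS path model on
#' the site table. All outputs are returned as a result bundle and, when
#' `output_dir` is set, written as CSVs plus a machine-readable manifest.
#' Reruns of an identical configuration give identical numeric outputs.
#'
#' @param config A configuration list (merged over [default_config()]) or
#'   a YAML path.
#' @return A list of class `riverweb_run` with every stage's outputs.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (is.character(config)) read_config(config) else merge_config(config)
  t0 <- proc.time()["elapsed"]
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf("[%7.1fs] %s", proc.time()["elapsed"] - t0, paste0(...))
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  note("loading inputs")
  inputs <- load_pipeline_inputs(cfg)
  net <- inputs$net
  sites <- validate_sites(net, inputs$sites)
  hyd <- do.call(hydraulic_params, cfg$hydrology)
  hydraulics <- reach_hydraulics(net, hyd)

  note("occupancy filtering")
  filtered <- filter_taxa(inputs$abundance, inputs$taxa,
                          min_occupancy = cfg$foodweb$min_occupancy)
  taxa_kept <- inputs$taxa[inputs$taxa$taxon_id %in%
                             unique(filtered$taxon_id), ]

  note("CCM link inference over ", nrow(taxa_kept), " taxa")
  dist <- distance_to_outlet(net)
  site_order <- dplyr::inner_join(sites, dist, by = "reach_id")
  links <- infer_links(filtered, taxa_kept,
                       site_order[, c("site_id", "distance_km")],
                       E_max = cfg$edm$E_max, tau_lag = cfg$edm$tau_lag,
                       lib_sizes = cfg$edm$lib_sizes,
                       n_samples = cfg$edm$n_samples,
                       alpha = cfg$edm$alpha,
                       delta_rho_min = cfg$edm$delta_rho_min,
                       rho_min = cfg$edm$rho_min,
                       n_surrogates = cfg$edm$n_surrogates,
                       include_fish_fish = cfg$edm$include_fish_fish,
                       seed = cfg$seed)

  note("metaweb assembly: ", nrow(links), " links")
  metaweb <- build_metaweb(links[, c("consumer", "resource")], taxa_kept)
  metaweb_metrics <- web_metrics(metaweb)

  note("transport calibration")
  weights <- NULL
  if (isTRUE(cfg$transport$production_by_abundance)) {
    # site-level mean detections interpolated as spatially uniform weights
    # unless reach-level abundance is available (preset scenarios)
    if (!is.null(inputs$scenario)) {
      wide <- tidyr::pivot_wider(inputs$scenario$abundance,
                                 id_cols = "reach_id",
                                 names_from = "taxon_id",
                                 values_from = "value", values_fill = 0)
      wide <- wide[match(net$reaches$reach_id, wide$reach_id), ]
      weights <- as.matrix(wide[-1])
    }
  }
  cal <- suppressWarnings(
    calibrate(net, hydraulics, filtered, sites, weights = weights,
              tau_bounds = cfg$transport$tau_bounds,
              n_starts = cfg$transport$n_starts,
              pseudocount = cfg$transport$pseudocount, seed = cfg$seed))

  note("predicting presence field (tau = ", signif(cal$tau, 3), " s)")
  w_fit <- calibration_weights(net, weights, cal$production$taxon_id)
  prod_rates <- sweep(w_fit, 2, cal$production$scale, "*")
  conc <- forward_concentration(net, hydraulics, cal$tau, prod_rates)
  presence <- presence_field(conc, observed = filtered, sites = sites)

  note("mapping per-reach metrics")
  field <- suppressMessages(
    map_metrics(net, metaweb, presence, covariates = inputs$covariates))
  field$discharge <- hydraulics$discharge[match(field$reach_id,
                                                hydraulics$reach_id)]

  note("gradient, pressure and correlation statistics")
  metric_cols <- intersect(cfg$spatial$metrics, names(field))
  gradients <- dplyr::bind_rows(lapply(metric_cols, gradient_trend,
                                       field = field))
  covar_cols <- intersect(c("precip", "hfp", "discharge"), names(field))
  contrasts <- if ("hfp" %in% names(field)) {
    dplyr::bind_rows(lapply(metric_cols, function(m) {
      tryCatch(pressure_contrast(field, m), error = function(e) NULL)
    }))
  }
  correlations <- if (length(covar_cols) > 0) {
    env_correlations(field, metric_cols, covar_cols)
  }

  site_table <- build_site_table(net, metaweb, filtered, taxa_kept, sites,
                                 inputs$covariates, hydraulics)

  plspm_out <- NULL
  if (isTRUE(cfg$plspm$enabled)) {
    note("PLS path model")
    plspm_out <- tryCatch(
      run_site_plspm(site_table, n_boot = cfg$plspm$n_boot, seed = cfg$seed),
      error = function(e) {
        note("PLS-PM skipped: ", conditionMessage(e))
        NULL
      })
  }

  note("done")
  bundle <- structure(list(
    config = cfg,
    links = links,
    metaweb = metaweb,
    metaweb_metrics = metaweb_metrics,
    calibration = cal,
    presence = presence,
    field = field,
    gradients = gradients,
    contrasts = contrasts,
    correlations = correlations,
    site_table = site_table,
    plspm = plspm_out,
    log = log_lines),
    class = "riverweb_run")

  if (!is.null(cfg$output_dir)) write_bundle(bundle, cfg$output_dir)
  invisible(bundle)
}

# per-site table: local-web metrics from site detections + covariates
build_site_table <- function(net, metaweb, filtered, taxa, sites,
                             covariates, hydraulics) {
  det <- dplyr::filter(filtered, .data$value > 0)
  dist <- distance_to_outlet(net)
  rows <- lapply(sites$site_id, function(s) {
    present <- det$taxon_id[det$site_id == s]
    m <- web_metrics(local_web(metaweb, present))
    grp <- taxa$trophic_group[match(present, taxa$taxon_id)]
    dplyr::bind_cols(tibble::tibble(
      site_id = s,
      fish_richness = sum(grp == "fish", na.rm = TRUE),
      zoo_richness = sum(grp == "zooplankton", na.rm = TRUE),
      algae_richness = sum(grp == "algae", na.rm = TRUE)), m)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::left_join(out, sites, by = "site_id")
  out <- dplyr::left_join(out, dist, by = "reach_id")
  out$discharge <- hydraulics$discharge[match(out$reach_id,
                                              hydraulics$reach_id)]
  if (!is.null(covariates)) {
    out <- dplyr::left_join(out, tibble::as_tibble(covariates), by = "reach_id")
  }
  out
}

run_site_plspm <- function(site_table, n_boot = 200, seed = 1) {
  blocks <- list(climate = "precip", hydrology = "discharge",
                 human = "hfp", fish_div = "fish_richness",
                 zoo_div = "zoo_richness", algal_div = "algae_richness",
                 complexity = c("L", "link_density"))
  blocks <- blocks[vapply(blocks, function(b)
    all(b %in% names(site_table)), logical(1))]
  inner <- tibble::tibble(
    from = c("climate", "hydrology", "human", "human", "human",
             "fish_div", "zoo_div", "algal_div"),
    to = c("human", "human", "fish_div", "zoo_div", "algal_div",
           "complexity", "complexity", "complexity"))
  inner <- inner[inner$from %in% names(blocks) & inner$to %in% names(blocks), ]
  spec <- path_spec(blocks, inner)
  fit <- plspm_fit(site_table, spec)
  boot <- plspm_bootstrap(site_table, spec, n_boot = n_boot, seed = seed)
  list(spec = spec, fit = fit, effects = path_effects(fit), bootstrap = boot)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    if (!is.null(x) && nrow(x) > 0) {
      readr::write_csv(x, file.path(dir, paste0(name, ".csv")))
    }
  }
  wr(bundle$links, "links")
  wr(bundle$metaweb_metrics, "metaweb_metrics")
  wr(tidy(bundle$calibration), "calibration")
  wr(bundle$presence, "presence")
  wr(bundle$field, "reach_metrics")
  wr(bundle$gradients, "gradients")
  wr(bundle$contrasts, "pressure_contrasts")
  wr(bundle$correlations, "env_correlations")
  wr(bundle$site_table, "site_metrics")
  if (!is.null(bundle$plspm)) {
    wr(tidy(bundle$plspm$fit), "plspm")
    wr(bundle$plspm$bootstrap, "plspm_bootstrap")
  }
  cfg <- bundle$config
  cfg$output_dir <- NULL  # manifest describes the computation, not the paths
  manifest <- list(
    package = "riverweb",
    version = as.character(utils::packageVersion("riverweb")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg),
    config = cfg)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(bundle$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.riverweb_run <- function(x, ...) {
  cat("<riverweb_run> metaweb S =", x$metaweb_metrics$S,
      "L =", x$metaweb_metrics$L,
      "| tau =", signif(x$calibration$tau, 3), "s\n")
  invisible(x)
}

#' Contrast two basin result bundles
#'
#' Tabulates metaweb metrics side by side with percent differences of the
#' complexity metrics, and the upstream-to-outlet gradient slopes and
#' correlations with their signs.
#'
#' @param bundle_a,bundle_b `riverweb_run` objects.
#' @param names Labels for the two bundles.
#' @return A list of class `basin_contrast`: `metrics` and `gradients`
#'   tibbles.
#' @export
compare_basins <- function(bundle_a, bundle_b, names = c("a", "b")) {
  ma <- bundle_a$metaweb_metrics
  mb <- bundle_b$metaweb_metrics
  shared <- intersect(names(ma), names(mb))
  if (length(shared) == 0) stop("incompatible metric sets", call. = FALSE)
  metrics <- tibble::tibble(
    metric = shared,
    a = as.numeric(ma[1, shared]),
    b = as.numeric(mb[1, shared]))
  metrics$pct_diff <- (metrics$a - metrics$b) / metrics$b * 100
  names(metrics)[2:3] <- names

  ga <- bundle_a$gradients
  gb <- bundle_b$gradients
  common <- intersect(ga$metric, gb$metric)
  if (length(common) == 0) stop("incompatible gradient metric sets", call. = FALSE)
  gradients <- dplyr::inner_join(
    ga[, c("metric", "slope", "r", "p")],
    gb[, c("metric", "slope", "r", "p")],
    by = "metric", suffix = paste0("_", names))
  gradients$opposite_sign <-
    sign(gradients[[paste0("slope_", names[1])]]) *
    sign(gradients[[paste0("slope_", names[2])]]) < 0
  structure(list(metrics = metrics, gradients = gradients, names = names),
            class = "basin_contrast")
}

#' @export
print.basin_contrast <- function(x, ...) {
  cat("<basin_contrast>", x$names[1], "vs", x$names[2], "\n")
  print(x$metrics)
  print(x$gradients)
  invisible(x)
}
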