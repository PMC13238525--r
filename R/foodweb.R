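#' Occupancy filtering of a site-by-taxon abundance table
#'
#' Retains taxa detected (value > 0) at strictly more than
#' `min_occupancy` of the sites — the standard quality filter against
#' sporadic false-positive eDNA detections — and checks that at least two
#' trophic groups survive, since a single-level table cannot support a
#' food web.
#'
#' @param abund Long tibble `site_id`, `taxon_id`, `value` (>= 0). Sites
#'   where a taxon has no row count as non-detections.
#' @param taxa Tibble `taxon_id`, `trophic_group`.
#' @param min_occupancy Occupancy fraction that must be strictly exceeded
#'   (default 0.5: more than half the sites).
#' @return The filtered abundance tibble; attribute `occupancy` holds the
#'   per-taxon detection fractions.
#' @export
filter_taxa <- function(abund, taxa, min_occupancy = 0.5) {
  stopifnot(all(c("site_id", "taxon_id", "value") %in% names(abund)))
  if (any(abund$value < 0)) stop("abundances must be >= 0", call. = FALSE)
  n_sites <- dplyr::n_distinct(abund$site_id)
  occ <- dplyr::summarise(dplyr::group_by(abund, .data$taxon_id),
                          occupancy = sum(.data$value > 0) / n_sites,
                          .groups = "drop")
  kept <- occ$taxon_id[occ$occupancy > min_occupancy]
  out <- dplyr::filter(abund, .data$taxon_id %in% kept)
  groups <- unique(taxa$trophic_group[taxa$taxon_id %in% kept])
  if (length(groups) < 2) {
    stop("occupancy filtering left fewer than 2 trophic groups; ",
         "a food web needs at least 2 trophic levels", call. = FALSE)
  }
  attr(out, "occupancy") <- occ
  out
}

#' Assemble a metaweb from inferred links
#'
#' @param links Data frame with columns `consumer`, `resource` (directed
#'   consumer -> resource links); duplicates are collapsed, self-links
#'   rejected.
#' @param taxa Tibble `taxon_id`, optionally `trophic_group`; all taxa are
#'   retained as nodes (isolated taxa count towards S).
#' @return An object of class `food_web` with `nodes` and `links` tibbles.
#' @export
build_metaweb <- function(links, taxa) {
  taxa <- tibble::as_tibble(taxa)
  stopifnot("taxon_id" %in% names(taxa))
  if (anyDuplicated(taxa$taxon_id)) stop("duplicate taxon_id", call. = FALSE)
  links <- tibble::as_tibble(links)
  if (nrow(links) > 0) {
    stopifnot(all(c("consumer", "resource") %in% names(links)))
    if (any(links$consumer == links$resource)) {
      stop("self-links are not allowed", call. = FALSE)
    }
    bad <- setdiff(c(links$consumer, links$resource), taxa$taxon_id)
    if (length(bad) > 0) {
      stop("link endpoints not in taxa: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    links <- dplyr::distinct(links, .data$consumer, .data$resource)
  } else {
    links <- tibble::tibble(consumer = character(), resource = character())
  }
  structure(list(nodes = taxa, links = links, degenerate = nrow(taxa) < 2),
            class = "food_web")
}

#' @export
print.food_web <- function(x, ...) {
  cat("<food_web> S =", nrow(x$nodes), " L =", nrow(x$links))
  if (isTRUE(x$degenerate)) cat("  [degenerate]")
  cat("\n")
  invisible(x)
}

#' Prey-averaged trophic levels
#'
#' TL_i = 1 for nodes with no resources (basal status is derived from the
#' link structure, not from group labels); otherwise TL_i = 1 + the mean
#' trophic level of i's resources. Solved as a linear system
#' (I - W) TL = 1 with W the row-normalized resource matrix, so webs with
#' cycles (intra-trophic links) are handled, provided every cycle has an
#' exit path to a basal node. Cannibalistic self-links are excluded before
#' solving.
#'
#' @param web A `food_web`.
#' @return Tibble `taxon_id`, `trophic_level`.
#' @export
trophic_levels <- function(web) {
  nodes <- web$nodes$taxon_id
  S <- length(nodes)
  links <- web$links[web$links$consumer != web$links$resource, ]
  W <- matrix(0, S, S, dimnames = list(nodes, nodes))
  if (nrow(links) > 0) {
    n_res <- table(factor(links$consumer, levels = nodes))
    W[cbind(match(links$consumer, nodes), match(links$resource, nodes))] <- 1
    W <- W / pmax(as.numeric(n_res), 1)
  }
  A <- diag(S) - W
  tl <- tryCatch(solve(A, rep(1, S)),
                 error = function(e) {
                   g <- igraph::graph_from_data_frame(
                     links[, c("consumer", "resource")],
                     vertices = nodes)
                   comp <- igraph::components(g, mode = "strong")
                   big <- names(comp$membership)[
                     comp$membership %in% which(comp$csize > 1)]
                   stop("trophic levels undefined: closed consumer cycle ",
                        "with no basal path among {",
                        paste(big, collapse = ", "), "}", call. = FALSE)
                 })
  tibble::tibble(taxon_id = nodes, trophic_level = as.numeric(tl))
}

#' Omnivory indices
#'
#' A consumer's omnivory index is the population standard deviation of its
#' resources' trophic levels (0 for consumers with a single resource);
#' community omnivory is the mean index over all consumers (nodes with at
#' least one resource).
#'
#' @param web A `food_web`.
#' @param levels Optional precomputed [trophic_levels()] table.
#' @return Tibble `taxon_id`, `omnivory` for consumers; attribute
#'   `community` holds the community mean.
#' @export
omnivory <- function(web, levels = NULL) {
  if (is.null(levels)) levels <- trophic_levels(web)
  links <- web$links[web$links$consumer != web$links$resource, ]
  tl <- stats::setNames(levels$trophic_level, levels$taxon_id)
  consumers <- unique(links$consumer)
  oi <- vapply(consumers, function(c) {
    res_tl <- tl[links$resource[links$consumer == c]]
    sqrt(mean((res_tl - mean(res_tl))^2))  # population SD
  }, numeric(1))
  out <- tibble::tibble(taxon_id = consumers, omnivory = unname(oi))
  attr(out, "community") <- if (length(oi) > 0) mean(oi) else NA_real_
  out
}

#' Food-web structure metrics
#'
#' L (connectivity: total link count), link density L/S, connectance
#' L/S^2, trophic length (the maximum prey-averaged trophic level, the
#' standard food-chain-length surrogate), and community omnivory.
#'
#' @param web A `food_web`.
#' @return One-row tibble `S`, `L`, `link_density`, `connectance`,
#'   `trophic_length`, `community_omnivory`.
#' @export
web_metrics <- function(web) {
  S <- nrow(web$nodes)
  L <- nrow(web$links)
  if (isTRUE(web$degenerate) || S < 2) {
    return(tibble::tibble(S = S, L = L, link_density = NA_real_,
                          connectance = NA_real_, trophic_length = NA_real_,
                          community_omnivory = NA_real_))
  }
  tl <- tryCatch(trophic_levels(web), error = function(e) {
    warning(conditionMessage(e), "; trophic metrics reported as NA",
            call. = FALSE)
    NULL
  })
  om <- if (!is.null(tl)) omnivory(web, tl)
  tibble::tibble(
    S = S, L = L,
    link_density = L / S,
    connectance = L / S^2,
    trophic_length = if (is.null(tl)) NA_real_ else max(tl$trophic_level),
    community_omnivory = if (is.null(tl)) NA_real_ else attr(om, "community"))
}

#' Induced local food web on present taxa
#'
#' The site- or reach-scale web is the metaweb's induced subgraph on the
#' taxa present there. Webs with fewer than 2 nodes are returned with the
#' `degenerate` flag set (their metrics are reported as missing, never
#' fabricated).
#'
#' @param web A `food_web` (metaweb).
#' @param present Character vector of present taxon ids.
#' @return A `food_web`.
#' @export
local_web <- function(web, present) {
  present <- intersect(web$nodes$taxon_id, present)
  nodes <- web$nodes[web$nodes$taxon_id %in% present, ]
  links <- web$links[web$links$consumer %in% present &
                       web$links$resource %in% present, ]
  structure(list(nodes = nodes, links = links,
                 degenerate = nrow(nodes) < 2),
            class = "food_web")
}

#' Read / write food-web link lists
#'
#' @param path CSV path with header `consumer,resource`.
#' @return [read_links()]: a tibble; [write_links()]: `path` invisibly.
#' @export
read_links <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname read_links
#' @param web A `food_web`.
#' @export
write_links <- function(web, path) {
  readr::write_csv(web$links, path)
  invisible(path)
}
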