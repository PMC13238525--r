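#' Construct a validated river network from a reach table
#'
#' A river network is a dendritic (tree-shaped) set of reaches: every reach
#' drains into exactly one downstream reach, except the single outlet reach,
#' which drains out of the basin. Reaches are the *edges* of the drainage
#' tree; junctions are implicit, so confluence mass balance is a fold over
#' the reaches immediately upstream of a reach.
#'
#' @param reaches A data frame with columns `reach_id`, `downstream_id`
#'   (`NA` or `""` for the outlet), `length_m`, `width_m`, `slope`,
#'   `elevation_m`, `source_area_m2`.
#' @return An object of class `reach_network`: the validated reach tibble
#'   plus precomputed upstream/downstream indices and a topological order.
#' @examples
#' y <- as_reach_network(tibble::tibble(
#'   reach_id = c("A", "B", "C"), downstream_id = c("C", "C", NA),
#'   length_m = c(1000, 1500, 2000), width_m = c(4, 4, 6),
#'   slope = c(0.01, 0.01, 0.005), elevation_m = c(120, 130, 100),
#'   source_area_m2 = c(2e5, 3e5, 4e5)))
#' downstream_path(y, "A")
#' @export
as_reach_network <- function(reaches) {
  required <- c("reach_id", "downstream_id", "length_m", "width_m", "slope",
                "elevation_m", "source_area_m2")
  missing_cols <- setdiff(required, names(reaches))
  if (length(missing_cols) > 0) {
    stop("reach table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  reaches <- tibble::as_tibble(reaches)[required]
  reaches$reach_id <- as.character(reaches$reach_id)
  reaches$downstream_id <- as.character(reaches$downstream_id)
  reaches$downstream_id[!is.na(reaches$downstream_id) &
                          reaches$downstream_id == ""] <- NA_character_

  dup <- reaches$reach_id[duplicated(reaches$reach_id)]
  if (length(dup) > 0) {
    stop("duplicate reach_id: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad <- which(!(reaches$length_m > 0) | !(reaches$width_m > 0) |
                 !(reaches$source_area_m2 > 0) | reaches$slope < 0)
  if (length(bad) > 0) {
    stop("invalid hydraulic attributes (need length, width, source area > 0 and slope >= 0) in row(s) ",
         paste(bad, collapse = ", "), " (reach ",
         paste(reaches$reach_id[bad], collapse = ", "), ")", call. = FALSE)
  }

  is_outlet <- is.na(reaches$downstream_id)
  if (sum(is_outlet) != 1) {
    stop("network must have exactly one outlet reach (downstream_id = NA); found ",
         sum(is_outlet), call. = FALSE)
  }
  unknown <- setdiff(stats::na.omit(reaches$downstream_id), reaches$reach_id)
  if (length(unknown) > 0) {
    stop("downstream_id refers to unknown reach(es): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  n <- nrow(reaches)
  idx <- stats::setNames(seq_len(n), reaches$reach_id)
  down_idx <- unname(idx[reaches$downstream_id])  # NA for outlet
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(down_idx[i])) {
      children[[down_idx[i]]] <- c(children[[down_idx[i]]], i)
    }
  }

  # breadth-first from the outlet over upstream neighbours; unreachable
  # reaches imply a cycle (downstream chains that never hit the outlet)
  outlet <- which(is_outlet)
  order_up <- integer(n)  # outlet-first order
  seen <- logical(n)
  queue <- outlet
  seen[outlet] <- TRUE
  k <- 0L
  while (length(queue) > 0) {
    cur <- queue[1]
    queue <- queue[-1]
    k <- k + 1L
    order_up[k] <- cur
    for (ch in children[[cur]]) {
      if (!seen[ch]) {
        seen[ch] <- TRUE
        queue <- c(queue, ch)
      }
    }
  }
  if (any(!seen)) {
    stop("cycle detected: reach(es) ", paste(reaches$reach_id[!seen], collapse = ", "),
         " never drain to the outlet", call. = FALSE)
  }

  structure(
    list(reaches = reaches,
         outlet_id = reaches$reach_id[outlet],
         idx = idx,
         down_idx = down_idx,
         children = children,
         order_down = rev(order_up)),  # upstream reaches before downstream
    class = "reach_network")
}

#' @export
print.reach_network <- function(x, ...) {
  cat("<reach_network> ", nrow(x$reaches), " reaches, outlet ", x$outlet_id,
      ", ", sum(lengths(x$children) == 0), " headwaters\n", sep = "")
  invisible(x)
}

#' @export
#' @method == reach_network
`==.reach_network` <- function(e1, e2) {
  isTRUE(all.equal(e1$reaches, e2$reaches))
}

#' Read a river network from a CSV edge list
#'
#' Expects the canonical header `reach_id,downstream_id,length_m,width_m,
#' slope,elevation_m,source_area_m2`; an empty `downstream_id` marks the
#' outlet.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A [as_reach_network()] object.
#' @export
read_network <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    reach_id = readr::col_character(),
    downstream_id = readr::col_character(),
    .default = readr::col_double()))
  as_reach_network(tab)
}

#' Write a river network to CSV
#'
#' Round-trips with [read_network()] on the canonical column order.
#'
#' @param net A `reach_network`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "reach_network"))
  readr::write_csv(net$reaches, path, na = "")
  invisible(path)
}

resolve_reach <- function(net, reach_id) {
  i <- net$idx[as.character(reach_id)]
  if (any(is.na(i))) {
    stop("unknown reach_id: ",
         paste(reach_id[is.na(i)], collapse = ", "), call. = FALSE)
  }
  unname(i)
}

#' Downstream flow path from a reach to the outlet
#'
#' @param net A `reach_network`.
#' @param reach_id A single reach identifier.
#' @return Character vector of reach ids starting at `reach_id` and ending
#'   at the outlet; each element is the downstream neighbour of the previous.
#' @export
downstream_path <- function(net, reach_id) {
  i <- resolve_reach(net, reach_id)
  stopifnot(length(i) == 1)
  path <- integer(0)
  while (!is.na(i)) {
    path <- c(path, i)
    i <- net$down_idx[i]
  }
  net$reaches$reach_id[path]
}

#' Flow distance from each reach to the basin outlet
#'
#' Distance is measured from a reach's upstream end, so every reach
#' contributes its own length and the distance strictly decreases along
#' each downstream step.
#'
#' @param net A `reach_network`.
#' @param reach_id Optional reach ids; default all reaches.
#' @return A tibble `reach_id`, `distance_km`, one row per requested reach
#'   in the requested order.
#' @export
distance_to_outlet <- function(net, reach_id = NULL) {
  n <- nrow(net$reaches)
  dist_m <- numeric(n)
  # accumulate outlet-first so each reach can add its downstream total
  for (i in rev(net$order_down)) {
    d <- net$down_idx[i]
    dist_m[i] <- net$reaches$length_m[i] + if (is.na(d)) 0 else dist_m[d]
  }
  out <- tibble::tibble(reach_id = net$reaches$reach_id, distance_km = dist_m / 1000)
  if (!is.null(reach_id)) out <- out[resolve_reach(net, reach_id), ]
  out
}

#' All reaches draining through a given reach
#'
#' @param net A `reach_network`.
#' @param reach_id A single reach identifier.
#' @return Character vector of reach ids whose downstream path passes
#'   through `reach_id`, including `reach_id` itself.
#' @export
upstream_set <- function(net, reach_id) {
  i <- resolve_reach(net, reach_id)
  stopifnot(length(i) == 1)
  acc <- integer(0)
  queue <- i
  while (length(queue) > 0) {
    cur <- queue[1]
    queue <- c(queue[-1], net$children[[cur]])
    acc <- c(acc, cur)
  }
  net$reaches$reach_id[sort(acc)]
}

#' Validate a site-to-reach mapping
#'
#' Sampling sites map one-to-one onto reaches: every `reach_id` must exist
#' and no two sites may share a reach (duplicates signal a user error since
#' sites are widely spaced).
#'
#' @param net A `reach_network`.
#' @param sites Data frame with columns `site_id`, `reach_id`.
#' @return The validated sites tibble.
#' @export
validate_sites <- function(net, sites) {
  stopifnot(all(c("site_id", "reach_id") %in% names(sites)))
  sites <- tibble::as_tibble(sites)
  sites$site_id <- as.character(sites$site_id)
  sites$reach_id <- as.character(sites$reach_id)
  resolve_reach(net, sites$reach_id)
  dup <- sites$reach_id[duplicated(sites$reach_id)]
  if (length(dup) > 0) {
    stop("multiple sites map to the same reach: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sites$site_id)) stop("duplicate site_id", call. = FALSE)
  sites
}
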