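# Shared fixtures: built in code, no data files.

# minimal Y-junction: A and B drain into outlet C
y_net <- function(length_c = 2000) {
  as_reach_network(tibble::tibble(
    reach_id = c("A", "B", "C"),
    downstream_id = c("C", "C", NA),
    length_m = c(1000, 1500, length_c),
    width_m = c(4, 4, 6),
    slope = c(0.01, 0.01, 0.005),
    elevation_m = c(120, 130, 100),
    source_area_m2 = c(2e5, 3e5, 4e5)))
}

# the transport hand-calculation network: A, B (1000 m, v = 1) into a
# zero-ish length outlet C; unit discharge per headwater
hand_net <- function() {
  as_reach_network(tibble::tibble(
    reach_id = c("A", "B", "C"),
    downstream_id = c("C", "C", NA),
    length_m = c(1000, 1000, 1e-9),
    width_m = c(7.2, 7.2, 7.2),
    slope = 0, elevation_m = 0, source_area_m2 = 1))
}

hand_hydraulics <- function() {
  tibble::tibble(reach_id = c("A", "B", "C"),
                 discharge = c(1, 1, 2), velocity = c(1, 1, 1))
}

# random dendritic tree built by an independent construction (sequential
# random attachment, not the package's pairwise-merge generator)
random_tree <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("t%03d", seq_len(n))
  downstream <- c(NA_character_,
                  ids[vapply(2:n, function(i) sample(i - 1, 1), integer(1))])
  tibble::tibble(
    reach_id = ids, downstream_id = downstream,
    length_m = stats::runif(n, 200, 5000),
    width_m = stats::runif(n, 2, 50),
    slope = stats::runif(n, 0, 0.05),
    elevation_m = stats::runif(n, 0, 500),
    source_area_m2 = stats::runif(n, 1e4, 1e6))
}

# Sugihara bidirectionally coupled logistic map
coupled_logistic <- function(n_keep = 400, burn = 100, x0 = 0.4, y0 = 0.2,
                             bxy = 0.02, byx = 0.1) {
  n <- n_keep + burn
  x <- y <- numeric(n)
  x[1] <- x0; y[1] <- y0
  for (t in seq_len(n - 1)) {
    x[t + 1] <- x[t] * (3.8 - 3.8 * x[t] - bxy * y[t])
    y[t + 1] <- y[t] * (3.5 - 3.5 * y[t] - byx * x[t])
  }
  list(x = x[(burn + 1):n], y = y[(burn + 1):n])
}

# pure-R exhaustive simplex oracle: brute-force distances, E+1 neighbours,
# exp(-d/d1) weights; independent of the C++ implementation
oracle_simplex <- function(lib_pts, lib_y, query, self = NA) {
  E <- ncol(lib_pts)
  d <- sqrt(colSums((t(lib_pts) - query)^2))
  if (!is.na(self)) d[self] <- Inf
  ord <- order(d)[seq_len(E + 1)]
  d1 <- d[ord[1]]
  if (d1 == 0) {
    exact <- ord[d[ord] == 0]
    return(mean(lib_y[exact]))
  }
  w <- exp(-d[ord] / d1)
  sum(w * lib_y[ord]) / sum(w)
}

# random food web over S nodes (first n_basal are basal)
random_web <- function(S, n_basal, p_link, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(S))
  links <- list()
  for (i in (n_basal + 1):S) {
    prey <- which(stats::runif(S) < p_link & seq_len(S) < i)
    if (length(prey) == 0) prey <- sample(seq_len(i - 1), 1)
    links[[i]] <- tibble::tibble(consumer = ids[i], resource = ids[prey])
  }
  build_metaweb(dplyr::bind_rows(links), tibble::tibble(taxon_id = ids))
}

# iterative (Jacobi) trophic-level oracle, independent of the solve() path
oracle_trophic_levels <- function(web, iters = 4000) {
  nodes <- web$nodes$taxon_id
  links <- web$links[web$links$consumer != web$links$resource, ]
  tl <- stats::setNames(rep(1, length(nodes)), nodes)
  for (k in seq_len(iters)) {
    tl_new <- vapply(nodes, function(nd) {
      res <- links$resource[links$consumer == nd]
      if (length(res) == 0) 1 else 1 + mean(tl[res])
    }, numeric(1))
    if (max(abs(tl_new - tl)) < 1e-13) break
    tl <- tl_new
  }
  tibble::tibble(taxon_id = nodes, trophic_level = unname(tl))
}
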