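test_that("occupancy filtering keeps taxa detected at more than half the sites", {
  n_sites <- 44  # basin-scale site count
  sites <- sprintf("s%02d", seq_len(n_sites))
  make_abund <- function(n_det, taxon) tibble::tibble(
    site_id = sites, taxon_id = taxon,
    value = c(rep(1, n_det), rep(0, n_sites - n_det)))
  abund <- dplyr::bind_rows(make_abund(23, "kept"), make_abund(22, "dropped"),
                            make_abund(44, "anchor"))
  taxa <- tibble::tibble(taxon_id = c("kept", "dropped", "anchor"),
                         trophic_group = c("fish", "algae", "algae"))
  out <- filter_taxa(abund, taxa)
  expect_setequal(unique(out$taxon_id), c("kept", "anchor"))  # 23/44 > 0.5, 22/44 not

  # all taxa everywhere -> identity
  full <- dplyr::bind_rows(make_abund(44, "a"), make_abund(44, "b"))
  taxa2 <- tibble::tibble(taxon_id = c("a", "b"),
                          trophic_group = c("fish", "algae"))
  expect_equal(nrow(filter_taxa(full, taxa2)), nrow(full))

  # single surviving trophic group violates the two-level rule
  taxa3 <- tibble::tibble(taxon_id = c("kept", "dropped", "anchor"),
                          trophic_group = "fish")
  expect_error(filter_taxa(abund, taxa3), "2 trophic")
})

test_that("occupancy survival matches a brute-force counting oracle", {
  set.seed(8)
  n_sites <- 30
  abund <- tidyr::expand_grid(site_id = sprintf("s%02d", 1:n_sites),
                              taxon_id = sprintf("t%02d", 1:10))
  abund$value <- stats::rbinom(nrow(abund), 1, stats::runif(nrow(abund), 0.2, 0.9)) *
    stats::rlnorm(nrow(abund))
  taxa <- tibble::tibble(taxon_id = sprintf("t%02d", 1:10),
                         trophic_group = rep(c("fish", "algae"), 5))
  out <- filter_taxa(abund, taxa)
  # oracle: count nonzero cells per taxon directly
  counts <- tapply(abund$value > 0, abund$taxon_id, sum)
  expect_setequal(unique(out$taxon_id), names(counts)[counts > n_sites / 2])
})

test_that("metaweb assembly deduplicates and keeps isolated nodes", {
  taxa <- tibble::tibble(taxon_id = c("a", "b", "c"))
  empty <- build_metaweb(tibble::tibble(), taxa)
  expect_equal(nrow(empty$nodes), 3)
  expect_equal(nrow(empty$links), 0)
  dup <- tibble::tibble(consumer = c("b", "b"), resource = c("a", "a"))
  expect_equal(nrow(build_metaweb(dup, taxa)$links), 1)
  expect_error(build_metaweb(tibble::tibble(consumer = "a", resource = "a"),
                             taxa), "self-link")
})

test_that("prey-averaged trophic levels match textbook chains and the formula", {
  taxa <- tibble::tibble(taxon_id = c("algae", "herb", "fish"))
  chain <- build_metaweb(tibble::tibble(consumer = c("fish", "herb"),
                                        resource = c("herb", "algae")), taxa)
  tl <- trophic_levels(chain)
  expect_equal(tl$trophic_level, c(1, 2, 3))

  omni <- build_metaweb(tibble::tibble(
    consumer = c("herb", "omni", "omni"),
    resource = c("algae", "algae", "herb")),
    tibble::tibble(taxon_id = c("algae", "herb", "omni")))
  tlo <- trophic_levels(omni)
  expect_equal(tlo$trophic_level[tlo$taxon_id == "omni"], 2.5)

  # closed consumer cycle with no basal exit is an error naming the cycle
  loop <- build_metaweb(tibble::tibble(consumer = c("a", "b"),
                                       resource = c("b", "a")),
                        tibble::tibble(taxon_id = c("a", "b")))
  expect_error(trophic_levels(loop), "cycle")
})

test_that("trophic levels agree with an iterative oracle on random webs", {
  for (seed in 1:50) {
    web <- random_web(S = sample(6:20, 1), n_basal = sample(2:4, 1),
                      p_link = 0.3, seed = seed)
    tl <- trophic_levels(web)
    oracle <- oracle_trophic_levels(web)
    expect_equal(tl$trophic_level, oracle$trophic_level, tolerance = 1e-10)
    expect_true(all(tl$trophic_level >= 1 - 1e-12))
    expect_true(all(tl$trophic_level <= nrow(web$nodes) + 1e-12))
    basal <- setdiff(web$nodes$taxon_id, unique(web$links$consumer))
    expect_true(all(abs(tl$trophic_level[tl$taxon_id %in% basal] - 1) < 1e-12))
  }
})

test_that("omnivory is the population SD of resource trophic levels", {
  omni <- build_metaweb(tibble::tibble(
    consumer = c("herb", "omni", "omni"),
    resource = c("algae", "algae", "herb")),
    tibble::tibble(taxon_id = c("algae", "herb", "omni")))
  oi <- omnivory(omni)
  expect_equal(oi$omnivory[oi$taxon_id == "omni"], 0.5)  # sd of {1, 2}
  expect_equal(oi$omnivory[oi$taxon_id == "herb"], 0)    # single resource

  chain <- build_metaweb(tibble::tibble(consumer = c("f", "h"),
                                        resource = c("h", "a")),
                         tibble::tibble(taxon_id = c("a", "h", "f")))
  expect_equal(attr(omnivory(chain), "community"), 0)

  # direct per-node recomputation oracle
  web <- random_web(12, 3, 0.35, seed = 77)
  tl <- trophic_levels(web)
  oi2 <- omnivory(web, tl)
  tlv <- stats::setNames(tl$trophic_level, tl$taxon_id)
  for (k in seq_len(nrow(oi2))) {
    res <- web$links$resource[web$links$consumer == oi2$taxon_id[k]]
    v <- tlv[res]
    expect_equal(oi2$omnivory[k], sqrt(mean((v - mean(v))^2)), tolerance = 1e-12)
  }
})

test_that("web metrics reproduce the basin-scale arithmetic identities", {
  # S = 77, L = 1146 and S = 63, L = 524 give the printed link densities
  expect_equal(1146 / 77, 14.88, tolerance = 1e-3)
  fake_links <- function(S, L) {
    ids <- sprintf("n%02d", seq_len(S))
    pairs <- expand.grid(consumer = ids, resource = ids,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$consumer > pairs$resource, ]  # acyclic enumeration
    pairs[seq_len(L), ]
  }
  web77 <- build_metaweb(fake_links(77, 1146),
                         tibble::tibble(taxon_id = sprintf("n%02d", 1:77)))
  m <- web_metrics(web77)
  expect_equal(m$S, 77); expect_equal(m$L, 1146)
  expect_equal(m$link_density, 1146 / 77)
  expect_equal(m$connectance, 1146 / 77^2)
  web63 <- build_metaweb(fake_links(63, 524),
                         tibble::tibble(taxon_id = sprintf("n%02d", 1:63)))
  expect_equal(web_metrics(web63)$link_density, 524 / 63)

  # fully connected 4-node web without self-links
  ids <- letters[1:4]
  full <- build_metaweb(
    subset(expand.grid(consumer = ids, resource = ids,
                       stringsAsFactors = FALSE), consumer != resource),
    tibble::tibble(taxon_id = ids))
  expect_warning(mfull <- web_metrics(full), "cycle")
  expect_equal(mfull$connectance, 12 / 16)
})

test_that("local webs are induced subgraphs with degenerate flagging", {
  web <- random_web(15, 4, 0.3, seed = 5)
  all_present <- local_web(web, web$nodes$taxon_id)
  expect_equal(web_metrics(all_present), web_metrics(web))
  one <- local_web(web, web$nodes$taxon_id[1])
  expect_true(one$degenerate)
  expect_true(is.na(web_metrics(one)$link_density))
  # brute-force link filtering oracle under random masks
  for (seed in 1:10) {
    set.seed(seed)
    present <- sample(web$nodes$taxon_id, sample(3:12, 1))
    sub <- local_web(web, present)
    manual <- web$links[web$links$consumer %in% present &
                          web$links$resource %in% present, ]
    expect_equal(nrow(sub$links), nrow(manual))
  }
  # monotonicity: adding a taxon never decreases links
  present <- web$nodes$taxon_id[1:6]
  for (extra in setdiff(web$nodes$taxon_id, present)) {
    expect_gte(nrow(local_web(web, c(present, extra))$links),
               nrow(local_web(web, present)$links))
  }
})
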