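#' Specify a PLS path model
#'
#' Latent variables are reflective composites of observed indicator
#' columns; the inner (structural) model is a directed acyclic set of
#' latent -> latent effects.
#'
#' @param blocks Named list: latent name -> character vector of indicator
#'   column names. Every indicator belongs to exactly one block.
#' @param inner Data frame with columns `from`, `to` (latent names),
#'   acyclic.
#' @param scheme Inner weighting scheme: `"centroid"` (default),
#'   `"factor"`, or `"path"`.
#' @return An object of class `path_spec`.
#' @export
path_spec <- function(blocks, inner, scheme = c("centroid", "factor", "path")) {
  scheme <- match.arg(scheme)
  stopifnot(is.list(blocks), length(blocks) >= 2,
            all(c("from", "to") %in% names(inner)))
  if (any(lengths(blocks) < 1)) stop("every block needs >= 1 indicator", call. = FALSE)
  inds <- unlist(blocks)
  if (anyDuplicated(inds)) {
    stop("indicator(s) in more than one block: ",
         paste(unique(inds[duplicated(inds)]), collapse = ", "), call. = FALSE)
  }
  latents <- names(blocks)
  bad <- setdiff(c(inner$from, inner$to), latents)
  if (length(bad) > 0) stop("unknown latent(s) in inner model: ",
                            paste(bad, collapse = ", "), call. = FALSE)
  g <- igraph::graph_from_data_frame(inner[, c("from", "to")], vertices = latents)
  if (!igraph::is_dag(g)) stop("inner model must be acyclic", call. = FALSE)
  structure(list(blocks = blocks, inner = tibble::as_tibble(inner[, c("from", "to")]),
                 scheme = scheme),
            class = "path_spec")
}

#' Fit a PLS path model (Lohmoeller alternating algorithm)
#'
#' Indicators are standardized; outer weights (Mode A) and latent scores
#' alternate with inner-scheme weighting until the outer weights change by
#' less than `tol`. Path coefficients are then OLS regressions of each
#' endogenous latent score on its predecessors; loadings are correlations
#' of indicators with their own latent score. Each latent is oriented to
#' correlate positively with its first indicator.
#'
#' @param data Site-by-indicator data frame (rows with missing indicator
#'   values are dropped; at least 10 complete rows required).
#' @param spec A [path_spec()].
#' @param tol Convergence tolerance on outer weights.
#' @param max_iter Maximum iterations.
#' @return An object of class `pls_pm`: loadings, path coefficients, R2,
#'   communalities, GOF, VIFs, latent scores, convergence trace.
#' @export
plspm_fit <- function(data, spec, tol = 1e-7, max_iter = 300) {
  st <- plspm_scores(data, spec, tol = tol, max_iter = max_iter)
  X <- st$X
  scores <- st$scores
  w <- st$w
  inds <- st$inds
  latents <- names(spec$blocks)
  block_of <- rep(latents, lengths(spec$blocks))

  loadings <- tibble::tibble(
    latent = block_of, indicator = inds,
    loading = vapply(seq_along(inds),
                     function(k) stats::cor(X[, inds[k]], scores[, block_of[k]]),
                     numeric(1)))

  endo <- unique(spec$inner$to)
  q <- length(latents)
  paths <- list(); r2 <- stats::setNames(rep(NA_real_, q), latents)
  for (lv in endo) {
    pred <- spec$inner$from[spec$inner$to == lv]
    df <- data.frame(y = scores[, lv], scores[, pred, drop = FALSE])
    fit <- stats::lm(y ~ . - 1, data = df)
    if (any(is.na(stats::coef(fit)))) {
      stop("singular inner regression for latent '", lv, "'", call. = FALSE)
    }
    paths[[lv]] <- tibble::tibble(from = pred, to = lv,
                                  estimate = unname(stats::coef(fit)))
    r2[lv] <- summary(fit)$r.squared
  }
  paths <- dplyr::bind_rows(paths)
  communality <- loadings$loading^2
  gof_val <- sqrt(mean(communality) * mean(r2[endo]))

  structure(list(
    spec = spec, n = st$n,
    weights = tibble::tibble(latent = block_of, indicator = inds,
                             weight = unname(w)),
    loadings = loadings,
    paths = paths,
    r2 = tibble::tibble(latent = endo, r2 = unname(r2[endo])),
    communality = tibble::tibble(indicator = inds, communality = communality),
    gof = gof_val,
    vif = plspm_vifs(scores, spec),
    scores = tibble::as_tibble(as.data.frame(scores)),
    converged = st$converged, iterations = st$iterations, trace = st$trace),
    class = "pls_pm")
}

# Lohmoeller alternating weight estimation: standardized indicators,
# Mode A outer estimation, chosen inner scheme; returns oriented
# unit-variance latent scores
plspm_scores <- function(data, spec, tol = 1e-7, max_iter = 300) {
  stopifnot(inherits(spec, "path_spec"))
  inds <- unname(unlist(spec$blocks))
  missing_cols <- setdiff(inds, names(data))
  if (length(missing_cols) > 0) {
    stop("data is missing indicator column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(data[, inds, drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  if (n < 10) stop("need >= 10 complete rows, got ", n, call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant indicator(s): ",
                          paste(colnames(X)[sds == 0], collapse = ", "),
                          call. = FALSE)
  X <- scale(X)
  latents <- names(spec$blocks)
  q <- length(latents)
  block_of <- rep(latents, lengths(spec$blocks))
  adj <- matrix(FALSE, q, q, dimnames = list(latents, latents))
  adj[cbind(match(spec$inner$from, latents), match(spec$inner$to, latents))] <- TRUE
  neighbour <- adj | t(adj)

  w <- stats::setNames(rep(1, length(inds)), inds)
  scores <- NULL
  converged <- FALSE
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    scores <- sapply(latents, function(lv) {
      xb <- X[, spec$blocks[[lv]], drop = FALSE]
      y <- xb %*% w[spec$blocks[[lv]]]
      as.numeric(y / stats::sd(y))
    })
    R <- stats::cor(scores)
    Z <- matrix(0, n, q, dimnames = list(NULL, latents))
    for (j in seq_len(q)) {
      e <- numeric(q)
      nb <- which(neighbour[, j] | neighbour[j, ])
      if (spec$scheme == "centroid") {
        e[nb] <- sign(R[nb, j])
      } else if (spec$scheme == "factor") {
        e[nb] <- R[nb, j]
      } else { # path scheme
        pred <- which(adj[, j])
        succ <- which(adj[j, ])
        if (length(pred) > 0) {
          e[pred] <- solve(R[pred, pred, drop = FALSE], R[pred, j])
        }
        e[succ] <- R[succ, j]
      }
      Z[, j] <- scores %*% e
    }
    w_new <- w
    for (lv in latents) {
      zb <- Z[, lv]
      if (stats::sd(zb) == 0) zb <- scores[, lv]
      w_new[spec$blocks[[lv]]] <-
        as.numeric(stats::cor(X[, spec$blocks[[lv]], drop = FALSE], zb))
    }
    delta <- max(abs(abs(w_new) - abs(w)))
    trace <- c(trace, delta)
    w <- w_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("PLS-PM did not converge in ", max_iter,
         " iterations (last weight changes: ",
         paste(signif(utils::tail(trace, 3), 3), collapse = ", "), ")",
         call. = FALSE)
  }
  scores <- sapply(latents, function(lv) {
    xb <- X[, spec$blocks[[lv]], drop = FALSE]
    y <- xb %*% w[spec$blocks[[lv]]]
    y <- y / stats::sd(y)
    # orient: positive correlation with the block's first indicator
    if (stats::cor(y, X[, spec$blocks[[lv]][1]]) < 0) y <- -y
    as.numeric(y)
  })
  list(X = X, scores = scores, w = w, inds = inds, n = n,
       converged = converged, iterations = it, trace = trace)
}

plspm_vifs <- function(scores, spec) {
  out <- list()
  for (lv in unique(spec$inner$to)) {
    pred <- spec$inner$from[spec$inner$to == lv]
    for (p in pred) {
      others <- setdiff(pred, p)
      v <- if (length(others) == 0) 1 else {
        fit <- stats::lm.fit(cbind(1, scores[, others, drop = FALSE]),
                             scores[, p])
        r2 <- 1 - sum(fit$residuals^2) / sum((scores[, p] - mean(scores[, p]))^2)
        if (r2 >= 1 - 1e-9) Inf else 1 / (1 - r2)
      }
      out[[length(out) + 1]] <- tibble::tibble(response = lv, predictor = p,
                                               vif = v)
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.pls_pm <- function(x, ...) {
  cat("<pls_pm> ", length(x$spec$blocks), " latents, n = ", x$n,
      ", GOF = ", signif(x$gof, 3), ", converged in ", x$iterations,
      " iterations\n", sep = "")
  invisible(x)
}

#' @export
tidy.pls_pm <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$paths, term = paste(.data$from, "->", .data$to),
                  type = "path")[, c("term", "type", "estimate")],
    tibble::tibble(term = paste0(x$loadings$latent, ": ", x$loadings$indicator),
                   type = "loading", estimate = x$loadings$loading))
}

#' @export
glance.pls_pm <- function(x, ...) {
  tibble::tibble(n = x$n, gof = x$gof, mean_r2 = mean(x$r2$r2),
                 mean_communality = mean(x$communality$communality),
                 max_vif = max(x$vif$vif), iterations = x$iterations,
                 converged = x$converged)
}

#' Goodness of fit of a PLS path model
#'
#' GOF = sqrt(mean communality across indicators x mean R2 across
#' endogenous latents).
#'
#' @param fit A `pls_pm` object.
#' @return A number in \[0, 1\].
#' @export
gof <- function(fit) {
  stopifnot(inherits(fit, "pls_pm"))
  sqrt(mean(fit$communality$communality) * mean(fit$r2$r2))
}

#' Drop weakly loading indicators and refit
#'
#' Iteratively removes indicators with |loading| below `threshold` and
#' refits until the measurement model is stable.
#'
#' @param data,spec,tol,max_iter As in [plspm_fit()].
#' @param threshold Absolute loading cutoff (default 0.7).
#' @return A list: `fit` (the refitted `pls_pm`), `spec` (the pruned
#'   [path_spec()]), `dropped` (removed indicators).
#' @export
prune_loadings <- function(data, spec, threshold = 0.7, tol = 1e-7,
                           max_iter = 300) {
  dropped <- character(0)
  repeat {
    fit <- plspm_fit(data, spec, tol = tol, max_iter = max_iter)
    weak <- fit$loadings$indicator[abs(fit$loadings$loading) < threshold]
    if (length(weak) == 0) {
      return(list(fit = fit, spec = spec, dropped = dropped))
    }
    blocks <- lapply(spec$blocks, setdiff, y = weak)
    empty <- names(blocks)[lengths(blocks) == 0]
    if (length(empty) > 0) {
      stop("pruning at |loading| < ", threshold, " empties block(s): ",
           paste(empty, collapse = ", "), call. = FALSE)
    }
    dropped <- c(dropped, weak)
    spec <- path_spec(blocks, spec$inner, spec$scheme)
  }
}

#' Variance inflation factors of the latent predictors
#'
#' Fits the model, then for every endogenous latent regresses each
#' predictor latent score on its co-predictors; VIF = 1 / (1 - R2).
#'
#' @param data,spec As in [plspm_fit()].
#' @param cutoff Pass/fail threshold (default 5).
#' @return Tibble `response`, `predictor`, `vif`, `pass`.
#' @export
vif_check <- function(data, spec, cutoff = 5) {
  st <- plspm_scores(data, spec)
  dplyr::mutate(plspm_vifs(st$scores, spec), pass = .data$vif < cutoff)
}

#' Direct, indirect, and total effects among latents
#'
#' Indirect effects are products of path coefficients summed over all
#' directed inner paths (computed by powers of the path matrix, which is
#' nilpotent since the inner model is acyclic).
#'
#' @param fit A `pls_pm` object.
#' @return Tibble `from`, `to`, `direct`, `indirect`, `total`.
#' @export
path_effects <- function(fit) {
  latents <- names(fit$spec$blocks)
  q <- length(latents)
  B <- matrix(0, q, q, dimnames = list(latents, latents))
  B[cbind(match(fit$paths$from, latents), match(fit$paths$to, latents))] <-
    fit$paths$estimate
  total <- B
  Bk <- B
  for (k in seq_len(q - 1)) {
    Bk <- Bk %*% B
    if (all(Bk == 0)) break
    total <- total + Bk
  }
  idx <- which(total != 0 | B != 0, arr.ind = TRUE)
  tibble::tibble(from = latents[idx[, 1]], to = latents[idx[, 2]],
                 direct = B[idx], indirect = total[idx] - B[idx],
                 total = total[idx])
}

#' Bootstrap significance of PLS path coefficients
#'
#' Case-resampling bootstrap: rows are resampled with replacement, the
#' model refitted, and each path's two-sided p-value taken from the
#' proportion of the bootstrap distribution on the far side of zero
#' (equivalently, the smallest percentile-CI level excluding 0).
#'
#' @param data,spec As in [plspm_fit()].
#' @param n_boot Number of bootstrap resamples (warns below 50).
#' @param seed Integer seed.
#' @param conf Confidence level for the reported percentile interval.
#' @return Tibble `from`, `to`, `estimate`, `ci_lower`, `ci_upper`,
#'   `p_value`, `n_boot_ok`.
#' @export
plspm_bootstrap <- function(data, spec, n_boot = 500, seed = 1, conf = 0.95) {
  if (n_boot < 50) warning("n_boot < 50 gives unstable p-values", call. = FALSE)
  fit0 <- plspm_fit(data, spec)
  inds <- unlist(spec$blocks)
  rows <- which(stats::complete.cases(data[, inds]))
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, nrow(fit0$paths))
  for (b in seq_len(n_boot)) {
    samp <- sample(rows, length(rows), replace = TRUE)
    fb <- tryCatch(plspm_fit(data[samp, , drop = FALSE], spec),
                   error = function(e) NULL)
    if (is.null(fb)) next
    boots[b, ] <- fb$paths$estimate[
      match(paste(fit0$paths$from, fit0$paths$to),
            paste(fb$paths$from, fb$paths$to))]
  }
  alpha <- 1 - conf
  out <- fit0$paths
  out$ci_lower <- apply(boots, 2, stats::quantile, alpha / 2, na.rm = TRUE)
  out$ci_upper <- apply(boots, 2, stats::quantile, 1 - alpha / 2, na.rm = TRUE)
  out$p_value <- vapply(seq_len(ncol(boots)), function(j) {
    b <- boots[!is.na(boots[, j]), j]
    2 * min((1 + sum(b <= 0)) / (1 + length(b)),
            (1 + sum(b >= 0)) / (1 + length(b)))
  }, numeric(1))
  out$n_boot_ok <- colSums(!is.na(boots))
  out
}
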