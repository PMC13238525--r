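#' Hydraulic scaling parameters
#'
#' Discharge is reconstructed from remotely sensed channel width by
#' inverting the downstream hydraulic-geometry relation W = a_w * Q^b_w
#' (Leopold-Maddock), optionally modulated by channel slope through the
#' exponent `gamma`; depth follows d = a_d * Q^b_d. Defaults are standard
#' at-a-basin coefficients (widths in metres, discharge in m^3/s).
#'
#' @param a_w,b_w Width coefficient and exponent, both > 0, `b_w` in (0, 1].
#' @param a_d,b_d Depth coefficient and exponent, `b_d` in (0, 1].
#' @param gamma Slope exponent; 0 (default) ignores slope.
#' @param s_min Slope floor used when `gamma != 0`, so flat reaches keep a
#'   positive discharge.
#' @return A list of class `hydraulic_params`.
#' @export
hydraulic_params <- function(a_w = 7.2, b_w = 0.5, a_d = 0.27, b_d = 0.39,
                             gamma = 0, s_min = 1e-4) {
  stopifnot(a_w > 0, b_w > 0, b_w <= 1, a_d > 0, b_d > 0, b_d < 1, s_min > 0)
  structure(list(a_w = a_w, b_w = b_w, a_d = a_d, b_d = b_d,
                 gamma = gamma, s_min = s_min),
            class = "hydraulic_params")
}

#' Local discharge from channel width and slope
#'
#' Q = (width / a_w)^(1/b_w) * max(slope, s_min)^gamma. Strictly increasing
#' in width.
#'
#' @param width Channel width in metres (> 0); vectorised.
#' @param slope Dimensionless channel slope (>= 0); vectorised.
#' @param params A [hydraulic_params()] object.
#' @return Discharge in m^3/s.
#' @export
local_discharge <- function(width, slope = 0, params = hydraulic_params()) {
  if (any(!(width > 0))) stop("width must be > 0", call. = FALSE)
  (width / params$a_w)^(1 / params$b_w) * pmax(slope, params$s_min)^params$gamma
}

#' Route discharge down the network
#'
#' Accumulates discharge downstream. With `method = "max"` (default) the
#' routed value is the larger of the reach's local width-based estimate and
#' the sum of routed discharge entering from immediately upstream, so noisy
#' remote-sensed widths can never make discharge decrease downstream. With
#' `method = "sum"` routing is pure mass accumulation (local + upstream),
#' the convention under which transported mass is exactly conserved.
#'
#' @param net A `reach_network`.
#' @param local_q Either a numeric vector in reach-table order, a named
#'   vector keyed by reach id, or a data frame `reach_id`, `discharge`.
#' @param method `"max"` or `"sum"`.
#' @return A tibble `reach_id`, `discharge` (m^3/s), nondecreasing along
#'   every downstream path.
#' @export
route_discharge <- function(net, local_q, method = c("max", "sum")) {
  method <- match.arg(method)
  q <- local_q_vector(net, local_q)
  routed <- q
  for (i in net$order_down) {       # upstream before downstream
    up <- net$children[[i]]
    inflow <- if (length(up) > 0) sum(routed[up]) else 0
    routed[i] <- if (method == "max") max(q[i], inflow) else q[i] + inflow
  }
  tibble::tibble(reach_id = net$reaches$reach_id, discharge = routed)
}

local_q_vector <- function(net, local_q) {
  n <- nrow(net$reaches)
  if (is.data.frame(local_q)) {
    stopifnot(all(c("reach_id", "discharge") %in% names(local_q)))
    q <- local_q$discharge[match(net$reaches$reach_id, as.character(local_q$reach_id))]
  } else if (!is.null(names(local_q))) {
    q <- unname(local_q[net$reaches$reach_id])
  } else {
    stopifnot(length(local_q) == n)
    q <- as.numeric(local_q)
  }
  if (anyNA(q)) stop("local discharge missing for some reaches", call. = FALSE)
  q
}

#' Mean advection velocity from discharge and channel geometry
#'
#' Depth d = a_d * Q^b_d; velocity v = Q / (width * d), i.e. discharge over
#' the rectangular cross-sectional area.
#'
#' @param discharge Discharge in m^3/s (> 0); vectorised.
#' @param width Channel width in metres (> 0); vectorised.
#' @param params A [hydraulic_params()] object.
#' @return Velocity in m/s.
#' @export
velocity <- function(discharge, width, params = hydraulic_params()) {
  if (any(!(discharge > 0)) || any(!(width > 0))) {
    stop("discharge and width must be > 0", call. = FALSE)
  }
  depth <- params$a_d * discharge^params$b_d
  discharge / (width * depth)
}

#' Per-reach hydraulics table for a network
#'
#' Convenience wrapper: local width-based discharge, routed discharge, and
#' advection velocity for every reach.
#'
#' @inheritParams route_discharge
#' @param params A [hydraulic_params()] object.
#' @return A tibble `reach_id`, `local_discharge`, `discharge`, `velocity`.
#' @export
reach_hydraulics <- function(net, params = hydraulic_params(),
                             method = c("max", "sum")) {
  q_local <- local_discharge(net$reaches$width_m, net$reaches$slope, params)
  routed <- route_discharge(net, q_local, method = match.arg(method))
  routed$velocity <- velocity(routed$discharge, net$reaches$width_m, params)
  tibble::tibble(reach_id = routed$reach_id,
                 local_discharge = q_local,
                 discharge = routed$discharge,
                 velocity = routed$velocity)
}
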