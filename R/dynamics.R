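# Forward simulation of the nested spread models.

MODEL_KINDS <- c("DIFF", "DIFF_R", "DIFF_RF")

model_code <- function(model) match(model, MODEL_KINDS) - 1L

#' Model parameter container
#'
#' Holds the global and regional parameters of one of the three nested
#' spread models: `DIFF` (linear network diffusion), `DIFF_R` (diffusion
#' plus Fisher-KPP rise toward a regional carrying capacity `beta`), and
#' `DIFF_RF` (rise plus a dynamic carrying capacity that falls at rate
#' `gamma` in response to local burden).
#'
#' @param model One of `"DIFF"`, `"DIFF_R"`, `"DIFF_RF"`.
#' @param rho Transport rate (per month), >= 0.
#' @param u0 Shared initial pathology value at the seed regions, > 0.
#' @param sigma Observation noise standard deviation, > 0.
#' @param seeds Seed regions: integer indices or region labels.
#' @param rho_secondary Optional second transport rate for bidirectional
#'   transport (paired with the secondary Laplacian).
#' @param alpha Global aggregation timescale (per month), `DIFF_R`/`DIFF_RF`.
#' @param beta Length-N regional carrying capacities (`DIFF_R`: any sign;
#'   `DIFF_RF`: initial values, >= 0).
#' @param gamma Length-N regional fall rates, >= 0 (`DIFF_RF` only).
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(model, rho, u0, sigma, seeds,
                             rho_secondary = NULL, alpha = NULL,
                             beta = NULL, gamma = NULL) {
  model <- match.arg(model, MODEL_KINDS)
  stopifnot(rho >= 0, u0 > 0, sigma > 0, length(seeds) >= 1)
  if (model != "DIFF") {
    if (is.null(alpha) || is.null(beta))
      stop(model, " requires alpha and beta", call. = FALSE)
    stopifnot(alpha >= 0)
  }
  if (model == "DIFF_RF") {
    if (is.null(gamma)) stop("DIFF_RF requires gamma", call. = FALSE)
    if (length(gamma) != length(beta))
      stop("beta and gamma must have equal length", call. = FALSE)
    if (any(beta < 0))
      stop("DIFF_RF requires beta >= 0 (prior support)", call. = FALSE)
    if (any(gamma < 0)) stop("gamma must be >= 0", call. = FALSE)
  } else if (!is.null(gamma)) {
    stop("gamma is only defined for DIFF_RF", call. = FALSE)
  }
  structure(list(model = model, rho = rho, rho_secondary = rho_secondary,
                 alpha = alpha, beta = beta, gamma = gamma, u0 = u0,
                 sigma = sigma, seeds = seeds),
            class = "model_parameters")
}

resolve_seeds <- function(seeds, region_ids) {
  if (is.character(seeds)) {
    ix <- match(seeds, region_ids)
    if (anyNA(ix))
      stop("unknown seed region(s): ",
           paste(seeds[is.na(ix)], collapse = ", "), call. = FALSE)
    ix
  } else {
    as.integer(seeds)
  }
}

# Combined drift matrix A = -(rho * L + rho2 * L2) acting on u.
transport_drift <- function(params, transport) {
  A <- -params$rho * transport$L
  if (!is.null(transport$L2)) {
    rho2 <- params$rho_secondary %||% params$rho
    A <- A - rho2 * transport$L2
  }
  A
}

#' Simulate a spread model
#'
#' Integrates the chosen model on a transport operator with an adaptive
#' embedded Runge-Kutta (Dormand-Prince 4/5) integrator, or with
#' `deSolve::lsoda` (stiff-capable) when `method = "lsoda"`. The initial
#' condition is zero everywhere except `u0` at the seed regions; for
#' `DIFF_RF` the carrying-capacity states start at `beta`.
#'
#' @param params A [model_parameters] object.
#' @param transport A `transport_operator` from [make_transport()].
#' @param times Strictly increasing output timepoints (months).
#' @param rtol,atol Relative/absolute solver tolerances.
#' @param method `"dopri"` (compiled adaptive RK45, default) or `"lsoda"`.
#' @return An object of class `trajectory_set`: list with `times`, `u`
#'   (regions x timepoints matrix) and, for `DIFF_RF`, `beta_t`.
#' @export
simulate_pathology <- function(params, transport, times, rtol = 1e-6,
                               atol = 1e-9, method = c("dopri", "lsoda")) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(transport, "transport_operator"))
  method <- match.arg(method)
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  N <- nrow(transport$L)
  code <- model_code(params$model)
  A <- transport_drift(params, transport)
  seeds <- resolve_seeds(params$seeds, rownames(transport$L))
  y0 <- numeric(if (code == 2L) 2L * N else N)
  y0[seeds] <- params$u0
  beta <- params$beta %||% numeric(0)
  gamma <- params$gamma %||% numeric(0)
  if (code == 2L) y0[N + seq_len(N)] <- beta

  if (method == "dopri") {
    res <- .rf_integrate(A, params$alpha %||% 0, beta, gamma, y0, times,
                         code, rtol, atol)
    if (!res$success)
      stop("ODE integration failed (model=", params$model, ", rho=",
           signif(params$rho, 4), ")", call. = FALSE)
    sol <- res$y
  } else {
    rhs <- function(t, y, p) {
      u <- y[seq_len(N)]
      du <- as.vector(A %*% u)
      if (code == 1L) du <- du + params$alpha * u * (beta - u)
      if (code == 2L) {
        b <- y[N + seq_len(N)]
        du <- du + params$alpha * u * (b - u)
        return(list(c(du, -gamma * u)))
      }
      list(du)
    }
    t_all <- if (times[1] > 0) c(0, times) else times
    ode <- deSolve::lsoda(y0, t_all, rhs, parms = NULL, rtol = rtol,
                          atol = atol)
    keep <- match(times, ode[, 1])
    sol <- t(ode[keep, -1, drop = FALSE])
  }
  u <- sol[seq_len(N), , drop = FALSE]
  rownames(u) <- rownames(transport$L)
  if (min(u) < -10 * atol)
    warning("negative pathology excursion beyond -10*atol (min = ",
            signif(min(u), 3), ")", call. = FALSE)
  out <- list(times = times, u = u, beta_t = NULL)
  if (code == 2L) {
    bt <- sol[N + seq_len(N), , drop = FALSE]
    rownames(bt) <- rownames(u)
    out$beta_t <- bt
  }
  structure(out, class = "trajectory_set")
}

#' Classify the shape of a regional trajectory
#'
#' Labels a time series `rise_and_fall` when an interior maximum exceeds
#' both endpoints by more than `tolerance`, `flat` when its total range is
#' below `tolerance`, and `monotone_rise` otherwise.
#'
#' @param u Numeric time series (length >= 3).
#' @param tolerance Comparison tolerance on the pathology scale.
#' @return One of `"monotone_rise"`, `"rise_and_fall"`, `"flat"`.
#' @export
classify_trajectory <- function(u, tolerance = 1e-8) {
  if (length(u) < 3 || any(!is.finite(u)))
    stop("need a finite series of length >= 3", call. = FALSE)
  if (diff(range(u)) < tolerance) return("flat")
  interior <- u[-c(1, length(u))]
  m <- max(interior)
  if (m > u[1] + tolerance && m > u[length(u)] + tolerance)
    return("rise_and_fall")
  "monotone_rise"
}

#' Simulate the two-species heterodimer model at a single region
#'
#' Integrates the healthy/misfolded protein kinetics
#' `p' = k0 - k1 p - k2 p ptilde`, `ptilde' = -k3 ptilde + k2 p ptilde`.
#' In the regime where healthy protein is abundant and fast-equilibrating,
#' the misfolded species follows Fisher-KPP (logistic) growth with
#' `alpha = k0 k2^2 / k1^2` and `beta = (k0 k2 - k1 k3) / (k1 alpha)`; see
#' [heterodimer_fkpp_params()].
#'
#' @param k0,k1,k2,k3 Production, clearance (healthy), conversion and
#'   clearance (misfolded) rates, all > 0.
#' @param p0,ptilde0 Initial healthy / misfolded concentrations.
#' @param times Output timepoints.
#' @param rtol,atol Solver tolerances.
#' @return Matrix with columns `time`, `p`, `ptilde`.
#' @export
simulate_heterodimer <- function(k0, k1, k2, k3, p0, ptilde0, times,
                                 rtol = 1e-8, atol = 1e-10) {
  stopifnot(k0 > 0, k1 > 0, k2 > 0, k3 > 0)
  rhs <- function(t, y, parms) {
    list(c(k0 - k1 * y[1] - k2 * y[1] * y[2],
           -k3 * y[2] + k2 * y[1] * y[2]))
  }
  t_all <- if (times[1] > 0) c(0, times) else times
  ode <- deSolve::lsoda(c(p0, ptilde0), t_all, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  keep <- match(times, ode[, 1])
  out <- cbind(time = times, p = ode[keep, 2], ptilde = ode[keep, 3])
  out
}

#' FKPP parameters implied by heterodimer kinetics
#'
#' @inheritParams simulate_heterodimer
#' @return List with `alpha` and `beta`, the aggregation timescale and
#'   carrying capacity of the reduced logistic model.
#' @export
heterodimer_fkpp_params <- function(k0, k1, k2, k3) {
  alpha <- k0 * k2^2 / k1^2
  beta <- (k0 * k2 - k1 * k3) / (k1 * alpha)
  list(alpha = alpha, beta = beta)
}

#' Export a trajectory set as a long data frame
#'
#' @param traj A `trajectory_set`.
#' @return Data frame with columns `region`, `time`, `value` and, when
#'   present, `beta`.
#' @export
trajectory_long <- function(traj) {
  stopifnot(inherits(traj, "trajectory_set"))
  df <- data.frame(
    region = rep(rownames(traj$u), times = ncol(traj$u)),
    time = rep(traj$times, each = nrow(traj$u)),
    value = as.vector(traj$u))
  if (!is.null(traj$beta_t)) df$beta <- as.vector(traj$beta_t)
  df
}
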