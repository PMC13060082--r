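# Model comparison: WAIC, AIC/BIC/MSE, origin-constrained R2, holdout.

#' Widely Applicable Information Criterion
#'
#' Computes `lppd` (log pointwise predictive density, via log-sum-exp over
#' posterior samples), the effective parameter count `p_waic` (sum of
#' per-observation sample variances of the log-likelihood, ddof = 1) and
#' `waic = -2 (lppd - p_waic)`, along with pointwise contributions used for
#' paired standard errors of WAIC differences.
#'
#' @param log_lik Matrix of pointwise log-likelihoods, posterior samples in
#'   rows, observations in columns (at least 2 samples).
#' @return Object of class `rf_waic`: list with `waic`, `lppd`, `p_waic`,
#'   `pointwise` (per-observation WAIC contributions), `n_obs`.
#' @export
waic <- function(log_lik) {
  log_lik <- as.matrix(log_lik)
  if (nrow(log_lik) < 2)
    stop("WAIC needs at least 2 posterior samples", call. = FALSE)
  if (ncol(log_lik) < 1)
    stop("WAIC needs at least 1 observation", call. = FALSE)
  S <- nrow(log_lik)
  lppd_i <- apply(log_lik, 2, logsumexp) - log(S)
  p_i <- col_vars(log_lik)
  pointwise <- -2 * (lppd_i - p_i)
  structure(list(waic = sum(pointwise), lppd = sum(lppd_i),
                 p_waic = sum(p_i), pointwise = pointwise,
                 n_obs = ncol(log_lik)),
            class = "rf_waic")
}

#' @export
print.rf_waic <- function(x, ...) {
  cat(sprintf("WAIC = %.2f (lppd = %.2f, p_waic = %.2f, n = %d)\n",
              x$waic, x$lppd, x$p_waic, x$n_obs))
  invisible(x)
}

#' AIC, BIC and mean squared error at a point estimate
#'
#' @param map_loglik Log-likelihood at the MAP estimate.
#' @param n_params Number of free parameters of the model class.
#' @param n_obs Number of observations.
#' @param residuals Residuals (observed minus predicted) at the MAP.
#' @return List with `aic`, `bic`, `mse`, `n_params`, `n_obs`.
#' @export
aic_bic_mse <- function(map_loglik, n_params, n_obs, residuals) {
  stopifnot(n_obs >= 1)
  list(aic = 2 * n_params - 2 * map_loglik,
       bic = n_params * log(n_obs) - 2 * map_loglik,
       mse = mean(residuals^2),
       n_params = n_params, n_obs = n_obs)
}

#' Number of free parameters of a model class
#'
#' @param model Model kind.
#' @param n_regions Number of regions.
#' @param n_rho Number of transport rates.
#' @return Integer count: DIFF has rho, u0, sigma; DIFF_R adds alpha and N
#'   carrying capacities; DIFF_RF further adds N fall rates.
#' @export
n_free_params <- function(model, n_regions, n_rho = 1) {
  model <- match.arg(model, MODEL_KINDS)
  switch(model,
         DIFF = n_rho + 2L,
         DIFF_R = n_rho + 3L + n_regions,
         DIFF_RF = n_rho + 3L + 2L * n_regions)
}

#' Origin-constrained R-squared
#'
#' Regression of observed on predicted constrained through the origin:
#' slope `b = sum(xy) / sum(x^2)` and `R2 = 1 - sum((y - bx)^2) / sum(y^2)`
#' (uncentered total sum of squares). The statistic reduces to the
#' squared uncentered correlation, so it is invariant to a common
#' positive rescaling and symmetric in its arguments; the slope is not
#' symmetric (`predicted` is always the regressor).
#'
#' @param predicted,observed Equal-length numeric vectors (length >= 2).
#' @return List with `r2` and `slope`.
#' @export
r2_origin <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 2)
  sxx <- sum(predicted^2)
  if (sxx == 0)
    stop("all-zero predictions: origin regression undefined", call. = FALSE)
  b <- sum(predicted * observed) / sxx
  list(r2 = 1 - sum((observed - b * predicted)^2) / sum(observed^2),
       slope = b)
}

#' Per-timepoint predicted-observed agreement
#'
#' Applies [r2_origin()] separately at each timepoint, optionally on
#' log10-transformed pairs (pairs where either value is non-positive are
#' dropped and counted).
#'
#' @param predicted Regions x timepoints matrix of model predictions (rows
#'   named by region, columns matching the observation time grid).
#' @param obs An [observation_set].
#' @param log_space Compare on log10 scale?
#' @return Data frame with columns `time`, `r2`, `slope`, `n_pairs`,
#'   `n_dropped`; `r2` is `NA` (with a message) when fewer than 2 pairs
#'   survive.
#' @export
per_timepoint_agreement <- function(predicted, obs, log_space = FALSE) {
  stopifnot(inherits(obs, "observation_set"))
  times <- attr(obs, "times")
  out <- lapply(seq_along(times), function(ti) {
    rec <- obs[obs$time == times[ti] & !is.na(obs$value), ]
    x <- predicted[match(rec$region, rownames(predicted)), ti]
    y <- rec$value
    dropped <- 0L
    if (log_space) {
      keep <- x > 0 & y > 0
      dropped <- sum(!keep)
      x <- log10(x[keep]); y <- log10(y[keep])
    }
    if (length(x) < 2 || all(x == 0)) {
      message(sprintf("timepoint %g: %d usable pair(s); R2 undefined",
                      times[ti], length(x)))
      return(data.frame(time = times[ti], r2 = NA_real_, slope = NA_real_,
                        n_pairs = length(x), n_dropped = dropped))
    }
    r <- r2_origin(x, y)
    data.frame(time = times[ti], r2 = r$r2, slope = r$slope,
               n_pairs = length(x), n_dropped = dropped)
  })
  do.call(rbind, out)
}

#' Model comparison table with Delta values
#'
#' Subtracts the per-criterion minimum from each model's WAIC/AIC/BIC/MSE
#' (so the best model scores 0), and attaches the paired standard error of
#' each Delta-WAIC computed from pointwise contributions, flagging models
#' whose WAIC distribution overlaps the best model's (|Delta| <= 2 paired
#' SE).
#'
#' @param metrics Named list, one element per model, each a list with an
#'   `rf_waic` object under `waic` and scalars `aic`, `bic`, `mse`.
#' @return Data frame with one row per model.
#' @export
delta_table <- function(metrics) {
  if (length(metrics) < 2)
    stop("need at least 2 models to compare", call. = FALSE)
  waics <- lapply(metrics, function(m) m$waic)
  n_obs <- vapply(waics, function(w) w$n_obs, 0)
  if (length(unique(n_obs)) != 1)
    stop("models were scored on different observation counts",
         call. = FALSE)
  wa <- vapply(waics, function(w) w$waic, 0)
  ai <- vapply(metrics, function(m) m$aic, 0)
  bi <- vapply(metrics, function(m) m$bic, 0)
  ms <- vapply(metrics, function(m) m$mse, 0)
  best <- which.min(wa)
  dse <- vapply(seq_along(waics), function(i) {
    d <- waics[[i]]$pointwise - waics[[best]]$pointwise
    sqrt(length(d) * stats::var(d))
  }, 0)
  data.frame(model = names(metrics),
             waic = wa, aic = ai, bic = bi, mse = ms,
             dwaic = wa - min(wa), daic = ai - min(ai),
             dbic = bi - min(bi), dmse = ms - min(ms),
             dwaic_se = dse,
             overlaps_best = (wa - min(wa)) <= 2 * dse,
             row.names = NULL)
}

#' Fit-quality metrics for a fitted model
#'
#' Convenience wrapper: WAIC from the stored pointwise log-likelihood,
#' AIC/BIC/MSE evaluated at the MAP draw.
#'
#' @param post An `rf_posterior`.
#' @param transport The transport operator used in the fit.
#' @param obs The observation set used in the fit.
#' @return List with `waic` (`rf_waic`), `aic`, `bic`, `mse`, `map`
#'   ([model_parameters]) and `predicted` (regions x timepoints matrix at
#'   the MAP).
#' @export
fit_metrics <- function(post, transport, obs) {
  stopifnot(inherits(post, "rf_posterior"))
  w <- waic(post$loglik_pointwise)
  mp <- map_estimate(post)
  ll <- log_likelihood(mp, transport, obs,
                       post$settings$rtol, post$settings$atol)
  traj <- simulate_pathology(mp, transport, attr(obs, "times"),
                             post$settings$rtol, post$settings$atol)
  oa <- obs_arrays(obs, rownames(transport$L))
  pred <- traj$u[cbind(oa$reg + 1L, oa$tix + 1L)]
  k <- n_free_params(post$model, length(post$region_ids), post$n_rho)
  ab <- aic_bic_mse(ll$total, k, length(oa$y), oa$y - pred)
  list(waic = w, aic = ab$aic, bic = ab$bic, mse = ab$mse, map = mp,
       predicted = traj$u, n_params = k)
}

#' Leave-one-timepoint-out evaluation
#'
#' Refits the model with one timepoint (by default the final one) excluded,
#' simulates through the held-out time at the MAP estimate, and scores
#' origin-constrained R-squared on (a) all observations including the
#' held-out ones and (b) the held-out records only.
#'
#' @param model Model kind.
#' @param transport A `transport_operator`.
#' @param obs An [observation_set] with at least 3 timepoints.
#' @param seeds Seed regions.
#' @param holdout_index 1-based index into the sorted timepoint grid
#'   (default: the last timepoint).
#' @param ... Passed to [fit_model()] (priors, sampler settings, seed).
#' @return List with `fit`, `map`, `r2_all`, `r2_holdout`, `holdout_time`,
#'   `predicted` and `holdout` (data frame of held-out records with
#'   predictions).
#' @export
leave_one_timepoint_out <- function(model, transport, obs, seeds,
                                    holdout_index = NULL, ...) {
  stopifnot(inherits(obs, "observation_set"))
  times <- attr(obs, "times")
  if (length(times) < 3)
    stop("leave-one-timepoint-out needs at least 3 timepoints",
         call. = FALSE)
  holdout_index <- holdout_index %||% length(times)
  if (holdout_index < 1 || holdout_index > length(times))
    stop("holdout_index out of range", call. = FALSE)
  t_hold <- times[holdout_index]
  train <- observation_set(obs[obs$time != t_hold, ],
                           attr(obs, "region_ids"))
  post <- fit_model(model, transport, train, seeds, ...)
  mp <- map_estimate(post)
  traj <- simulate_pathology(mp, transport, times)
  oa <- obs_arrays(obs, rownames(transport$L))
  pred <- traj$u[cbind(oa$reg + 1L, oa$tix + 1L)]
  is_hold <- oa$times[oa$tix + 1L] == t_hold
  r_all <- r2_origin(pred, oa$y)
  r_hold <- r2_origin(pred[is_hold], oa$y[is_hold])
  list(fit = post, map = mp, r2_all = r_all$r2, r2_holdout = r_hold$r2,
       holdout_time = t_hold, predicted = traj$u,
       holdout = data.frame(region = obs$region[is_hold],
                            time = obs$time[is_hold],
                            observed = oa$y[is_hold],
                            predicted = pred[is_hold]))
}
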