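# Bayesian estimation: likelihood, adaptive MCMC, diagnostics, KS filter.

#' Replicate-level observation set
#'
#' Long-format container of regional pathology measurements: one record per
#' region, timepoint and animal replicate. Replicate counts may vary by
#' timepoint.
#'
#' @param df Data frame with columns `region`, `time`, `replicate`, `value`
#'   (aliases `time_months` for `time` are accepted).
#' @param region_ids Reference region labels (e.g. from a [connectome]);
#'   every record's region must appear here.
#' @return An object of class `observation_set` (a validated data frame
#'   with a `times` attribute holding the sorted timepoint grid).
#' @export
observation_set <- function(df, region_ids) {
  df <- as.data.frame(df)
  if ("time_months" %in% names(df) && !"time" %in% names(df))
    names(df)[names(df) == "time_months"] <- "time"
  need <- c("region", "time", "replicate", "value")
  if (!all(need %in% names(df)))
    stop("observations need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$region), region_ids)
  if (length(bad))
    stop("unknown region label(s) in observations: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.numeric(df$time) || !is.numeric(df$value))
    stop("time and value must be numeric", call. = FALSE)
  structure(df[need], class = c("observation_set", "data.frame"),
            region_ids = region_ids,
            times = sort(unique(df$time)))
}

obs_arrays <- function(obs, region_ids) {
  keep <- !is.na(obs$value)
  n_na <- sum(!keep)
  if (n_na > 0) obs <- obs[keep, ]
  times <- sort(unique(obs$time))
  list(y = as.numeric(obs$value),
       reg = match(obs$region, region_ids) - 1L,
       tix = match(obs$time, times) - 1L,
       times = times, n_missing = n_na)
}

#' Gaussian observation log-likelihood
#'
#' Sums `log Normal(y | u_region(t; theta), sigma^2)` over all records,
#' with the trajectory from [simulate_pathology()]. Records with missing
#' values are skipped.
#'
#' @param params A [model_parameters] object.
#' @param transport A `transport_operator`.
#' @param obs An [observation_set].
#' @param rtol,atol Solver tolerances.
#' @return List with `total` (scalar log-likelihood; `-Inf` on integration
#'   failure, with a warning) and `pointwise` (per-record values).
#' @export
log_likelihood <- function(params, transport, obs, rtol = 1e-6,
                           atol = 1e-9) {
  stopifnot(inherits(obs, "observation_set"))
  ids <- rownames(transport$L)
  oa <- obs_arrays(obs, ids)
  traj <- tryCatch(
    simulate_pathology(params, transport, oa$times, rtol, atol),
    error = function(e) e)
  if (inherits(traj, "error")) {
    warning("integration failed during likelihood evaluation: ",
            conditionMessage(traj), call. = FALSE)
    return(list(total = -Inf, pointwise = rep(NA_real_, length(oa$y))))
  }
  mu <- traj$u[cbind(oa$reg + 1L, oa$tix + 1L)]
  pw <- stats::dnorm(oa$y, mu, params$sigma, log = TRUE)
  list(total = sum(pw), pointwise = pw)
}

#' Fit a spread model by adaptive MCMC
#'
#' Samples the posterior of all free parameters under the given priors
#' using an adaptive Metropolis-within-Gibbs sampler: positive-support
#' parameters are updated on the log scale, and per-coordinate proposal
#' scales adapt in batches toward the target acceptance rate during warmup
#' only. Chains are initialised from a posterior-mode search (`init =
#' "optimize"`, default) with overdispersed jitter, or from prior draws.
#' Pointwise log-likelihoods are stored for WAIC; the Gelman-Rubin
#' statistic is computed per parameter and a warning lists any parameter
#' with R-hat above 1.05.
#'
#' @param model One of `"DIFF"`, `"DIFF_R"`, `"DIFF_RF"`.
#' @param transport A `transport_operator`.
#' @param obs An [observation_set] (may contain zero rows, in which case
#'   the posterior equals the prior).
#' @param seeds Seed regions (labels or indices into the transport
#'   operator's region order).
#' @param priors A `prior_spec`; defaults to [default_priors()].
#' @param chains,warmup,samples,thin MCMC layout: retained draws per chain
#'   = `samples`, taken every `thin` sweeps after `warmup` adaptive sweeps.
#' @param target_accept Per-coordinate acceptance target of the adaptive
#'   random-walk kernel (0.44 is standard for coordinate-wise updates;
#'   gradient-based samplers of this model family use 0.65).
#' @param rng_seed Master seed; all chains derive from it deterministically.
#' @param init `"optimize"` or `"prior"`.
#' @param init_jitter Sd of the overdispersion jitter applied to each
#'   chain's transformed starting point.
#' @param rtol,atol Solver tolerances used inside the likelihood.
#' @return An object of class `rf_posterior`.
#' @export
fit_model <- function(model, transport, obs, seeds,
                      priors = NULL, chains = 4, warmup = 1000,
                      samples = 1000, thin = 1, target_accept = 0.44,
                      rng_seed = 1, init = c("optimize", "prior"),
                      init_jitter = 0.25, rtol = 1e-6, atol = 1e-9) {
  model <- match.arg(model, MODEL_KINDS)
  init <- match.arg(init)
  stopifnot(inherits(transport, "transport_operator"), chains >= 1)
  ids <- rownames(transport$L)
  N <- length(ids)
  n_rho <- if (is.null(transport$L2)) 1L else 2L
  if (is.null(priors)) priors <- default_priors(model, N, n_rho)
  fp <- flatten_priors(priors, model, N, n_rho)
  P <- length(fp$mu)
  positive <- fp$trunc  # sampled on log scale iff positive support
  Ls <- if (n_rho == 2) list(transport$L, transport$L2) else
    list(transport$L)
  seeds_ix <- resolve_seeds(seeds, ids) - 1L
  oa <- obs_arrays(obs, ids)
  code <- model_code(model)

  logpost_t <- function(x) {
    th <- ifelse(positive == 1L, exp(x), x)
    r <- .rf_logpost(th, code, Ls, seeds_ix, oa$y, oa$reg, oa$tix, oa$times,
                     rtol, atol, fp$mu, fp$sd, fp$trunc, positive)
    r$logprior + r$loglik + sum(x[positive == 1L])
  }

  set.seed(rng_seed)
  # deterministic central starting point, then optional mode search
  th0 <- ifelse(fp$trunc == 1L, pmax(fp$mu, 0) + 0.5 * fp$sd, fp$mu)
  x0 <- ifelse(positive == 1L, log(th0), th0)
  if (init == "optimize" && length(oa$y) > 0) {
    opt <- tryCatch(
      stats::optim(x0, function(x) -logpost_t(x), method = "L-BFGS-B",
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value)) x0 <- opt$par
  }

  draws <- array(NA_real_, dim = c(samples, P, chains),
                 dimnames = list(NULL, fp$names, NULL))
  M <- length(oa$y)
  ll_pw <- vector("list", chains)
  ll <- lp <- matrix(NA_real_, samples, chains)
  acc <- matrix(NA_real_, P, chains)
  for (ch in seq_len(chains)) {
    repeat {
      xs <- x0 + stats::rnorm(P, 0, init_jitter)
      if (is.finite(logpost_t(xs))) break
    }
    th_start <- ifelse(positive == 1L, exp(xs), xs)
    res <- .rf_mwg_chain(th_start, code, Ls, seeds_ix, oa$y, oa$reg, oa$tix,
                         oa$times, rtol, atol, fp$mu, fp$sd, fp$trunc,
                         positive, warmup, samples, thin, target_accept,
                         numeric(0))
    draws[, , ch] <- res$draws
    ll_pw[[ch]] <- res$loglik_pointwise
    ll[, ch] <- res$loglik
    lp[, ch] <- res$logprior
    acc[, ch] <- res$accept_rate
  }
  rhat <- vapply(seq_len(P),
                 function(j) gelman_rubin(draws[, j, , drop = TRUE]), 0)
  names(rhat) <- fp$names
  bad <- names(rhat)[is.finite(rhat) & rhat > 1.05]
  if (length(bad) && chains >= 2)
    warning("convergence warning: R-hat > 1.05 for ",
            paste(utils::head(bad, 12), collapse = ", "),
            if (length(bad) > 12) sprintf(" (+%d more)", length(bad) - 12),
            call. = FALSE)
  structure(list(
    draws = draws, param_names = fp$names, rhat = rhat,
    loglik_pointwise = do.call(rbind, ll_pw), loglik = as.vector(ll),
    logprior = as.vector(lp), accept_rate = acc,
    model = model, region_ids = ids, seeds = seeds, n_rho = n_rho,
    priors_flat = fp, obs_times = oa$times, n_obs = M,
    settings = list(chains = chains, warmup = warmup, samples = samples,
                    thin = thin, target_accept = target_accept,
                    rng_seed = rng_seed, rtol = rtol, atol = atol)),
    class = "rf_posterior")
}

#' @export
print.rf_posterior <- function(x, ...) {
  cat(sprintf("%s posterior: %d params, %d chains x %d draws, max R-hat %.3f\n",
              x$model, length(x$param_names), dim(x$draws)[3],
              dim(x$draws)[1], max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Pooled posterior draws as a matrix
#'
#' @param post An `rf_posterior`.
#' @return Matrix (chains x samples) rows by parameter columns.
#' @export
posterior_matrix <- function(post) {
  stopifnot(inherits(post, "rf_posterior"))
  d <- post$draws
  out <- do.call(rbind, lapply(seq_len(dim(d)[3]),
                               function(ch) d[, , ch, drop = TRUE]))
  colnames(out) <- post$param_names
  out
}

# Regional posterior summaries: matrix of draws for beta[i] / gamma[i].
regional_draws <- function(post, which = c("beta", "gamma")) {
  which <- match.arg(which)
  m <- posterior_matrix(post)
  cols <- grep(paste0("^", which, "\\["), colnames(m))
  if (!length(cols)) stop("posterior has no ", which, " parameters",
                          call. = FALSE)
  out <- m[, cols, drop = FALSE]
  colnames(out) <- post$region_ids
  out
}

#' Maximum a posteriori estimate over retained draws
#'
#' Returns the retained draw maximising log-prior + log-likelihood,
#' repackaged as a [model_parameters] object.
#'
#' @param post An `rf_posterior`.
#' @return A [model_parameters] object with attribute `log_posterior`.
#' @export
map_estimate <- function(post) {
  stopifnot(inherits(post, "rf_posterior"))
  lp <- post$logprior + post$loglik
  if (!length(lp)) stop("no draws", call. = FALSE)
  ix <- which.max(lp)
  th <- posterior_matrix(post)[ix, ]
  draw_to_params(post, th, log_posterior = lp[ix])
}

draw_to_params <- function(post, th, log_posterior = NULL) {
  N <- length(post$region_ids)
  nm <- post$param_names
  getv <- function(pat) unname(th[grep(pat, nm)])
  rho <- getv("^rho1?$")
  rho2 <- if (post$n_rho == 2) unname(th[nm == "rho2"]) else NULL
  p <- model_parameters(
    model = post$model, rho = rho, rho_secondary = rho2,
    alpha = if (post$model != "DIFF") unname(th[nm == "alpha"]) else NULL,
    beta = if (post$model != "DIFF") getv("^beta\\[") else NULL,
    gamma = if (post$model == "DIFF_RF") getv("^gamma\\[") else NULL,
    u0 = unname(th[nm == "u0"]), sigma = unname(th[nm == "sigma"]),
    seeds = post$seeds)
  attr(p, "log_posterior") <- log_posterior
  p
}

#' Gelman-Rubin split R-hat
#'
#' Classic split-chain potential scale reduction factor: each chain is
#' split in half, and R-hat compares between- to within-half variances.
#'
#' @param draws Matrix (iterations x chains) or list of equal-length
#'   numeric vectors, for a single parameter.
#' @return Scalar R-hat (>= 1 up to floating point error).
#' @export
gelman_rubin <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  if (ncol(draws) < 2)
    stop("R-hat needs at least 2 chains", call. = FALSE)
  if (nrow(draws) < 10)
    stop("R-hat needs at least 10 draws per chain", call. = FALSE)
  n2 <- floor(nrow(draws) / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(draws)), function(ch) {
    cbind(draws[seq_len(n2), ch], draws[n2 + seq_len(n2), ch])
  }))
  m <- ncol(halves); n <- nrow(halves)
  W <- mean(apply(halves, 2, stats::var))
  B <- n * stats::var(colMeans(halves))
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior-update filter (one-sample Kolmogorov-Smirnov)
#'
#' Compares posterior draws of one parameter against its analytic prior
#' CDF. A parameter counts as updated when the KS p-value falls below
#' `alpha`; parameters whose posteriors were not updated from the prior
#' carry no information and are excluded from downstream biological
#' analyses.
#'
#' @param draws Numeric vector of posterior draws (pooled across chains).
#' @param prior An `rf_prior`.
#' @param alpha Significance threshold (default 0.001).
#' @return List with `updated` (logical), `p_value` and `statistic`.
#' @export
posterior_updated <- function(draws, prior, alpha = 0.001) {
  stopifnot(length(draws) > 0, inherits(prior, "rf_prior"))
  kt <- suppressWarnings(
    stats::ks.test(draws, function(q) prior_cdf(prior, q)))
  list(updated = kt$p.value < alpha, p_value = kt$p.value,
       statistic = unname(kt$statistic))
}

#' Apply the posterior-update filter to all regional parameters
#'
#' @param post An `rf_posterior`.
#' @param which `"beta"` or `"gamma"`.
#' @param alpha KS significance threshold.
#' @return Data frame with columns `region`, `updated`, `p_value`,
#'   `posterior_mean`.
#' @export
regional_update_filter <- function(post, which = c("beta", "gamma"),
                                   alpha = 0.001) {
  which <- match.arg(which)
  d <- regional_draws(post, which)
  pri <- post$priors_flat$priors[grep(paste0("^", which, "\\["),
                                      post$priors_flat$names)]
  res <- lapply(seq_len(ncol(d)), function(i)
    posterior_updated(d[, i], pri[[i]], alpha))
  data.frame(region = colnames(d),
             updated = vapply(res, `[[`, TRUE, "updated"),
             p_value = vapply(res, `[[`, 0, "p_value"),
             posterior_mean = colMeans(d),
             row.names = NULL)
}
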