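# Prior descriptors: Normal and zero-truncated Normal.

#' Prior distribution descriptors
#'
#' `prior_normal(mu, sd)` is a Normal prior on the whole real line;
#' `prior_truncnorm(mu, sd)` is a Normal truncated to (0, Inf). These are
#' the two families used for all model parameters.
#'
#' @param mu Location of the untruncated Normal.
#' @param sd Scale, > 0.
#' @return An object of class `rf_prior`.
#' @export
prior_normal <- function(mu, sd) {
  stopifnot(sd > 0)
  structure(list(type = "normal", mu = mu, sd = sd), class = "rf_prior")
}

#' @rdname prior_normal
#' @export
prior_truncnorm <- function(mu, sd) {
  stopifnot(sd > 0)
  structure(list(type = "truncnorm", mu = mu, sd = sd), class = "rf_prior")
}

#' @export
print.rf_prior <- function(x, ...) {
  cat(sprintf("%s(mu = %g, sd = %g)\n",
              if (x$type == "truncnorm") "Normal+(0,Inf)" else "Normal",
              x$mu, x$sd))
  invisible(x)
}

#' Prior density, CDF and sampling
#'
#' @param prior An `rf_prior`.
#' @param x,q,n Evaluation points / sample size.
#' @param log Return log density?
#' @return Numeric vector.
#' @export
prior_density <- function(prior, x, log = FALSE) {
  stopifnot(inherits(prior, "rf_prior"))
  if (prior$type == "normal") return(stats::dnorm(x, prior$mu, prior$sd, log))
  lz <- stats::pnorm(0, prior$mu, prior$sd, lower.tail = FALSE, log.p = TRUE)
  ld <- stats::dnorm(x, prior$mu, prior$sd, log = TRUE) - lz
  ld[x <= 0] <- -Inf
  if (log) ld else exp(ld)
}

#' @rdname prior_density
#' @export
prior_cdf <- function(prior, q) {
  stopifnot(inherits(prior, "rf_prior"))
  if (prior$type == "normal") return(stats::pnorm(q, prior$mu, prior$sd))
  z0 <- stats::pnorm(0, prior$mu, prior$sd)
  p <- (stats::pnorm(q, prior$mu, prior$sd) - z0) / (1 - z0)
  p[q <= 0] <- 0
  pmin(pmax(p, 0), 1)
}

#' @rdname prior_density
#' @export
prior_sample <- function(prior, n) {
  stopifnot(inherits(prior, "rf_prior"))
  if (prior$type == "normal") return(stats::rnorm(n, prior$mu, prior$sd))
  # inverse-CDF sampling of the truncated Normal
  z0 <- stats::pnorm(0, prior$mu, prior$sd)
  u <- stats::runif(n, z0, 1)
  stats::qnorm(u, prior$mu, prior$sd)
}

#' Default priors for a model class
#'
#' Returns the package-default prior specification: transport and
#' aggregation rates and `DIFF_RF` regional parameters get half-scale
#' truncated Normals; `DIFF_R` carrying capacities are unconstrained
#' Normals; the `DIFF` transport rate is a wide positive Normal
#' (`Normal+(50, 10)`) and its seed initial value has a considerably wider
#' prior than in the rise models, since pure diffusion must carry enough
#' mass from the seed to cover the network.
#'
#' @param model One of `"DIFF"`, `"DIFF_R"`, `"DIFF_RF"`.
#' @param n_regions Number of regions (length of regional parameter
#'   vectors).
#' @param n_rho Number of transport rates (2 for bidirectional transport).
#' @return A named list of `rf_prior` objects (class `prior_spec`), with
#'   `beta`/`gamma` entries recycled across regions at flattening time.
#' @export
default_priors <- function(model, n_regions = NULL, n_rho = 1) {
  model <- match.arg(model, MODEL_KINDS)
  p <- switch(model,
    DIFF = list(rho = prior_truncnorm(50, 10),
                u0 = prior_truncnorm(0, 50),
                sigma = prior_truncnorm(0, 0.1)),
    DIFF_R = list(rho = prior_truncnorm(0, 0.1),
                  alpha = prior_truncnorm(0, 0.1),
                  u0 = prior_truncnorm(0, 1),
                  sigma = prior_truncnorm(0, 0.1),
                  beta = prior_normal(0, 1)),
    DIFF_RF = list(rho = prior_truncnorm(0, 0.1),
                   alpha = prior_truncnorm(0, 0.1),
                   u0 = prior_truncnorm(0, 1),
                   sigma = prior_truncnorm(0, 0.1),
                   beta = prior_truncnorm(0, 0.1),
                   gamma = prior_truncnorm(0, 0.1)))
  if (n_rho == 2) p$rho <- list(p$rho, p$rho)
  structure(p, class = "prior_spec", model = model, n_regions = n_regions)
}

#' Weakly-informative priors for synthetic studies
#'
#' Unit-scale truncated Normals for all positive parameters (and unit
#' Normals for `DIFF_R` carrying capacities), matching the scale of the
#' synthetic-study generator. The `DIFF` seed value keeps a wide prior.
#'
#' @inheritParams default_priors
#' @return A `prior_spec`.
#' @export
synthetic_priors <- function(model, n_regions = NULL, n_rho = 1) {
  model <- match.arg(model, MODEL_KINDS)
  p <- switch(model,
    DIFF = list(rho = prior_truncnorm(0, 2),
                u0 = prior_truncnorm(0, 50),
                sigma = prior_truncnorm(0, 0.5)),
    DIFF_R = list(rho = prior_truncnorm(0, 2),
                  alpha = prior_truncnorm(0, 2),
                  u0 = prior_truncnorm(0, 1),
                  sigma = prior_truncnorm(0, 0.5),
                  beta = prior_normal(0, 1)),
    DIFF_RF = list(rho = prior_truncnorm(0, 2),
                   alpha = prior_truncnorm(0, 2),
                   u0 = prior_truncnorm(0, 1),
                   sigma = prior_truncnorm(0, 0.5),
                   beta = prior_truncnorm(0, 1),
                   gamma = prior_truncnorm(0, 1)))
  if (n_rho == 2) p$rho <- list(p$rho, p$rho)
  structure(p, class = "prior_spec", model = model, n_regions = n_regions)
}

#' Moment-matched empirical priors from a previous posterior
#'
#' Builds truncated-Normal priors for the global parameters from the
#' posterior draws of an earlier fit (matching posterior mean and sd),
#' leaving regional priors at their supplied defaults. This mirrors
#' refitting a second dataset with global priors set from the first.
#'
#' @param posterior An `rf_posterior` from [fit_model()].
#' @param base A `prior_spec` providing the regional (and any unmatched)
#'   priors.
#' @return A `prior_spec` with updated global entries.
#' @export
empirical_priors <- function(posterior, base) {
  stopifnot(inherits(posterior, "rf_posterior"),
            inherits(base, "prior_spec"))
  draws <- posterior_matrix(posterior)
  for (nm in intersect(c("rho", "alpha", "u0", "sigma"), names(base))) {
    col <- if (nm == "rho" && !nm %in% colnames(draws)) "rho1" else nm
    if (!col %in% colnames(draws)) next
    m <- mean(draws[, col]); s <- stats::sd(draws[, col])
    base[[nm]] <- if (inherits(base[[nm]], "rf_prior") &&
                      base[[nm]]$type == "normal")
      prior_normal(m, s) else prior_truncnorm(m, s)
  }
  base
}

# Flatten a prior_spec into the sampler's coordinate order:
# rho (xK), alpha, u0, sigma, beta (xN), gamma (xN).
flatten_priors <- function(priors, model, n_regions, n_rho = 1) {
  stopifnot(inherits(priors, "prior_spec") || is.list(priors))
  get1 <- function(nm) {
    p <- priors[[nm]]
    if (is.null(p)) stop("prior spec is missing '", nm, "'", call. = FALSE)
    p
  }
  rp <- priors$rho
  rho_list <- if (inherits(rp, "rf_prior")) rep(list(rp), n_rho) else rp
  if (length(rho_list) != n_rho)
    stop("need ", n_rho, " rho prior(s)", call. = FALSE)
  out <- list(); nms <- character(0)
  add <- function(p, nm) {
    out[[length(out) + 1]] <<- p
    nms[length(nms) + 1] <<- nm
  }
  for (k in seq_len(n_rho))
    add(rho_list[[k]], if (n_rho == 1) "rho" else paste0("rho", k))
  if (model != "DIFF") add(get1("alpha"), "alpha")
  add(get1("u0"), "u0")
  add(get1("sigma"), "sigma")
  expand_regional <- function(nm) {
    p <- get1(nm)
    plist <- if (inherits(p, "rf_prior")) rep(list(p), n_regions) else p
    if (length(plist) != n_regions)
      stop("'", nm, "' prior list must have one entry per region",
           call. = FALSE)
    for (i in seq_len(n_regions))
      add(plist[[i]], sprintf("%s[%d]", nm, i))
  }
  if (model != "DIFF") expand_regional("beta")
  if (model == "DIFF_RF") expand_regional("gamma")
  list(mu = vapply(out, function(p) p$mu, 0),
       sd = vapply(out, function(p) p$sd, 0),
       trunc = vapply(out, function(p) as.integer(p$type == "truncnorm"), 0L),
       names = nms, priors = out)
}
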