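# Shared fixtures: tiny connectomes and observation sets built in code.

toy_connectome <- function(n = 2, seed = 1) {
  if (n == 1) {
    W <- matrix(0, 1, 1, dimnames = list("A", "A"))
    return(connectome(W))
  }
  withr::with_seed(seed, {
    W <- matrix(stats::runif(n * n), n, n)
    diag(W) <- 0
    ids <- paste0("N", seq_len(n))
    dimnames(W) <- list(ids, ids)
    connectome(W, coords = matrix(stats::runif(3 * n, 0, 10), n, 3))
  })
}

isolated_transport <- function() {
  make_transport(toy_connectome(1), "retrograde")
}

# observation set with hand-set residual structure on a single region
single_region_obs <- function(values, times, conn = toy_connectome(1)) {
  observation_set(
    data.frame(region = conn$region_ids[1], time = rep(times, 1),
               replicate = 1, value = values),
    conn$region_ids)
}

# fixed-step RK4 reference integrator for single-region models
rk4_reference <- function(rhs, y0, t_end, dt = 1e-4) {
  n_steps <- ceiling(t_end / dt)
  y <- y0
  t <- 0
  for (i in seq_len(n_steps)) {
    h <- min(dt, t_end - t)
    if (h <= 0) break
    k1 <- rhs(t, y)
    k2 <- rhs(t + h / 2, y + h / 2 * k1)
    k3 <- rhs(t + h / 2, y + h / 2 * k2)
    k4 <- rhs(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

logistic_closed_form <- function(alpha, beta, u0, t) {
  beta / (1 + ((beta - u0) / u0) * exp(-alpha * beta * t))
}
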