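# Shared fixtures and independent oracles, all generated in code.

hbar <- qensmem::qens_constants$hbar

# Monte-Carlo random walk in a reflecting sphere: independent oracle for the
# spectral intermediate scattering function.  Walkers start uniform in the
# sphere; a step leaving the sphere is mirrored at the surface.  Returns the
# self-ISF Re<exp(iQ dz)> and its standard error at the requested times.
mc_sphere_isf <- function(q, radius, d, times, n_walkers = 2e4,
                          n_steps = 400, seed = 1) {
  set.seed(seed)
  t_max <- max(times)
  dt <- t_max / n_steps
  # uniform start positions
  u <- matrix(rnorm(3 * n_walkers), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pos <- u * radius * runif(n_walkers)^(1 / 3)
  z0 <- pos[, 3]
  step_sd <- sqrt(2 * d * dt)
  snap_idx <- vapply(times, function(t) as.integer(max(1, round(t / dt))), integer(1))
  out <- matrix(NA_real_, length(times), 2)
  for (s in seq_len(n_steps)) {
    pos <- pos + matrix(rnorm(3 * n_walkers, sd = step_sd), ncol = 3)
    r <- sqrt(rowSums(pos^2))
    hit <- r > radius
    if (any(hit)) pos[hit, ] <- pos[hit, ] * (2 * radius - r[hit]) / r[hit]
    k <- which(snap_idx == s)
    if (length(k) > 0) {
      c_q <- cos(q * (pos[, 3] - z0))
      for (j in k) out[j, ] <- c(mean(c_q), sd(c_q) / sqrt(n_walkers))
    }
  }
  data.frame(t = times, isf = out[, 1], se = out[, 2])
}

# Small fast grid for fitting tests (8 Q groups, 181 energy points)
small_grid <- function() {
  qensmem::make_instrument_grid(n_e = 181,
                                q_values = qensmem::default_q_grid(8))
}

# Noiseless simulated datasets are deterministic and reused across tests
sim_cache <- new.env(parent = emptyenv())

noiseless_run <- function(name) {
  if (is.null(sim_cache[[name]])) {
    sim <- qensmem::generate_dataset(qensmem::preset(name, noise_level = 0))
    sim_cache[[name]] <- qensmem::run_pipeline(sim)
  }
  sim_cache[[name]]
}
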