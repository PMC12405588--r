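# Random circuit parameterisations and an independent fixed-step oracle for
# solver validation.

random_spec <- function(seed) {
  set.seed(seed)
  spec <- circuit_spec(w_iLNa = runif(1, 0.2, 2),
                       rmax_iLNa = runif(1, 10, 25),
                       i_Hb = runif(1, 0, 12),
                       stimulus_amplitude = runif(1, 0.5, 4),
                       k_ex = runif(1, 1, 4),
                       tau = runif(7, 0.5, 20),
                       V0 = c(0, runif(6, 5, 25)))
  mask <- matrix(runif(49) < 0.3, 7, 7); diag(mask) <- FALSE
  spec$A_ex[mask] <- pmax(spec$A_ex[mask], runif(sum(mask), 0, 1.5))
  mask2 <- matrix(runif(49) < 0.3, 7, 7); diag(mask2) <- FALSE
  spec$A_in[mask2] <- pmax(spec$A_in[mask2], runif(sum(mask2), 0, 2))
  spec
}

# explicit-Euler endpoint with the rate equation written out independently
euler_endpoint <- function(sp, dur, dt = 1e-3) {
  r <- numeric(7)
  stim <- c(sp$stimulus_amplitude, numeric(6))
  for (s in seq_len(round(dur / dt))) {
    dr <- (-sp$V0 - r + stim + sp$tonic_input +
             sp$k_ex * (sp$rmax - r) * (sp$A_ex %*% r) -
             sp$A_in %*% r) / sp$tau
    dr[r < 1e-9 & dr < 0] <- 0
    r <- pmax(r + dt * dr, 0)
  }
  as.numeric(r)
}

# first n random specs whose stimulated dynamics settle to a fixed point
convergent_specs <- function(start_seed, n) {
  out <- list()
  seed <- start_seed
  while (length(out) < n) {
    sp <- random_spec(seed)
    st <- steady_state(sp, t_cap = 600)
    if (st$converged) out[[length(out) + 1]] <- sp
    seed <- seed + 1
  }
  out
}
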