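# Small configurations used across tests. Durations and grids are kept tiny:
# unit tests probe rules, not emergent dynamics.

tiny_cfg <- function(...) {
  sim_config(grid_width = 15, grid_height = 15, duration = 2, seed = 42,
             record_every = 1, ...)
}

# Dense direct solve of the same discretization used by the relaxation
# solver: D lap(C) - decay*C + source = 0, zero-flux edges, Dirichlet at
# vessel sites. Independent oracle (base solve(), no shared code path).
dense_solve <- function(n, D, dx, vessel_sites, dirichlet, decay = 0,
                        source = 0) {
  N <- n * n
  decay <- rep(decay, length.out = N)
  source <- rep(source, length.out = N)
  A <- matrix(0, N, N)
  rhs <- numeric(N)
  Dd <- D / dx^2
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      s <- i + (j - 1L) * n
      if (s %in% vessel_sites) {
        A[s, s] <- 1
        rhs[s] <- dirichlet
        next
      }
      nbs <- c(if (i > 1) s - 1L, if (i < n) s + 1L,
               if (j > 1) s - n, if (j < n) s + n)
      A[s, s] <- -length(nbs) * Dd - decay[s]
      for (q in nbs) A[s, q] <- A[s, q] + Dd
      rhs[s] <- -source[s]
    }
  }
  matrix(solve(A, rhs), n, n)
}
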