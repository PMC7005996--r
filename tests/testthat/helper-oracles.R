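# Shared fixtures and independent oracles used across test files.

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# Stationary law of a birth-death chain with constant birth rate g
# (zero at M-1) and death rate k*n: truncated Poisson(g/k).
truncated_poisson <- function(mean, M) {
  w <- dpois(0:(M - 1), mean)
  w / sum(w)
}

# Mean-field oracle for the slow-promoter (nonadiabatic) limit of MISA:
# conditional on the 16 joint promoter states, each mRNA is an
# independent truncated Poisson at its synthesis level; the promoter
# chain uses binding propensities h * E[n^2 | state] / 2. Returns the
# marginal mRNA distribution of gene X.
misa_slow_mixture_marginal <- function(params, M) {
  levels <- logic_levels(misa_motif_id())
  gx <- ifelse(levels == 1, params$g_hi_x, params$g_lo)
  gy <- ifelse(levels == 1, params$g_hi_y, params$g_lo)
  mom <- function(g) {
    w <- truncated_poisson(g / params$k, M)
    n <- 0:(M - 1)
    list(w = w, m2 = sum(n^2 * w))
  }
  momx <- lapply(gx, mom)
  momy <- lapply(gy, mom)
  prom_moves <- list(c(0, 1, NA), c(1, 0, NA), c(0, 2, NA), c(2, 0, NA),
                     c(1, 3, NA), c(3, 1, NA), c(2, 3, NA), c(3, 2, NA))
  rate_for <- function(from, to, bind_self, bind_cross) {
    key <- paste(from, to)
    switch(key,
      "0 1" = bind_self, "1 0" = params$f_a,
      "0 2" = bind_cross, "2 0" = params$f_r,
      "1 3" = bind_cross, "3 1" = params$f_r,
      "2 3" = bind_self, "3 2" = params$f_a)
  }
  Q <- matrix(0, 16, 16)
  for (sx in 0:3) for (sy in 0:3) {
    from <- sy + 4 * sx + 1
    bsx <- params$h_a * momx[[sx + 1]]$m2 / 2
    bcx <- params$h_r * momy[[sy + 1]]$m2 / 2
    bsy <- params$h_a * momy[[sy + 1]]$m2 / 2
    bcy <- params$h_r * momx[[sx + 1]]$m2 / 2
    for (mv in prom_moves) {
      if (sx == mv[1]) {
        to <- sy + 4 * mv[2] + 1
        Q[to, from] <- Q[to, from] + rate_for(mv[1], mv[2], bsx, bcx)
      }
      if (sy == mv[1]) {
        to <- mv[2] + 4 * sx + 1
        Q[to, from] <- Q[to, from] + rate_for(mv[1], mv[2], bsy, bcy)
      }
    }
  }
  diag(Q) <- diag(Q) - colSums(Q)
  w <- solve(rbind(Q[-16, ], rep(1, 16)), c(rep(0, 15), 1))
  marg <- numeric(M)
  for (sx in 0:3) for (sy in 0:3) {
    marg <- marg + w[sy + 4 * sx + 1] * momx[[sx + 1]]$w
  }
  marg
}

# Random kinetic parameters inside the fast (adiabatic) regime.
random_fast_params <- function() {
  kinetic_params(
    g_hi_x = runif(1, 0.8, 1.4), g_hi_y = runif(1, 0.8, 1.4),
    h_a = 10^runif(1, 1, log10(500)), f_a = 10^runif(1, 1, 5),
    h_r = 10^runif(1, 1, log10(500)), f_r = 10^runif(1, 1, 5)
  )
}

# Memoized expensive fixtures, shared across test files.
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small fast-regime MISA quasipotential shape-space (M = 21) used by
# shape-space interpretation and trajectory tests.
small_misa_space <- function() {
  fixture("small_misa_space", {
    grid <- misa_grid(g_hi = c(0.9, 1.3),
                      h_a = c(20, 400), f_a = c(20, 2e4),
                      h_r = c(20, 400), f_r = c(20, 2e4))
    lib <- compute_landscape_library(grid, "quasipotential")
    fit_shape_space(lib, 3)
  })
}
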