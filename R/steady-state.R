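#' Solve the chemical master equation for its stationary distribution
#'
#' The stationary distribution is the normalized null vector of the
#' generator K. It is computed by fixing the last state's probability,
#' solving the reduced sparse linear system with a banded LU
#' factorization (the frozen state linearization bounds the bandwidth by
#' 16 M), and renormalizing. The contract is the residual bound, not the
#' algorithm: `max|K pi|` relative to the generator scale must not
#' exceed `tol_residual`. Tiny negative entries (round-off) are clipped
#' to zero before renormalization; negatives beyond `tol_negative`
#' indicate solver failure and raise an error.
#'
#' The solve fixes the probability of an anchor state to one, so its
#' accuracy depends on the anchor carrying non-negligible stationary
#' mass (a vanishing anchor makes the ratio vector overflow). The
#' anchor is therefore chosen from a mean-field estimate of the
#' promoter-state chain (binding propensities averaged over the
#' conditional Poisson copy-number law), with the remaining promoter
#' combinations as fallbacks; each candidate is accepted only if the
#' solution is finite, nonnegative and meets the residual bound.
#'
#' @param K A [build_rate_matrix()] result (or a raw `dgCMatrix`
#'   generator plus `M`).
#' @param M Copy-number states per gene; taken from `K` when available.
#' @param tol_residual Relative residual bound (default 1e-8).
#' @param tol_negative Most negative entry tolerated before erroring
#'   (default -1e-12).
#' @param anchor Optional 1-based index of the state whose probability
#'   is fixed during the linear solve; by default chosen automatically.
#' @return A `stationary_distribution`: list with `pi` (length-N
#'   probability vector), `residual` (absolute), `residual_rel`, and `M`.
#' @examples
#' sol <- solve_stationary(build_rate_matrix(misa_model(M = 6)))
#' sum(sol$pi)
#' @export
solve_stationary <- function(K, M = NULL, tol_residual = 1e-8, tol_negative = -1e-12,
                             anchor = NULL) {
  model <- NULL
  if (inherits(K, "cme_rate_matrix")) {
    model <- K$model
    M <- K$M
    K <- K$K
  }
  if (is.null(M)) abort("`M` is required when passing a raw generator.",
                        class = "coexland_error_args")
  N <- ncol(K)
  candidates <- if (!is.null(anchor)) as.integer(anchor) else anchor_candidates(model, M, N)
  Tm <- as(K, "TsparseMatrix")
  scale <- max(abs(Matrix::diag(K)))
  last_err <- NULL
  for (j0 in candidates) {
    res <- tryCatch(
      solve_anchored(K, Tm, N, M, j0, tol_residual, tol_negative, scale),
      coexland_error_solver = function(e) e
    )
    if (!inherits(res, "condition")) return(res)
    last_err <- res
  }
  stop(last_err)
}

# Candidate anchors: for each joint promoter state, the copy-number
# pair at the conditional Poisson means, ordered by the mean-field
# promoter-chain weight.
anchor_candidates <- function(model, M, N) {
  if (is.null(model)) return(unique(c(N, 1L)))
  g <- synthesis_rates(model)
  k <- model$params$k
  w <- promoter_meanfield_weights(model)
  sx <- (seq_len(16L) - 1L) %/% 4L
  sy <- (seq_len(16L) - 1L) %% 4L
  nx <- pmin(M - 1L, round(g$x[sx + 1L] / k))
  ny <- pmin(M - 1L, round(g$y[sy + 1L] / k))
  idx <- as.integer(sy + 4L * sx + 16L * (ny + M * nx)) + 1L
  unique(c(idx[order(w, decreasing = TRUE)], N))
}

# Mean-field stationary weights of the 16 joint promoter states:
# binding propensities h * E[n^2 | promoter state] / 2 with n at its
# conditional truncated-Poisson law.
promoter_meanfield_weights <- function(model) {
  p <- model$params
  M <- model$M
  g <- synthesis_rates(model)
  m2 <- function(gs) {
    w <- stats::dpois(0:(M - 1), gs / p$k)
    w <- w / sum(w)
    sum((0:(M - 1))^2 * w)
  }
  m2x <- vapply(g$x, m2, numeric(1))
  m2y <- vapply(g$y, m2, numeric(1))
  moves <- list(c(0, 1), c(1, 0), c(0, 2), c(2, 0),
                c(1, 3), c(3, 1), c(2, 3), c(3, 2))
  rate_of <- function(from, to, bind_self, bind_cross) {
    switch(paste(from, to),
      "0 1" = bind_self, "1 0" = p$f_a,
      "0 2" = bind_cross, "2 0" = p$f_r,
      "1 3" = bind_cross, "3 1" = p$f_r,
      "2 3" = bind_self, "3 2" = p$f_a)
  }
  Q <- matrix(0, 16, 16)
  for (sx in 0:3) for (sy in 0:3) {
    from <- sy + 4 * sx + 1
    for (mv in moves) {
      if (sx == mv[1]) {
        to <- sy + 4 * mv[2] + 1
        Q[to, from] <- Q[to, from] + rate_of(mv[1], mv[2],
                                             p$h_a * m2x[sx + 1] / 2,
                                             p$h_r * m2y[sy + 1] / 2)
      }
      if (sy == mv[1]) {
        to <- mv[2] + 4 * sx + 1
        Q[to, from] <- Q[to, from] + rate_of(mv[1], mv[2],
                                             p$h_a * m2y[sy + 1] / 2,
                                             p$h_r * m2x[sx + 1] / 2)
      }
    }
  }
  diag(Q) <- diag(Q) - colSums(Q)
  w <- tryCatch(solve(rbind(Q[-16, ], rep(1, 16)), c(rep(0, 15), 1)),
                error = function(e) rep(1 / 16, 16))
  pmax(w, 0)
}

solve_anchored <- function(K, Tm, N, M, j0, tol_residual, tol_negative, scale) {
  ti <- Tm@i; tj <- Tm@j; tx <- Tm@x
  j0m1 <- j0 - 1L # 0-based
  in_red <- ti != j0m1 & tj != j0m1
  shift <- function(v) v - (v > j0m1)
  bsel <- tj == j0m1 & ti != j0m1
  b <- numeric(N - 1L)
  b[shift(ti[bsel]) + 1L] <- -tx[bsel]
  x <- cpp_band_solve(shift(ti[in_red]), shift(tj[in_red]), tx[in_red],
                      as.integer(N - 1L), as.integer(16L * M + 1L), b)
  p <- append(x, 1, after = j0 - 1L)
  s <- sum(p)
  if (!all(is.finite(p)) || !is.finite(s) || s <= 0) {
    abort("stationary solve diverged; solver failure or ill-scaled anchor.",
          class = "coexland_error_solver")
  }
  p <- p / s
  neg <- min(p)
  if (neg < tol_negative) {
    abort(sprintf("stationary solve produced negative probability %.3e (beyond %.1e).",
                  neg, tol_negative),
          class = "coexland_error_solver")
  }
  p[p < 0] <- 0
  p <- p / sum(p)
  resid <- max(abs(K %*% p))
  if (resid > tol_residual * scale) {
    abort(sprintf("stationary residual %.3e exceeds %.1e * generator scale %.3e.",
                  resid, tol_residual, scale),
          class = "coexland_error_solver")
  }
  structure(list(pi = p, residual = resid, residual_rel = resid / scale, M = M),
            class = "stationary_distribution")
}

#' @export
print.stationary_distribution <- function(x, ...) {
  cat("<stationary_distribution> N =", length(x$pi),
      " residual =", format(x$residual, digits = 3), "\n")
  invisible(x)
}

#' Gene-pair coexpression landscape
#'
#' An M x M grid over mRNA count pairs (n_x, n_y). In probability form
#' the grid is the stationary probability of observing a cell with those
#' counts; the quasipotential form is `phi = -ln(pi)` (valleys are
#' likely, stable expression states).
#'
#' @param grid M x M numeric matrix (rows n_x = 0..M-1, cols n_y).
#' @param representation `"probability"` or `"quasipotential"`.
#' @param provenance `"model"` or `"empirical"`.
#' @param floor Probability floor used for the quasipotential transform
#'   (recorded for provenance), or `NA`.
#' @return A `coexpression_landscape`.
#' @export
coexpression_landscape <- function(grid, representation = c("probability", "quasipotential"),
                                   provenance = c("model", "empirical"), floor = NA_real_) {
  representation <- match.arg(representation)
  provenance <- match.arg(provenance)
  if (!is.matrix(grid) || nrow(grid) != ncol(grid)) {
    abort("`grid` must be a square matrix.", class = "coexland_error_landscape")
  }
  if (representation == "probability") {
    if (any(grid < 0) || abs(sum(grid) - 1) > 1e-6) {
      abort("probability landscape must be nonnegative and sum to 1.",
            class = "coexland_error_landscape")
    }
  }
  structure(list(grid = grid, representation = representation,
                 provenance = provenance, M = nrow(grid), floor = floor),
            class = "coexpression_landscape")
}

#' @export
print.coexpression_landscape <- function(x, ...) {
  cat("<coexpression_landscape>", x$representation, "/", x$provenance,
      " M =", x$M, "\n")
  invisible(x)
}

#' @export
tidy.coexpression_landscape <- function(x, ...) {
  M <- x$M
  tibble::tibble(
    nx = rep(0:(M - 1), times = M),
    ny = rep(0:(M - 1), each = M),
    value = as.vector(x$grid)
  )
}

#' Project the full stationary distribution onto the mRNA subspace
#'
#' Sums the stationary probability over the 16 promoter-state
#' combinations, mimicking what single-cell RNA-seq observes: transcript
#' counts only. Mass is conserved exactly.
#'
#' @param sol A [solve_stationary()] result (or a bare length-N vector
#'   with `M` supplied).
#' @param M Copy-number states per gene when `sol` is a bare vector.
#' @return A probability-form [coexpression_landscape()].
#' @export
marginalize_promoters <- function(sol, M = NULL) {
  if (inherits(sol, "stationary_distribution")) {
    M <- sol$M
    p <- sol$pi
  } else {
    p <- sol
    if (is.null(M)) abort("`M` is required for a bare probability vector.",
                          class = "coexland_error_args")
  }
  if (length(p) != 16L * M * M) {
    abort("probability vector length must be 16*M^2.", class = "coexland_error_args")
  }
  # i = sy + 4 sx + 16 (ny + M nx): promoter index varies fastest
  grid <- matrix(colSums(matrix(p, nrow = 16L)), nrow = M, byrow = TRUE)
  coexpression_landscape(grid, "probability", "model")
}

#' Quasipotential transform of a probability landscape
#'
#' `phi = -ln(max(pi, floor))`. The floor (default 1e-6) keeps the
#' transform finite for unobserved or numerically-zero cells and is the
#' same for model and empirical landscapes so that both feed the same
#' shape-space commensurably.
#'
#' @param landscape A probability-form [coexpression_landscape()].
#' @param floor Positive probability floor, default 1e-6.
#' @return A quasipotential-form landscape.
#' @examples
#' -log(1e-6) # quasipotential of an unobserved cell
#' @export
quasipotential <- function(landscape, floor = 1e-6) {
  if (!inherits(landscape, "coexpression_landscape") ||
      landscape$representation != "probability") {
    abort("`landscape` must be a probability-form coexpression landscape.",
          class = "coexland_error_representation")
  }
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0) {
    abort("`floor` must be a single positive probability.",
          class = "coexland_error_args")
  }
  phi <- -log(pmax(landscape$grid, floor))
  structure(list(grid = phi, representation = "quasipotential",
                 provenance = landscape$provenance, M = landscape$M, floor = floor),
            class = "coexpression_landscape")
}

#' Probability mass on the truncation boundary
#'
#' Diagnostic for the copy-number cap: total stationary probability of
#' states with either count at M-1. Should be negligible when
#' `g_hi / k << M - 1`.
#'
#' @param landscape A probability-form landscape.
#' @return Single number in \[0, 1\].
#' @export
boundary_mass <- function(landscape) {
  if (landscape$representation != "probability") {
    abort("boundary mass is defined for probability landscapes.",
          class = "coexland_error_representation")
  }
  M <- landscape$M
  sum(landscape$grid[M, ]) + sum(landscape$grid[, M]) - landscape$grid[M, M]
}

#' Compute a model's coexpression landscape end to end
#'
#' Builds the generator, solves for the stationary distribution,
#' marginalizes out the promoter states, and optionally applies the
#' quasipotential transform.
#'
#' @param model A `gene_network_model`.
#' @param representation `"probability"` or `"quasipotential"`.
#' @param floor Probability floor for the quasipotential form.
#' @return A [coexpression_landscape()].
#' @examples
#' land <- compute_landscape(misa_model(M = 8))
#' sum(land$grid)
#' @export
compute_landscape <- function(model, representation = c("probability", "quasipotential"),
                              floor = 1e-6) {
  representation <- match.arg(representation)
  land <- marginalize_promoters(solve_stationary(build_rate_matrix(model)))
  if (representation == "quasipotential") land <- quasipotential(land, floor)
  land
}

#' Stochastic simulation (Gillespie) occupancy of the full state space
#'
#' Direct-method stochastic simulation of the network's 20 reaction
#' channels, returning the time-weighted occupancy of every enumerated
#' state. Serves as an independent Monte-Carlo check on the exact
#' stationary solve. The first `burn_in` fraction of simulated time is
#' discarded to remove initial-condition bias. Reproducible for a fixed
#' `seed`.
#'
#' @param model A `gene_network_model`.
#' @param t_end Simulated time horizon in hours.
#' @param seed Integer seed (applied locally), or `NULL` to use the
#'   current RNG state.
#' @param burn_in Fraction of `t_end` discarded before accumulating
#'   occupancy (default 0.1).
#' @param init Initial state `c(nx, ny, sx, sy)`, default all zero.
#' @return A length-N occupancy vector summing to 1 (all mass on `init`
#'   when `t_end` is 0).
#' @export
ssa_simulate <- function(model, t_end, seed = NULL, burn_in = 0.1,
                         init = c(0L, 0L, 0L, 0L)) {
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end < 0) {
    abort("`t_end` must be a single nonnegative time in hours.",
          class = "coexland_error_args")
  }
  p <- model$params
  g <- synthesis_rates(model)
  run <- function() {
    cpp_ssa_occupancy(model$M, g$x, g$y, p$k, p$h_a, p$f_a, p$h_r, p$f_r,
                      as.numeric(t_end), burn_in, as.integer(init))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
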