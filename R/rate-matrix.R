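#' Reaction channels of the two-gene network
#'
#' Twenty channels: synthesis and degradation of each mRNA, plus eight
#' promoter-state transitions per gene. Promoter transitions change only
#' the binding state, never the mRNA counts: the bound transcription
#' factor is a protein proxied by its mRNA level, so no transcript is
#' sequestered by binding.
#'
#' @return Character vector of reaction ids.
#' @export
reaction_ids <- function() {
  prom <- c("00->self", "self->00", "00->other", "other->00",
            "self->both", "both->self", "other->both", "both->other")
  c("synth_x", "synth_y", "deg_x", "deg_y",
    paste0("x:", prom), paste0("y:", prom))
}

#' Propensity of one reaction in one state
#'
#' Standard stochastic kinetic rate laws: synthesis at the logic table's
#' rate for the current promoter state (zero at the reflecting boundary
#' n = M-1), degradation `k * n`, homodimer binding `h * n_regulator^2 / 2`
#' (self rates `h_a`, `f_a`; cross rates `h_r`, `f_r`), unbinding `f`.
#' A promoter transition whose source binding state differs from the
#' state's has propensity zero.
#'
#' @param model A [flex_model()] / [misa_model()].
#' @param state State tuple: numeric/integer `c(nx, ny, sx, sy)` or a
#'   one-row data frame with those columns.
#' @param reaction One of [reaction_ids()].
#' @return Propensity in events per hour.
#' @examples
#' m <- misa_model(kinetic_params(h_r = 1), M = 21)
#' propensity(m, c(0, 2, 0, 0), "x:00->other") # h_r * 2^2 / 2
#' @export
propensity <- function(model, state, reaction) {
  if (is.data.frame(state)) state <- unlist(state[1, c("nx", "ny", "sx", "sy")])
  if (length(state) != 4L) abort("`state` must be (nx, ny, sx, sy).",
                                 class = "coexland_error_state")
  nx <- state[[1]]; ny <- state[[2]]; sx <- state[[3]]; sy <- state[[4]]
  M <- model$M
  if (nx < 0 || nx >= M || ny < 0 || ny >= M || sx < 0 || sx > 3 || sy < 0 || sy > 3) {
    abort("state tuple out of range for this model.", class = "coexland_error_state")
  }
  if (!reaction %in% reaction_ids()) {
    abort(paste0("unknown reaction id: ", reaction), class = "coexland_error_reaction")
  }
  p <- model$params
  g <- synthesis_rates(model)
  if (reaction == "synth_x") return(if (nx < M - 1) g$x[sx + 1] else 0)
  if (reaction == "synth_y") return(if (ny < M - 1) g$y[sy + 1] else 0)
  if (reaction == "deg_x") return(p$k * nx)
  if (reaction == "deg_y") return(p$k * ny)
  gene <- substr(reaction, 1, 1)
  move <- substr(reaction, 3, nchar(reaction))
  s <- if (gene == "x") sx else sy
  n_self <- if (gene == "x") nx else ny
  n_other <- if (gene == "x") ny else nx
  bind_self <- p$h_a * n_self^2 / 2
  bind_cross <- p$h_r * n_other^2 / 2
  code <- c("00" = 0, "self" = 1, "other" = 2, "both" = 3)
  parts <- strsplit(move, "->", fixed = TRUE)[[1]]
  from <- code[[parts[1]]]
  if (s != from) return(0)
  switch(move,
    "00->self" = bind_self,
    "self->00" = p$f_a,
    "00->other" = bind_cross,
    "other->00" = p$f_r,
    "self->both" = bind_cross,
    "both->self" = p$f_r,
    "other->both" = bind_self,
    "both->other" = p$f_a
  )
}

#' Build the sparse CME generator for a model
#'
#' Assembles the N x N reaction rate matrix K over the enumerated state
#' space: off-diagonal `K[l, m]` is the propensity of the reaction taking
#' state m to state l, and each diagonal entry is minus its column sum,
#' so the columns of a valid generator sum to zero.
#'
#' @param model A `gene_network_model`.
#' @return A `cme_rate_matrix`: list with the sparse generator `K`
#'   (`Matrix::dgCMatrix`), `M`, and the generating `model`.
#' @examples
#' K <- build_rate_matrix(misa_model(M = 6))
#' max(abs(Matrix::colSums(K$K)))
#' @export
build_rate_matrix <- function(model) {
  M <- model$M
  N <- 16L * M * M
  idx <- 0:(N - 1L)
  sy <- idx %% 4L
  sx <- (idx %/% 4L) %% 4L
  ny <- (idx %/% 16L) %% M
  nx <- idx %/% (16L * M)
  p <- model$params
  g <- synthesis_rates(model)
  gx <- g$x[sx + 1L]
  gy <- g$y[sy + 1L]

  ii <- vector("list", 20); jj <- vector("list", 20); xx <- vector("list", 20)
  slot <- 0L
  add <- function(from, to, rate) {
    keep <- rate > 0
    slot <<- slot + 1L
    ii[[slot]] <<- to[keep]; jj[[slot]] <<- from[keep]; xx[[slot]] <<- rate[keep]
  }
  step_nx <- 16L * M
  add(idx, idx + step_nx, ifelse(nx < M - 1L, gx, 0))
  add(idx, idx + 16L, ifelse(ny < M - 1L, gy, 0))
  add(idx, idx - step_nx, p$k * nx)
  add(idx, idx - 16L, p$k * ny)
  bind_self_x <- p$h_a * nx^2 / 2; bind_cross_x <- p$h_r * ny^2 / 2
  add(idx, idx + 4L, ifelse(sx == 0L, bind_self_x, 0))
  add(idx, idx - 4L, ifelse(sx == 1L, p$f_a, 0))
  add(idx, idx + 8L, ifelse(sx == 0L, bind_cross_x, 0))
  add(idx, idx - 8L, ifelse(sx == 2L, p$f_r, 0))
  add(idx, idx + 8L, ifelse(sx == 1L, bind_cross_x, 0))
  add(idx, idx - 8L, ifelse(sx == 3L, p$f_r, 0))
  add(idx, idx + 4L, ifelse(sx == 2L, bind_self_x, 0))
  add(idx, idx - 4L, ifelse(sx == 3L, p$f_a, 0))
  bind_self_y <- p$h_a * ny^2 / 2; bind_cross_y <- p$h_r * nx^2 / 2
  add(idx, idx + 1L, ifelse(sy == 0L, bind_self_y, 0))
  add(idx, idx - 1L, ifelse(sy == 1L, p$f_a, 0))
  add(idx, idx + 2L, ifelse(sy == 0L, bind_cross_y, 0))
  add(idx, idx - 2L, ifelse(sy == 2L, p$f_r, 0))
  add(idx, idx + 2L, ifelse(sy == 1L, bind_cross_y, 0))
  add(idx, idx - 2L, ifelse(sy == 3L, p$f_r, 0))
  add(idx, idx + 1L, ifelse(sy == 2L, bind_self_y, 0))
  add(idx, idx - 1L, ifelse(sy == 3L, p$f_a, 0))

  K <- Matrix::sparseMatrix(i = unlist(ii) + 1L, j = unlist(jj) + 1L,
                            x = unlist(xx), dims = c(N, N))
  Matrix::diag(K) <- Matrix::diag(K) - Matrix::colSums(K)
  structure(list(K = K, M = M, model = model), class = "cme_rate_matrix")
}

#' @export
print.cme_rate_matrix <- function(x, ...) {
  cat("<cme_rate_matrix> N =", ncol(x$K), " nnz =", length(x$K@x), "\n")
  invisible(x)
}
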