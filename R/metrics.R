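#' Scalar coexpression metrics of a probability landscape
#'
#' Four commonly used summaries of a bivariate count distribution
#' pi(n_x, n_y): Shannon entropy, population Pearson correlation of the
#' counts, mutual information, and the coexpression index. Entropy and
#' mutual information use natural logarithms (nats), consistent with the
#' quasipotential `phi = -ln(pi)`. The coexpression index is the
#' conditional probability that a cell has nonzero counts of both genes
#' given it has a nonzero count of at least one:
#' `sum(pi[nx>0 & ny>0]) / sum(pi[nx>0 | ny>0])`.
#'
#' Degenerate inputs (zero marginal variance for the correlation; all
#' mass at (0,0) for the index) are signaled as a classed error
#' (`coexland_error_undefined`) rather than silently propagating `NaN`;
#' [landscape_metrics()] converts them to `NA`.
#'
#' @param landscape A probability-form [coexpression_landscape()] or a
#'   nonnegative matrix summing to 1.
#' @return A single number.
#' @examples
#' land <- compute_landscape(misa_model(M = 8))
#' shannon_entropy(land)
#' coexpression_index(land)
#' @name landscape-metrics
NULL

metric_grid <- function(landscape) {
  if (inherits(landscape, "coexpression_landscape")) {
    if (landscape$representation != "probability") {
      abort("metrics are defined on probability landscapes.",
            class = "coexland_error_representation")
    }
    g <- landscape$grid
  } else if (is.matrix(landscape)) {
    g <- landscape
  } else {
    abort("`landscape` must be a coexpression landscape or matrix.",
          class = "coexland_error_args")
  }
  if (any(g < 0) || abs(sum(g) - 1) > 1e-6) {
    abort("probability landscape must be nonnegative and sum to 1 (within 1e-6).",
          class = "coexland_error_landscape")
  }
  g
}

#' @rdname landscape-metrics
#' @export
shannon_entropy <- function(landscape) {
  g <- metric_grid(landscape)
  nz <- g > 0
  -sum(g[nz] * log(g[nz]))
}

#' @rdname landscape-metrics
#' @export
pearson_correlation <- function(landscape) {
  g <- metric_grid(landscape)
  M <- nrow(g)
  n <- 0:(M - 1)
  px <- rowSums(g); py <- colSums(g)
  mx <- sum(n * px); my <- sum(n * py)
  vx <- sum(n^2 * px) - mx^2; vy <- sum(n^2 * py) - my^2
  if (vx <= 0 || vy <= 0) {
    abort("Pearson correlation undefined: a marginal has zero variance.",
          class = "coexland_error_undefined")
  }
  cxy <- sum(outer(n, n) * g) - mx * my
  cxy / sqrt(vx * vy)
}

#' @rdname landscape-metrics
#' @export
mutual_information <- function(landscape) {
  g <- metric_grid(landscape)
  px <- rowSums(g); py <- colSums(g)
  pprod <- outer(px, py)
  nz <- g > 0
  sum(g[nz] * log(g[nz] / pprod[nz]))
}

#' @rdname landscape-metrics
#' @export
coexpression_index <- function(landscape) {
  g <- metric_grid(landscape)
  both <- sum(g[-1, -1])
  either <- sum(g) - g[1, 1]
  if (either <= 0) {
    abort("coexpression index undefined: all mass at (0, 0).",
          class = "coexland_error_undefined")
  }
  both / either
}

#' All four metrics as a one-row tibble
#'
#' Metrics that are undefined for the given landscape (see
#' [landscape-metrics]) are reported as `NA`.
#'
#' @param landscape A probability-form landscape.
#' @return Tibble with columns `shannon_entropy`, `pearson_correlation`,
#'   `mutual_information`, `coexpression_index`.
#' @export
landscape_metrics <- function(landscape) {
  safe <- function(f) {
    tryCatch(f(landscape),
             coexland_error_undefined = function(e) NA_real_)
  }
  tibble::tibble(
    shannon_entropy = safe(shannon_entropy),
    pearson_correlation = safe(pearson_correlation),
    mutual_information = safe(mutual_information),
    coexpression_index = safe(coexpression_index)
  )
}
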