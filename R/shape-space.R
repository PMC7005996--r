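#' Fit the PCA landscape shape-space on a model library
#'
#' Each library landscape is a replicate and each of the M^2 count-pair
#' probabilities (or quasipotentials) is a feature. PCA is computed on
#' the raw feature covariance (mean-centered, no feature scaling).
#' Eigenvector sign is arbitrary, so a convention is frozen: components
#' 1 and 2 are flipped, if needed, so that a reference "hi/hi"
#' coexpression landscape (independent truncated-Poisson marginals at
#' the active synthesis level) projects nonnegatively; remaining
#' components are flipped so their largest-magnitude loading is
#' positive.
#'
#' @param library A [compute_landscape_library()] result (single
#'   representation).
#' @param n_components Default number of scores reported by
#'   [project_landscape()] (the full basis is retained internally).
#' @return A `shape_space`: list with `mean`, `rotation` (features x
#'   components), `sdev`, `var_fraction`, `n_components`,
#'   `representation`, `M`, `floor`, `sign_flipped`.
#' @export
fit_shape_space <- function(library, n_components = 3) {
  if (!inherits(library, "landscape_library")) {
    abort("`library` must be a landscape_library.", class = "coexland_error_args")
  }
  X <- library$features
  if (nrow(X) < n_components) {
    abort("library must have at least `n_components` rows.",
          class = "coexland_error_args")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  if (total_var <= .Machine$double.eps * max(1, sum(abs(X)))) {
    abort("library has zero variance (all landscapes identical); no shape-space can be fitted.",
          class = "coexland_error_degenerate")
  }
  space <- structure(
    list(mean = pc$center, rotation = pc$rotation, sdev = pc$sdev,
         var_fraction = pc$sdev^2 / total_var,
         n_components = as.integer(n_components),
         representation = library$representation,
         M = library$M, floor = library$floor,
         sign_flipped = rep(FALSE, ncol(pc$rotation))),
    class = "shape_space")
  # sign convention via the hi/hi reference landscape
  arch <- archetype_landscapes(library$M, library$representation,
                               floor = if (is.na(library$floor)) 1e-6 else library$floor)
  v <- as.vector(arch$hi_hi$grid) - space$mean
  scores <- drop(v %*% space$rotation)
  flip <- rep(FALSE, ncol(space$rotation))
  k12 <- seq_len(min(2L, ncol(space$rotation)))
  flip[k12] <- scores[k12] < 0
  if (ncol(space$rotation) > 2) {
    for (j in 3:ncol(space$rotation)) {
      flip[j] <- space$rotation[which.max(abs(space$rotation[, j])), j] < 0
    }
  }
  space$rotation[, flip] <- -space$rotation[, flip]
  space$sign_flipped <- flip
  space
}

#' @export
print.shape_space <- function(x, ...) {
  cat("<shape_space>", x$representation, " M =", x$M,
      " components =", x$n_components, "\n")
  vf <- round(100 * x$var_fraction[seq_len(min(3, length(x$var_fraction)))], 1)
  cat("  explained variance (%):", paste(vf, collapse = ", "), "...\n")
  invisible(x)
}

#' @export
tidy.shape_space <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$sdev),
    sdev = x$sdev,
    var_fraction = x$var_fraction,
    cum_fraction = cumsum(x$var_fraction)
  )
}

#' @export
glance.shape_space <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$mean),
    n_components = x$n_components,
    representation = x$representation,
    M = x$M,
    var_fraction_1 = x$var_fraction[1],
    var_fraction_2 = if (length(x$var_fraction) > 1) x$var_fraction[2] else NA_real_,
    var_fraction_3 = if (length(x$var_fraction) > 2) x$var_fraction[3] else NA_real_
  )
}

#' Project a landscape into a fitted shape-space
#'
#' Scores are the mean-centered feature vector times the component
#' loadings. The landscape's representation and grid size must match
#' the training library's; projecting the training mean gives the zero
#' vector.
#'
#' @param landscape A [coexpression_landscape()].
#' @param space A [fit_shape_space()] result.
#' @param n_components Number of scores (default the space's setting);
#'   `Inf` for all retained components.
#' @return A one-row tibble with columns `c1` ... `cn`.
#' @export
project_landscape <- function(landscape, space, n_components = space$n_components) {
  if (!inherits(landscape, "coexpression_landscape")) {
    abort("`landscape` must be a coexpression landscape.", class = "coexland_error_args")
  }
  if (landscape$representation != space$representation) {
    abort(sprintf("representation mismatch: landscape is %s but the space was trained on %s.",
                  landscape$representation, space$representation),
          class = "coexland_error_representation")
  }
  v <- as.vector(landscape$grid)
  if (length(v) != length(space$mean)) {
    abort("landscape feature length does not match the shape-space.",
          class = "coexland_error_args")
  }
  n <- min(n_components, ncol(space$rotation))
  scores <- drop((v - space$mean) %*% space$rotation[, seq_len(n), drop = FALSE])
  tibble::as_tibble(as.list(stats::setNames(scores, paste0("c", seq_len(n)))))
}

#' Reconstruct a feature vector from shape-space scores
#'
#' @param scores Numeric vector of scores (length up to the number of
#'   retained components).
#' @param space A `shape_space`.
#' @return Numeric feature vector of length M^2.
#' @export
reconstruct_landscape <- function(scores, space) {
  scores <- as.numeric(scores)
  n <- length(scores)
  drop(space$rotation[, seq_len(n), drop = FALSE] %*% scores) + space$mean
}

#' Project every library landscape, grouped by motif class
#'
#' @param space A `shape_space`.
#' @param library A `landscape_library` whose descriptors carry
#'   `motif_class` labels.
#' @return Tibble with `motif_id`, `motif_class` and score columns, one
#'   row per library landscape.
#' @export
motif_occupancy <- function(space, library) {
  if (!"motif_class" %in% names(library$models)) {
    abort("library rows carry no motif-class labels.", class = "coexland_error_args")
  }
  if (library$representation != space$representation) {
    abort("library and shape-space representations differ.",
          class = "coexland_error_representation")
  }
  n <- space$n_components
  S <- sweep(library$features, 2, space$mean) %*%
    space$rotation[, seq_len(n), drop = FALSE]
  colnames(S) <- paste0("c", seq_len(n))
  dplyr::bind_cols(library$models[, c("motif_id", "motif_class")],
                   tibble::as_tibble(S))
}

#' Reference archetype landscapes
#'
#' Synthetic reference shapes built from truncated-Poisson marginals,
#' used for the shape-space sign convention and for interpreting
#' components: `lo_lo` (both genes off), `hi_hi` (independent high
#' coexpression), `antagonistic` (equal mixture of X-only and Y-only
#' high expression), and `asymmetric` (X high, Y off).
#'
#' @param M Grid size.
#' @param representation `"probability"` or `"quasipotential"`.
#' @param floor Probability floor for the quasipotential form.
#' @param g_hi,g_lo,k Rates defining the high and low mean counts
#'   (`g/k`).
#' @return Named list of [coexpression_landscape()] objects.
#' @export
archetype_landscapes <- function(M, representation = c("probability", "quasipotential"),
                                 floor = 1e-6, g_hi = 1.1, g_lo = 0.001, k = 0.2) {
  representation <- match.arg(representation)
  tp <- function(mean) {
    w <- stats::dpois(0:(M - 1), mean)
    w / sum(w)
  }
  hi <- tp(g_hi / k); lo <- tp(g_lo / k)
  mk <- function(grid) coexpression_landscape(grid, "probability", "model")
  out <- list(
    lo_lo = mk(outer(lo, lo)),
    hi_hi = mk(outer(hi, hi)),
    antagonistic = mk(0.5 * outer(hi, lo) + 0.5 * outer(lo, hi)),
    asymmetric = mk(outer(hi, lo))
  )
  if (representation == "quasipotential") out <- lapply(out, quasipotential, floor = floor)
  out
}
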