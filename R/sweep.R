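#' Log-spaced parameter values
#'
#' @param n Number of values.
#' @param lo,hi Positive range endpoints.
#' @return Numeric vector of `n` log-spaced values from `lo` to `hi`.
#' @export
log_spaced <- function(n, lo, hi) {
  if (lo <= 0 || hi <= lo) abort("need 0 < lo < hi.", class = "coexland_error_args")
  exp(seq(log(lo), log(hi), length.out = n))
}

regime_range <- function(parameter, regime) {
  b <- regime_bounds()
  if (regime == "both") {
    rows <- b[b$parameter == parameter, ]
    c(min(rows$min), max(rows$max))
  } else {
    row <- b[b$parameter == parameter & b$regime == regime, ]
    c(row$min, row$max)
  }
}

#' Parameter grid for the mutual-inhibition/self-activation (MISA) sweep
#'
#' Cartesian product over the active synthesis rate (including
#' asymmetric gene pairs) and the four promoter-kinetics rates, with the
#' regulatory logic fixed to MISA. Defaults give a fast-regime
#' (adiabatic) grid of 1,296 unique models: all ordered `g_hi` pairs
#' from 3 levels, 3 log-spaced binding rates and 4 log-spaced unbinding
#' rates for each of the self- and cross-interactions. Values are
#' checked against the regime bounds of [regime_bounds()].
#'
#' @param g_hi Active synthesis levels (mRNA/hr); all ordered (x, y)
#'   pairs are formed when `asymmetric` is `TRUE`.
#' @param h_a,h_r Binding-rate levels (hr^-1 mRNA^-2).
#' @param f_a,f_r Unbinding-rate levels (/hr).
#' @param g_lo,k Leak synthesis and degradation rates.
#' @param M Copy-number states per gene.
#' @param regime `"fast"`, `"slow"`, or `"both"`; used to validate the
#'   h/f levels.
#' @param asymmetric Include asymmetric `g_hi` pairs (default `TRUE`).
#' @return A tibble of model parameter rows (deduplicated), one model per row.
#' @examples
#' nrow(misa_grid(g_hi = c(1, 1.2), f_a = c(10, 100), f_r = c(10, 100),
#'                h_a = c(10, 100), h_r = c(10, 100)))
#' @export
misa_grid <- function(g_hi = c(0.8, 1.1, 1.4),
                      h_a = log_spaced(3, 10, 500),
                      f_a = log_spaced(4, 10, 1e5),
                      h_r = log_spaced(3, 10, 500),
                      f_r = log_spaced(4, 10, 1e5),
                      g_lo = 0.001, k = 0.2, M = 21,
                      regime = "fast", asymmetric = TRUE) {
  gpairs <- if (asymmetric) {
    tidyr::expand_grid(g_hi_x = g_hi, g_hi_y = g_hi)
  } else {
    tibble::tibble(g_hi_x = g_hi, g_hi_y = g_hi)
  }
  grid <- tidyr::expand_grid(gpairs, h_a = h_a, f_a = f_a, h_r = h_r, f_r = f_r)
  grid <- dplyr::distinct(grid)
  if (nrow(grid) == 0) abort("empty parameter grid.", class = "coexland_error_grid")
  check_regime_bounds(grid, regime)
  dplyr::mutate(grid, motif_id = misa_motif_id(), g_lo = g_lo, k = k, M = M,
                .before = 1)
}

#' Parameter grid for the Two-Gene Flex sweep
#'
#' The same kinetic grid applied to every interacting regulatory-logic
#' variant (the two constant variants encode no gene-gene interaction
#' and are excluded; MISA is one of the 14 kept). Defaults give 2,268
#' models: 14 motifs x 2 symmetric `g_hi` levels x 3 log-spaced values
#' for each of `h_a`, `h_r` (spanning both kinetic regimes,
#' 1e-6 to 500) and `f_a`, `f_r` (1e-6 to 1e5).
#'
#' @param motif_ids Logic variants to sweep; defaults to all interacting
#'   variants from [motif_catalogue()].
#' @inheritParams misa_grid
#' @return A tibble of model parameter rows.
#' @export
flex_grid <- function(motif_ids = NULL,
                      g_hi = c(0.8, 1.4),
                      h_a = log_spaced(3, 1e-6, 500),
                      f_a = log_spaced(3, 1e-6, 1e5),
                      h_r = log_spaced(3, 1e-6, 500),
                      f_r = log_spaced(3, 1e-6, 1e5),
                      g_lo = 0.001, k = 0.2, M = 21,
                      regime = "both", asymmetric = FALSE) {
  cat_tbl <- motif_catalogue()
  if (is.null(motif_ids)) motif_ids <- cat_tbl$motif_id[cat_tbl$interacting]
  if (any(!motif_ids %in% 0:15)) abort("motif ids must lie in 0..15.",
                                       class = "coexland_error_motif_id")
  base <- misa_grid(g_hi = g_hi, h_a = h_a, f_a = f_a, h_r = h_r, f_r = f_r,
                    g_lo = g_lo, k = k, M = M, regime = regime,
                    asymmetric = asymmetric)
  base$motif_id <- NULL
  grid <- tidyr::expand_grid(motif_id = as.integer(motif_ids), base)
  if (nrow(grid) == 0) abort("empty parameter grid.", class = "coexland_error_grid")
  grid
}

check_regime_bounds <- function(grid, regime) {
  hr_ <- regime_range("h", regime)
  fr_ <- regime_range("f", regime)
  hs <- c(grid$h_a, grid$h_r); fs <- c(grid$f_a, grid$f_r)
  out_of <- function(v, r) any(v < r[1] * (1 - 1e-9) | v > r[2] * (1 + 1e-9))
  if (out_of(hs, hr_) || out_of(fs, fr_)) {
    warn(sprintf("some h/f values fall outside the %s-regime bounds.", regime),
         class = "coexland_warning_bounds")
  }
  invisible(grid)
}

grid_row_model <- function(row) {
  flex_model(row$motif_id,
             kinetic_params(g_lo = row$g_lo, g_hi_x = row$g_hi_x,
                            g_hi_y = row$g_hi_y, k = row$k,
                            h_a = row$h_a, f_a = row$f_a,
                            h_r = row$h_r, f_r = row$f_r),
             M = row$M)
}

#' Compute a landscape library from a parameter grid
#'
#' Solves the CME for each model row and stacks the landscapes as
#' feature rows (length M^2, column-major over (n_x, n_y)). The result
#' is a pure function of the grid: the exact solver has no seed, and
#' row order is preserved regardless of `workers`. Models whose solve
#' fails are dropped with a warning recording the reason.
#'
#' @param grid A [misa_grid()] / [flex_grid()] tibble.
#' @param representation `"probability"` or `"quasipotential"`.
#' @param floor Probability floor for quasipotential libraries.
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @return A `landscape_library`: list with `models` (descriptor tibble,
#'   including `motif_class`), `features` (R x M^2 matrix),
#'   `representation`, `M`, `floor`.
#' @examples
#' \donttest{
#' lib <- compute_landscape_library(misa_grid(g_hi = 1.1, h_a = 50, h_r = 50,
#'                                            f_a = c(10, 100), f_r = 100, M = 12))
#' dim(lib$features)
#' }
#' @export
compute_landscape_library <- function(grid, representation = c("probability", "quasipotential"),
                                      floor = 1e-6, workers = 1) {
  representation <- match.arg(representation)
  if (nrow(grid) == 0) abort("empty model grid.", class = "coexland_error_grid")
  if (length(unique(grid$M)) != 1L) {
    abort("all models in one library must share M.", class = "coexland_error_grid")
  }
  one <- function(r) {
    row <- grid[r, ]
    tryCatch(
      as.vector(compute_landscape(grid_row_model(row), representation, floor)$grid),
      error = function(e) structure(conditionMessage(e), class = "coexland_fail")
    )
  }
  res <- if (workers > 1) {
    parallel::mclapply(seq_len(nrow(grid)), one, mc.cores = workers)
  } else {
    lapply(seq_len(nrow(grid)), one)
  }
  failed <- vapply(res, inherits, logical(1), "coexland_fail")
  if (all(failed)) {
    abort(paste0("all models failed; first reason: ", res[[1]]),
          class = "coexland_error_sweep")
  }
  if (any(failed)) {
    warn(sprintf("%d of %d models failed and were excluded (e.g. %s).",
                 sum(failed), nrow(grid), res[[which(failed)[1]]]),
         class = "coexland_warning_sweep")
  }
  keep <- !failed
  features <- do.call(rbind, res[keep])
  models <- grid[keep, , drop = FALSE]
  cat_tbl <- motif_catalogue()
  models$motif_class <- cat_tbl$motif_class[match(models$motif_id, cat_tbl$motif_id)]
  models$motif_label <- cat_tbl$motif_label[match(models$motif_id, cat_tbl$motif_id)]
  structure(list(models = models, features = features,
                 representation = representation, M = grid$M[[1]],
                 floor = if (representation == "quasipotential") floor else NA_real_),
            class = "landscape_library")
}

#' @export
print.landscape_library <- function(x, ...) {
  cat("<landscape_library>", nrow(x$features), "landscapes x", ncol(x$features),
      "features;", x$representation, "; M =", x$M, "\n")
  invisible(x)
}

#' Extract one library row as a coexpression landscape
#'
#' @param library A `landscape_library`.
#' @param row Row number.
#' @return A [coexpression_landscape()].
#' @export
library_landscape <- function(library, row) {
  grid <- matrix(library$features[row, ], nrow = library$M)
  structure(list(grid = grid, representation = library$representation,
                 provenance = "model", M = library$M, floor = library$floor),
            class = "coexpression_landscape")
}

#' Metric table for every landscape in a library
#'
#' @param library A probability-form `landscape_library`.
#' @return The descriptor tibble with the four metric columns appended.
#' @export
library_metrics <- function(library) {
  if (library$representation != "probability") {
    abort("metrics require a probability-form library.",
          class = "coexland_error_representation")
  }
  mets <- purrr::map_dfr(seq_len(nrow(library$features)),
                         function(r) landscape_metrics(library_landscape(library, r)))
  dplyr::bind_cols(library$models, mets)
}

#' Write / read a landscape library as delimited text
#'
#' One TSV with a small commented metadata header, the descriptor
#' columns, and the M^2 feature columns (`f1` ... `fM2`, column-major
#' over (n_x, n_y)). Round-trips bit-exactly at full double precision.
#'
#' @param library A `landscape_library`.
#' @param path File path.
#' @return `read_landscape_library()` returns the `landscape_library`;
#'   `write_landscape_library()` returns `path` invisibly.
#' @export
write_landscape_library <- function(library, path) {
  feat <- tibble::as_tibble(library$features, .name_repair = ~ paste0("f", seq_along(.x)))
  tab <- dplyr::bind_cols(library$models, feat)
  meta <- c(
    paste0("# coexland-landscape-library"),
    paste0("# representation: ", library$representation),
    paste0("# M: ", library$M),
    paste0("# floor: ", format(library$floor, digits = 17)),
    paste0("# descriptor_cols: ", ncol(library$models))
  )
  writeLines(meta, path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_landscape_library
#' @export
read_landscape_library <- function(path) {
  hdr <- readLines(path, n = 5)
  if (!startsWith(hdr[1], "# coexland-landscape-library")) {
    abort("not a coexland landscape-library file.", class = "coexland_error_io")
  }
  get <- function(key) sub(paste0("# ", key, ": "), "", hdr[startsWith(hdr, paste0("# ", key, ":"))])
  representation <- get("representation")
  M <- as.integer(get("M"))
  floor <- as.numeric(get("floor"))
  ndesc <- as.integer(get("descriptor_cols"))
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  models <- tab[, seq_len(ndesc), drop = FALSE]
  features <- as.matrix(tab[, -seq_len(ndesc), drop = FALSE])
  dimnames(features) <- NULL
  structure(list(models = models, features = features,
                 representation = representation, M = M, floor = floor),
            class = "landscape_library")
}
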