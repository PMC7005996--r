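#' Kinetic rate constants for the two-gene stochastic network
#'
#' Rates follow vertebrate-scale estimates: transcription around one
#' mRNA per hour when a promoter is active, a leaky but effectively-off
#' rate when repressed, degradation of order hours, and promoter-state
#' change (transcription-factor binding/unbinding, or slower chromatin
#' remodelling) spanning the fast (adiabatic) and slow (nonadiabatic)
#' regimes. Binding is modelled as homodimeric, so the binding propensity
#' is quadratic in regulator copy number, `h * n^2 / 2`, and the
#' protein-to-mRNA proportionality is subsumed into `h`.
#'
#' @param g_lo Repressed (leaky) synthesis rate, mRNA/hr. Default 0.001.
#' @param g_hi Active synthesis rate, mRNA/hr; sets both genes unless
#'   `g_hi_x`/`g_hi_y` are given (asymmetric model).
#' @param g_hi_x,g_hi_y Per-gene active synthesis rates, mRNA/hr.
#' @param k mRNA degradation rate, /hr. Default 0.2.
#' @param h_a,f_a Self-regulatory (auto) binding (hr^-1 mRNA^-2) and
#'   unbinding (/hr) rates.
#' @param h_r,f_r Cross-regulatory binding and unbinding rates.
#' @return A `kinetic_params` list.
#' @examples
#' kinetic_params(h_a = 100, f_a = 1000, h_r = 100, f_r = 1000)
#' @export
kinetic_params <- function(g_lo = 0.001, g_hi = 1.1, g_hi_x = g_hi, g_hi_y = g_hi,
                           k = 0.2, h_a = 100, f_a = 1000, h_r = 100, f_r = 1000) {
  p <- list(g_lo = g_lo, g_hi_x = g_hi_x, g_hi_y = g_hi_y, k = k,
            h_a = h_a, f_a = f_a, h_r = h_r, f_r = f_r)
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))
  if (!all(num)) abort("all kinetic parameters must be single finite numbers.",
                       class = "coexland_error_params")
  if (any(unlist(p) <= 0)) abort("all kinetic rates must be strictly positive.",
                                 class = "coexland_error_params")
  if (g_lo >= min(g_hi_x, g_hi_y)) {
    abort("`g_lo` must be smaller than the active synthesis rate `g_hi`.",
          class = "coexland_error_params")
  }
  structure(p, class = "kinetic_params")
}

#' Table of promoter-kinetics regime bounds
#'
#' The fast (adiabatic) regime reflects measured timescales of
#' transcription-factor binding/unbinding to DNA; the slow (nonadiabatic)
#' regime covers epigenetic or chromatin changes on hour-to-day
#' timescales or longer.
#'
#' @return A tibble with columns `regime`, `parameter` (`h` or `f`),
#'   `min`, `max`.
#' @export
regime_bounds <- function() {
  tibble::tibble(
    regime = c("fast", "fast", "slow", "slow"),
    parameter = c("h", "f", "h", "f"),
    min = c(10, 10, 1e-6, 1e-6),
    max = c(500, 1e5, 10, 10)
  )
}

#' Discrete stochastic two-gene network model
#'
#' Bundles a regulatory-logic variant with kinetic parameters and the
#' copy-number cap `M` (counts range over 0..M-1, with a reflecting
#' boundary at M-1). `M` should satisfy `g_hi / k << M - 1` so that the
#' truncation carries negligible probability; [boundary_mass()] provides
#' the diagnostic.
#'
#' @param motif_id Logic variant id in 0..15 (see [motif_catalogue()]).
#' @param params A [kinetic_params()] object.
#' @param M Number of copy-number states per gene (default 21).
#' @return A `gene_network_model`.
#' @examples
#' misa_model(kinetic_params(h_a = 20, f_a = 50, h_r = 20, f_r = 50))
#' @export
flex_model <- function(motif_id, params = kinetic_params(), M = 21) {
  if (!inherits(params, "kinetic_params")) params <- do.call(kinetic_params, params)
  check_M(M)
  lv <- logic_levels(motif_id)
  structure(
    list(motif_id = as.integer(motif_id),
         levels = lv,
         motif_class = classify_motif(lv),
         motif_label = motif_label(motif_id),
         params = params,
         M = as.integer(M)),
    class = "gene_network_model"
  )
}

#' @rdname flex_model
#' @export
misa_model <- function(params = kinetic_params(), M = 21) {
  flex_model(misa_motif_id(), params, M)
}

check_M <- function(M) {
  if (length(M) != 1L || is.na(M) || M %% 1 != 0 || M < 1) {
    abort("`M` must be a single positive integer.", class = "coexland_error_M")
  }
  invisible(as.integer(M))
}

#' @export
print.gene_network_model <- function(x, ...) {
  p <- x$params
  cat("<gene_network_model> motif", x$motif_id, paste0("(", x$motif_label, ","),
      paste0(x$motif_class, ")"), "M =", x$M, "\n")
  cat("  levels (00,self,other,both):",
      paste(ifelse(x$levels == 1, "hi", "lo"), collapse = ", "), "\n")
  cat(sprintf("  g_lo=%.3g g_hi_x=%.3g g_hi_y=%.3g k=%.3g\n", p$g_lo, p$g_hi_x, p$g_hi_y, p$k))
  cat(sprintf("  h_a=%.3g f_a=%.3g h_r=%.3g f_r=%.3g\n", p$h_a, p$f_a, p$h_r, p$f_r))
  invisible(x)
}

# Per-promoter-state synthesis rates for each gene.
synthesis_rates <- function(model) {
  p <- model$params
  list(
    x = ifelse(model$levels == 1L, p$g_hi_x, p$g_lo),
    y = ifelse(model$levels == 1L, p$g_hi_y, p$g_lo)
  )
}
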