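#' Read a model specification from a plain-text config file
#'
#' Key/value lines (`key = value` or `key: value`, `#` comments).
#' Recognized keys: `logic` (a motif id 0-15 or `"MISA"`), `g_lo`,
#' `g_hi` (or `g_hi_x`/`g_hi_y`), `k`, `h_a`, `f_a`, `h_r`, `f_r`, `M`.
#' Unset rates fall back to the [kinetic_params()] defaults.
#'
#' @param path Config file path.
#' @return A `gene_network_model`.
#' @examples
#' cfg <- tempfile(fileext = ".cfg")
#' writeLines(c("logic = MISA", "g_hi = 1.2", "h_a = 100", "f_a = 50",
#'              "h_r = 100", "f_r = 50", "M = 21"), cfg)
#' read_model_config(cfg)
#' @export
read_model_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[=:]", perl = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) {
    abort(paste0("unparseable config line: ", lines[bad][1]),
          class = "coexland_error_io")
  }
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, `[[`, character(1), 2))
  conf <- stats::setNames(as.list(vals), tolower(keys))
  known <- c("logic", "g_lo", "g_hi", "g_hi_x", "g_hi_y", "k",
             "h_a", "f_a", "h_r", "f_r", "m")
  unknown <- setdiff(names(conf), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "coexland_error_io")
  }
  logic <- conf$logic %||% "MISA"
  motif_id <- if (toupper(logic) == "MISA") misa_motif_id() else {
    v <- suppressWarnings(as.integer(logic))
    if (is.na(v)) abort(paste0("invalid logic id: ", logic), class = "coexland_error_io")
    v
  }
  num <- function(key, default) {
    if (is.null(conf[[key]])) return(default)
    v <- suppressWarnings(as.numeric(conf[[key]]))
    if (is.na(v)) abort(paste0("non-numeric value for ", key), class = "coexland_error_io")
    v
  }
  g_hi <- num("g_hi", 1.1)
  params <- kinetic_params(
    g_lo = num("g_lo", 0.001),
    g_hi_x = num("g_hi_x", g_hi), g_hi_y = num("g_hi_y", g_hi),
    k = num("k", 0.2),
    h_a = num("h_a", 100), f_a = num("f_a", 1000),
    h_r = num("h_r", 100), f_r = num("f_r", 1000)
  )
  flex_model(motif_id, params, M = num("m", 21))
}
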