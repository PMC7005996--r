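#' The catalogue of symmetric two-gene regulatory logic variants
#'
#' Each gene's promoter has two binding sites (its own transcription factor
#' and the partner gene's), giving four promoter-binding states:
#' `00` (nothing bound), `self` (own TF bound), `other` (partner TF bound)
#' and `both`. A logic variant assigns a transcription level (`lo` or `hi`)
#' to each promoter state; the assignment for gene Y is always the mirror
#' image of gene X's, so 2^4 = 16 symmetric variants exist. The variant id
#' encodes the four levels as bits in the order (00, self, other, both),
#' least-significant first, with 1 = `hi`.
#'
#' Variants are grouped into motif classes by the sign of the partner
#' gene's effect on transcription (comparing `other` vs `00` and `both` vs
#' `self`): mutual activation, mutual repression, no interaction (which
#' includes purely self-regulating variants), and incoherent variants
#' whose two comparisons disagree in sign. The two constant variants
#' (always `hi`, always `lo`) encode no regulation at all and are flagged
#' non-interacting; sweeps exclude them.
#'
#' @return A tibble with one row per variant: `motif_id` (0-15), levels
#'   `l00`, `lself`, `lother`, `lboth` (0 = `lo`, 1 = `hi`), `motif_class`,
#'   `motif_label`, and `interacting` (`FALSE` only for the two constant
#'   variants).
#' @examples
#' motif_catalogue()
#' @export
motif_catalogue <- function() {
  ids <- 0:15
  lv <- t(vapply(ids, logic_levels, integer(4)))
  colnames(lv) <- c("l00", "lself", "lother", "lboth")
  cls <- vapply(ids, function(i) classify_motif(logic_levels(i)), character(1))
  lab <- vapply(ids, motif_label, character(1))
  tibble::tibble(
    motif_id = ids,
    l00 = lv[, 1], lself = lv[, 2], lother = lv[, 3], lboth = lv[, 4],
    motif_class = cls,
    motif_label = lab,
    interacting = !(ids %in% c(0L, 15L))
  )
}

#' Decode a motif id into per-promoter-state transcription levels
#'
#' @param motif_id Integer in 0-15.
#' @return Integer vector of length 4 (states 00, self, other, both),
#'   0 = `lo`, 1 = `hi`.
#' @examples
#' logic_levels(misa_motif_id()) # c(0, 1, 0, 0)
#' @export
logic_levels <- function(motif_id) {
  if (length(motif_id) != 1L || is.na(motif_id) || motif_id %% 1 != 0 ||
      motif_id < 0 || motif_id > 15) {
    abort("`motif_id` must be a single integer in 0..15.",
          class = "coexland_error_motif_id")
  }
  as.integer(bitwAnd(as.integer(motif_id) %/% c(1L, 2L, 4L, 8L), 1L))
}

#' @rdname logic_levels
#' @export
misa_motif_id <- function() 2L

# Motif class from the sign of the cross-regulatory effect:
# d1 = other vs 00, d2 = both vs self.
classify_motif <- function(levels) {
  d1 <- levels[3] - levels[1]
  d2 <- levels[4] - levels[2]
  if (d1 == 0 && d2 == 0) return("no-interaction")
  if (d1 >= 0 && d2 >= 0) return("mutual-activation")
  if (d1 <= 0 && d2 <= 0) return("mutual-repression")
  "incoherent"
}

motif_label <- function(motif_id) {
  lv <- logic_levels(motif_id)
  if (motif_id == misa_motif_id()) return("MISA")
  if (identical(lv, c(1L, 0L, 1L, 0L))) return("simple repressor")
  if (identical(lv, c(1L, 0L, 0L, 0L))) return("dual repressor")
  if (motif_id == 0L) return("constant off")
  if (motif_id == 15L) return("constant on")
  paste0("logic-", motif_id)
}
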