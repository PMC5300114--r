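#' Plume-finder inheritance rescoring
#'
#' Replaces each window's score with a blend of its own raw score and the
#' (already rescored) scores of its minimally longer "parent" windows — the
#' windows at the next length present in the grid whose spans contain it; at
#' full resolution these are the two windows one residue longer. Processing
#' runs in a single pass from the longest length down to the shortest, so
#' parents are finalized before their children:
#'
#' `new(s, L) = (1 - h) * raw(s, L) + h * mean(new(parents))`
#'
#' Windows with no parent (the longest length, or grid corners with no
#' containing window) keep their raw score; windows with a single parent use
#' that parent alone. With heritability `h` near 1, a short window inherits
#' almost all of its score from the longer windows containing it, which lets
#' the base of a high-scoring "plume" light up even where alignment
#' statistics for short peptides are weak, and smooths pixel-to-pixel noise.
#' A reference value of `h = 0.93` gives strong smoothing. The literature
#' describes this weighted average without printing coefficients; the
#' parents-averaged-then-blended recurrence above is this package's reading,
#' with `h` fully exposed.
#'
#' @param result A `scan_result` with a complete grid for its parameters.
#' @param heritability Blend weight `h` in `[0, 1)`; `h = 0` returns the
#'   input unchanged.
#' @return A rescored copy of `result` (the `score` column is replaced; the
#'   `k_at_min`/`y_at_min`/`min_probability` columns still describe the raw
#'   scan).
#' @export
rescore_inheritance <- function(result, heritability = 0.93) {
  stopifnot(inherits(result, "scan_result"))
  h <- heritability
  if (!(is.numeric(h) && length(h) == 1L && h >= 0 && h < 1)) {
    stop("heritability must lie in [0, 1)")
  }
  w <- result$windows
  new_score <- w$score
  lens <- sort(unique(w$length), decreasing = TRUE)
  idx_by_len <- split(seq_len(nrow(w)), w$length)
  if (length(lens) > 1L) {
    for (li in seq_along(lens)[-1L]) {
      L <- lens[li]
      Lp <- lens[li - 1L]
      children <- idx_by_len[[as.character(L)]]
      parents <- idx_by_len[[as.character(Lp)]]
      pstart <- w$start[parents]
      pnew <- new_score[parents]
      for (i in children) {
        s <- w$start[i]
        sel <- pstart <= s & (pstart + Lp - 1L) >= (s + L - 1L)
        if (any(sel)) {
          new_score[i] <- (1 - h) * w$score[i] + h * mean(pnew[sel])
        }
      }
    }
  }
  out <- result
  out$windows$score <- new_score
  out$rescored <- TRUE
  out
}

#' Extrapolate window scores to single residues
#'
#' Approximates a per-residue score by averaging, for each residue, the
#' scores of every fixed-length window that contains it: an interior residue
#' of a query lies in up to `W` windows of length `W`, while residues within
#' `W - 1` of either terminus are covered by fewer. This is an extrapolation
#' for interpretation, not a score the scan itself asserts — alignment-based
#' scores lose meaning at single-residue scale, so treat the profile as a
#' pointer to regions worth inspecting in alignments or structures.
#'
#' @param result A `scan_result` — raw from [scan_query()], or the output of
#'   [rescore_inheritance()] to profile rescored values.
#' @param W Window length to average over (e.g. 9 or 30). The scan must
#'   contain every length-`W` window at position step 1.
#' @return A data frame with `position` (1-based residue), `value` (mean
#'   score) and `support` (number of contributing windows).
#' @export
residue_scores <- function(result, W) {
  stopifnot(inherits(result, "scan_result"))
  W <- as.integer(W)
  Nq <- result$query_length
  stopifnot(W >= 1L, W <= Nq)
  w <- result$windows[result$windows$length == W, , drop = FALSE]
  need_starts <- seq_len(Nq - W + 1L)
  if (!all(need_starts %in% w$start)) {
    stop("scan grid lacks length-", W, " windows at every position; ",
         "rerun the scan with position_step = 1 and a length grid covering ", W)
  }
  w <- w[match(need_starts, w$start), ]
  cs <- c(0, cumsum(w$score))
  pos <- seq_len(Nq)
  lo <- pmax(1L, pos - W + 1L)
  hi <- pmin(pos, Nq - W + 1L)
  support <- hi - lo + 1L
  data.frame(position = pos, value = (cs[hi + 1L] - cs[lo]) / support,
             support = support)
}
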