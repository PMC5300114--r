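#' Short-rainbow colormap
#'
#' Maps a scaled score in `[0, 1]` to an RGB color running from blue
#' `(0, 0, 255)` at 0 to red `(255, 0, 0)` at 1, through cyan, green and
#' yellow — a "short rainbow" that never enters purple, which reads
#' ambiguously between the two endpoints. The traversal rate through the
#' spectrum is deliberately non-uniform: human vision reads a wide band of
#' wavelengths as much the same green, so the map crosses the green hues
#' quickly and spends more of its range near the blue and red ends, making
#' uniform score changes correspond more closely to uniform perceived color
#' changes. The fixed control points are hue 240/180/120/60/0 degrees at
#' t = 0, 0.30, 0.50, 0.65, 1 (piecewise-linear, strictly monotone in hue).
#'
#' @param t Numeric vector; values are clamped to `[0, 1]`.
#' @return An integer matrix with one row per input and columns `r`, `g`,
#'   `b` in 0-255.
#' @examples
#' short_rainbow(c(0, 0.5, 1))
#' @export
short_rainbow <- function(t) {
  t <- pmin(1, pmax(0, as.numeric(t)))
  breaks <- c(0, 0.30, 0.50, 0.65, 1)
  hues <- c(240, 180, 120, 60, 0)
  h <- stats::approx(breaks, hues, xout = t)$y
  m <- t(grDevices::col2rgb(grDevices::hsv(h / 360, s = 1, v = 1)))
  dimnames(m) <- list(NULL, c("r", "g", "b"))
  m
}

#' Heatmap rendering options
#'
#' @param score_floor Score mapped to blue (default 0).
#' @param score_cap Score mapped to red; `NULL` (default) uses the maximum
#'   score in the data. Fixing a cap puts several plots on one color scale,
#'   which is the recommended way to compare a query against its paralogs.
#' @param point_size Plotting character expansion; `NULL` picks a size that
#'   makes the full-resolution grid read as a continuous triangle.
#' @return A `heatmap_spec` object.
#' @export
heatmap_spec <- function(score_floor = 0, score_cap = NULL,
                         point_size = NULL) {
  if (!is.null(score_cap) && score_cap <= score_floor) {
    stop("score_cap must exceed score_floor")
  }
  structure(list(score_floor = score_floor, score_cap = score_cap,
                 point_size = point_size),
            class = "heatmap_spec")
}

#' Map scores to short-rainbow hex colors
#'
#' Pure function of `(score, floor, cap)`: scores are rescaled to `[0, 1]`
#' between floor and cap (clamping outside values) and passed through
#' [short_rainbow()]. A degenerate range (`cap <= floor`, e.g. a flat
#' negative-control scan) maps everything to blue rather than erroring.
#'
#' @param scores Numeric scores.
#' @param floor,cap Color scale limits.
#' @return A list with `t` (scaled scores) and `hex` (colors).
#' @export
heatmap_colors <- function(scores, floor = 0, cap = max(scores)) {
  t <- if (cap <= floor) rep(0, length(scores)) else
    pmin(1, pmax(0, (scores - floor) / (cap - floor)))
  m <- short_rainbow(t)
  list(t = t, hex = grDevices::rgb(m[, "r"], m[, "g"], m[, "b"],
                                   maxColorValue = 255))
}

#' Render a scan result as a triangular heat map
#'
#' Draws one mark per scored window at x = window midpoint, y = window
#' length, colored by the short-rainbow map of its score. A full-resolution
#' scan yields a triangular silhouette (the full-length window has a single
#' placement at the apex); a scan truncated at a maximum length yields a
#' trapezoid. High-scoring V-shaped "plumes" point their base at the short
#' signature region driving the signal. Alongside the image, a sidecar TSV
#' (`<path>.tsv`) records `midpoint`, `length`, `scaled_score` and `hex` for
#' every mark, for external plotting.
#'
#' @param result A `scan_result`.
#' @param spec A [heatmap_spec()].
#' @param path Output file ending in `.png` or `.svg`.
#' @return Invisibly, a list with `path`, `sidecar` and the mark count.
#' @export
render_heatmap <- function(result, spec = heatmap_spec(), path) {
  stopifnot(inherits(result, "scan_result"), inherits(spec, "heatmap_spec"))
  w <- result$windows
  if (nrow(w) == 0L) stop("scan result contains no windows")
  cap <- if (is.null(spec$score_cap)) max(w$score) else spec$score_cap
  col <- heatmap_colors(w$score, spec$score_floor, cap)
  cex <- spec$point_size
  if (is.null(cex)) cex <- max(0.25, min(2, 250 / result$query_length))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    grDevices::png(path, width = 1400, height = 1000, res = 150,
                   type = "cairo")
  } else if (ext == "svg") {
    grDevices::svg(path, width = 9, height = 6.5)
  } else {
    stop("unsupported output format '.", ext, "'; use .png or .svg")
  }
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4.5, 4.5, 3, 1))
  graphics::plot(w$midpoint, w$length, col = col$hex, pch = 15, cex = cex,
                 xlim = c(1, result$query_length),
                 ylim = c(0, result$query_length),
                 xlab = "subsequence midpoint (residue)",
                 ylab = "subsequence length (residues)",
                 main = paste0(result$query_id,
                               "  (blue = ", signif(spec$score_floor, 3),
                               ", red = ", signif(cap, 3), ")"))
  sidecar <- paste0(path, ".tsv")
  utils::write.table(
    data.frame(midpoint = w$midpoint, length = w$length,
               scaled_score = col$t, hex = col$hex),
    sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(path = path, sidecar = sidecar, marks = nrow(w)))
}
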