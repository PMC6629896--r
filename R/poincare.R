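#' Poincare plot summary (SD1, SD2, ratio)
#'
#' For paired observations (x, y) — univariately y is x delayed by one beat —
#' the cloud's dispersion along the minor axis (perpendicular to the identity
#' line) is `SD1 = sd((y - x)/sqrt(2))` and along the major axis
#' `SD2 = sd((y + x)/sqrt(2))` (sample convention). SD1 reflects short-term,
#' SD2 long-term variability.
#'
#' @param x numeric vector; with `y = NULL` the univariate plot
#'   `x[n]` vs `x[n+1]` is used.
#' @param y optional second channel paired with `x`.
#' @return An object of class `ppa_summary`: list with `sd1`, `sd2`, `ratio`.
#' @export
ppa_summary <- function(x, y = NULL) {
  if (is.null(y)) { y <- x[-1]; x <- x[-length(x)] }
  if (length(x) != length(y))
    stop("x and y must be paired", call. = FALSE)
  if (length(x) < 3L)
    stop("at least three paired points required", call. = FALSE)
  sd1 <- stats::sd((y - x) / sqrt(2))
  sd2 <- stats::sd((y + x) / sqrt(2))
  if (sd2 == 0)
    stop("degenerate geometry: zero dispersion along the major axis",
         call. = FALSE)
  structure(list(sd1 = sd1, sd2 = sd2, ratio = sd1 / sd2),
            class = "ppa_summary")
}

#' Segmented Poincare plot analysis
#'
#' Rotates the Poincare cloud by 45 degrees about its centroid so the major
#' axis is horizontal, then lays a 12 x 12 rectangular grid over the rotated
#' cloud: 12 columns of width SD2/2 spanning the centroid +/- 3 SD2 (major
#' axis) and 12 rows of height SD1/2 spanning +/- 3 SD1 (minor axis). Each
#' cell's occupancy probability is the fraction of points it contains, in
#' percent; points outside the grid accumulate in `out_of_grid`. Row and
#' column probabilities are the sums of their cells. Cells are half-open
#' `[low, high)`, so a point exactly on an internal edge belongs to the
#' higher-index cell. Row 1 is the bottom row, column 1 the left column.
#'
#' @inheritParams ppa_summary
#' @param lag for cross-signal plots (`y` given): pairs `x[n]` with
#'   `y[n + lag]`; default 1 mirrors the univariate construction. Use 0 for
#'   same-beat pairing.
#' @return An object of class `sppa_result`: `cell_probs` (12 x 12, percent,
#'   rows indexed bottom-up), `row_probs`, `col_probs`, `out_of_grid`,
#'   `summary` (a [ppa_summary]).
#' @export
sppa_analyze <- function(x, y = NULL, lag = 1L) {
  if (is.null(y)) { y <- x[-1]; x <- x[-length(x)] }
  else if (lag > 0L) {
    if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
    y <- y[-seq_len(lag)]
    x <- x[seq_len(length(x) - lag)]
  }
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  n <- length(x)
  if (n < 12L) stop("at least 12 paired points required", call. = FALSE)
  sm <- ppa_summary(x, y)
  if (sm$sd1 == 0 || sm$sd2 == 0)
    stop("degenerate geometry: zero SD1 or SD2", call. = FALSE)
  cx <- mean(x); cy <- mean(y)
  # 45-degree rotation about the centroid: u is the minor-axis (SD1)
  # coordinate, v the major-axis (SD2) coordinate
  u <- ((y - cy) - (x - cx)) / sqrt(2)
  v <- ((x - cx) + (y - cy)) / sqrt(2)
  row_edges <- seq(-3 * sm$sd1, 3 * sm$sd1, by = sm$sd1 / 2)
  col_edges <- seq(-3 * sm$sd2, 3 * sm$sd2, by = sm$sd2 / 2)
  ri <- findInterval(u, row_edges, rightmost.closed = FALSE)
  ci <- findInterval(v, col_edges, rightmost.closed = FALSE)
  inside <- ri >= 1L & ri <= 12L & ci >= 1L & ci <= 12L
  cells <- matrix(0, 12, 12)
  if (any(inside)) {
    tab <- table(factor(ri[inside], levels = 1:12),
                 factor(ci[inside], levels = 1:12))
    cells[] <- as.numeric(tab)
  }
  cell_probs <- cells / n * 100
  structure(list(cell_probs = cell_probs,
                 row_probs = rowSums(cell_probs),
                 col_probs = colSums(cell_probs),
                 out_of_grid = sum(!inside) / n * 100,
                 summary = sm, rotation_deg = 45),
            class = "sppa_result")
}

#' SPPA feature vector for one channel pair
#'
#' Emits `SPPAxy_Row_1..12`, `SPPAxy_Column_1..12` and the 144 cell
#' probabilities `SPPAxy_Cell_r_c` (percent).
#'
#' @param x1,x2 beat-value sequences of the two channels.
#' @param tag two-letter coupling tag.
#' @param lag see [sppa_analyze()].
#' @return Named numeric vector of 168 features.
#' @export
sppa_features <- function(x1, x2, tag, lag = 1L) {
  r <- sppa_analyze(x1, x2, lag = lag)
  cells <- as.vector(t(r$cell_probs))
  cn <- as.vector(t(outer(1:12, 1:12, function(i, j)
    paste0("Cell_", i, "_", j))))
  out <- c(r$row_probs, r$col_probs, cells)
  names(out) <- c(paste0("SPPA", tag, "_Row_", 1:12),
                  paste0("SPPA", tag, "_Column_", 1:12),
                  paste0("SPPA", tag, "_", cn))
  out
}

#' Univariate PPA features for one channel
#'
#' @param x beat-value sequence.
#' @param tag single channel letter (`"c"`, `"s"`, `"d"`).
#' @return Named vector `PPAx_SD1`, `PPAx_SD2`, `PPAx_SD1/SD2`.
#' @export
ppa_features <- function(x, tag) {
  sm <- ppa_summary(x)
  out <- c(sm$sd1, sm$sd2, sm$ratio)
  names(out) <- paste0("PPA", tag, c("_SD1", "_SD2", "_SD1/SD2"))
  out
}
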