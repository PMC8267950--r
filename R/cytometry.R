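# DNA image-cytometry histogram classification (Auer-style, reduced to the
# operational diploid/aneuploid rule): a sample is aneuploid when a stem
# line (modal peak of the DNA-content histogram) sits outside the 2c and 4c
# windows, or when more than 10 cells measure above 5c.

#' Build a DNA-content histogram
#'
#' @param c_value numeric DNA content per bin, in c units, strictly
#'   increasing.
#' @param cell_count non-negative integer cells per bin.
#' @return list of class `dna_histogram` with `c_value`, `cell_count`,
#'   `n_cells`.
#' @export
dna_histogram <- function(c_value, cell_count) {
  stopifnot(length(c_value) == length(cell_count))
  if (length(c_value) == 0L) stop("empty histogram")
  if (any(diff(c_value) <= 0)) stop("c_value must be strictly increasing")
  if (any(cell_count < 0) || any(cell_count != round(cell_count)))
    stop("cell_count must be non-negative integers")
  structure(list(c_value = as.numeric(c_value),
                 cell_count = as.integer(round(cell_count)),
                 n_cells = as.integer(sum(cell_count))),
            class = "dna_histogram")
}

#' Read a (c_value, cell_count) TSV into a DNA histogram
#' @param path TSV with columns `c_value` and `cell_count`.
#' @return a [dna_histogram()].
#' @export
read_histogram <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  dna_histogram(df$c_value, df$cell_count)
}

#' Classify a DNA histogram as diploid or aneuploid
#'
#' Stem lines are detected on a Gaussian-kernel smoothing of the histogram
#' (bandwidth `bandwidth` c): local maxima whose topographic prominence
#' reaches what a co-located cluster of `prominence` x n_cells cells would
#' produce. The verdict is aneuploid iff some stem line lies outside
#' +/- `window` of both 2c and 4c, or strictly more than 10 cells measure
#' above 5c; otherwise diploid.
#'
#' @param hist a [dna_histogram()].
#' @param window half-width of the 2c/4c acceptance windows (default 0.25c).
#' @param bandwidth Gaussian kernel bandwidth in c units (default 0.1).
#' @param prominence stem-line prominence floor as a fraction of total cells
#'   (default 0.025).
#' @param min_cells recommended minimum cells; fewer only warns.
#' @return list of class `cytometry_verdict` with `classification`
#'   (`"diploid"`/`"aneuploid"`), `stem_lines` (c positions), and
#'   `cells_above_5c`.
#' @export
classify_histogram <- function(hist, window = 0.25, bandwidth = 0.1,
                               prominence = 0.025, min_cells = 1214L) {
  stopifnot(inherits(hist, "dna_histogram"))
  if (hist$n_cells == 0L) stop("histogram contains no cells")
  if (hist$n_cells < min_cells)
    warning(sprintf("only %d cells measured (recommended minimum %d)",
                    hist$n_cells, min_cells))

  grid <- seq(max(0, min(hist$c_value) - 4 * bandwidth),
              max(hist$c_value) + 4 * bandwidth, by = 0.01)
  dens <- vapply(grid, function(x) {
    sum(hist$cell_count * stats::dnorm(x, mean = hist$c_value,
                                       sd = bandwidth))
  }, numeric(1))

  # prominence floor: the peak height a point mass of `prominence` of all
  # cells would add at the kernel mode
  floor_h <- prominence * hist$n_cells * stats::dnorm(0, sd = bandwidth)
  peaks <- find_peaks(dens, floor_h)
  stem_lines <- grid[peaks]

  above_5c <- sum(hist$cell_count[hist$c_value > 5])
  off_stem <- stem_lines[abs(stem_lines - 2) > window &
                           abs(stem_lines - 4) > window]
  classification <- if (length(off_stem) > 0L || above_5c > 10L)
    "aneuploid" else "diploid"
  structure(list(classification = classification, stem_lines = stem_lines,
                 cells_above_5c = as.integer(above_5c)),
            class = "cytometry_verdict")
}

# indices of local maxima of y with topographic prominence >= floor_h:
# prominence of a peak is its height minus the higher of the two minima
# separating it from higher terrain on either side
find_peaks <- function(y, floor_h) {
  n <- length(y)
  is_max <- which(diff(sign(diff(y))) < 0) + 1L
  keep <- logical(length(is_max))
  for (k in seq_along(is_max)) {
    i <- is_max[k]
    h <- y[i]
    # walk left until higher ground (or the edge); track the lowest valley
    left_min <- h
    j <- i
    while (j > 1L && y[j] <= h) { j <- j - 1L; left_min <- min(left_min, y[j]) }
    if (y[j] <= h) left_min <- min(left_min, 0)  # reached edge: base is 0
    right_min <- h
    j <- i
    while (j < n && y[j] <= h) { j <- j + 1L; right_min <- min(right_min, y[j]) }
    if (y[j] <= h) right_min <- min(right_min, 0)
    keep[k] <- (h - max(left_min, right_min)) >= floor_h
  }
  is_max[keep]
}

#' @export
print.cytometry_verdict <- function(x, ...) {
  cat(sprintf("<cytometry_verdict> %s; stem lines at %s c; %d cells above 5c\n",
              x$classification,
              paste(sprintf("%.2f", x$stem_lines), collapse = ", "),
              x$cells_above_5c))
  invisible(x)
}
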