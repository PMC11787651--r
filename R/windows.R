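# Precursor isolation window schemes: fixed-width, density-balanced
# variable-width, cycle-time estimation, CSV import/export.

.new_scheme <- function(low, high, overlap, ms1_ms, ms2_ms, overhead_ms) {
  s <- data.frame(index = seq_along(low), low = low, high = high)
  attr(s, "overlap") <- overlap
  attr(s, "ms1_ms") <- ms1_ms
  attr(s, "ms2_ms") <- ms2_ms
  attr(s, "overhead_ms") <- overhead_ms
  class(s) <- c("window_scheme", "data.frame")
  s
}

#' Fixed-width isolation window scheme
#'
#' Windows of constant width whose centers advance by (width - overlap)
#' from the first to the last center, as in fixed-window DIA histone methods
#' (35 windows of m/z 24 with 1 Da overlap, centers m/z 307 to 1089).
#'
#' @param first_center,last_center m/z of the first and last window centers.
#' @param width window width (m/z), must exceed \code{overlap}.
#' @param overlap overlap between consecutive windows (Da).
#' @param ms1_ms,ms2_ms,overhead_ms accumulation times and per-scan
#'   overhead (ms) recorded for cycle-time estimation.
#' @return a \code{window_scheme} data.frame (index, low, high).
#' @examples
#' s <- fixed_scheme(307, 1089, 24, 1)
#' nrow(s) # 35
#' @export
fixed_scheme <- function(first_center, last_center, width, overlap = 1,
                         ms1_ms = 100, ms2_ms = 10, overhead_ms = 5.6) {
  if (!(width > overlap && overlap >= 0)) stop("need width > overlap >= 0")
  step <- width - overlap
  k <- (last_center - first_center) / step
  if (abs(k - round(k)) > 1e-9)
    stop("last_center - first_center must be a multiple of width - overlap")
  centers <- first_center + step * (0:round(k))
  .new_scheme(centers - width / 2, centers + width / 2, overlap,
              ms1_ms, rep(ms2_ms, length(centers)), overhead_ms)
}

#' Variable-width isolation window scheme from target density
#'
#' Places window boundaries at equal-count quantiles of the target m/z
#' distribution, so that windows are narrow where targets are dense and
#' wide where they are sparse (emulating vendor variable-window
#' calculators). Each window is then widened to at least \code{min_width},
#' and consecutive windows are extended to overlap by \code{overlap}.
#'
#' @param target_mzs precursor m/z values of the targets.
#' @param n_windows number of windows.
#' @param min_width minimum pre-overlap window width (m/z).
#' @param overlap overlap between consecutive windows (Da).
#' @param range numeric(2) precursor range to cover; must contain all
#'   targets.
#' @inheritParams fixed_scheme
#' @return a \code{window_scheme}.
#' @export
variable_scheme <- function(target_mzs, n_windows, min_width = 5,
                            overlap = 1, range = NULL,
                            ms1_ms = 100, ms2_ms = 10, overhead_ms = 5.6) {
  if (!length(target_mzs)) stop("empty target list")
  stopifnot(n_windows >= 1L)
  x <- sort(target_mzs)
  if (is.null(range)) range <- c(x[1] - min_width, x[length(x)] + min_width)
  if (range[1] > x[1] || range[2] < x[length(x)])
    stop("range must cover all targets")
  N <- length(x)
  # interior boundaries at equal-count cuts: midpoint between the targets
  # on either side of the cut, so per-window counts differ by <= 1
  b <- numeric(n_windows + 1)
  b[1] <- range[1]; b[n_windows + 1] <- range[2]
  if (n_windows > 1) {
    if (N < 2) { # too few targets to define density quantiles
      b <- seq(range[1], range[2], length.out = n_windows + 1)
    } else {
      for (j in seq_len(n_windows - 1)) {
        k <- round(j * N / n_windows)
        k <- min(max(k, 1L), N - 1L)
        b[j + 1] <- (x[k] + x[k + 1]) / 2
      }
    }
  }
  # enforce min pre-overlap width: forward pass then backward clamp
  for (j in 2:(n_windows + 1)) b[j] <- max(b[j], b[j - 1] + min_width)
  if (b[n_windows + 1] > range[2]) {
    b[n_windows + 1] <- range[2]
    for (j in n_windows:1) b[j] <- min(b[j], b[j + 1] - min_width)
    if (b[1] < range[1])
      stop("range too narrow for n_windows * min_width")
    b[1] <- range[1]
  }
  low <- b[-length(b)]; high <- b[-1]
  if (n_windows > 1) {
    low[-1] <- low[-1] - overlap / 2
    high[-length(high)] <- high[-length(high)] + overlap / 2
  }
  .new_scheme(low, high, overlap, ms1_ms, rep(ms2_ms, n_windows), overhead_ms)
}

#' Estimated cycle time of a scheme
#'
#' One cycle is an MS1 scan followed by one MS2 scan per window:
#' MS1 accumulation + sum of window accumulations + per-scan overhead
#' times (n_windows + 1), in seconds. The per-scan overhead captures
#' unlisted instrument transfer time and is an explicit parameter.
#'
#' @param scheme a \code{window_scheme}.
#' @param overhead_ms per-scan overhead (ms); defaults to the value stored
#'   on the scheme.
#' @return cycle time in seconds.
#' @export
cycle_time <- function(scheme, overhead_ms = attr(scheme, "overhead_ms")) {
  n <- nrow(scheme)
  (attr(scheme, "ms1_ms") + sum(attr(scheme, "ms2_ms")) +
     overhead_ms * (n + 1)) / 1000
}

#' @export
print.window_scheme <- function(x, ...) {
  cat("<window_scheme> ", nrow(x), " windows, m/z ",
      sprintf("%.1f", x$low[1]), "-", sprintf("%.1f", x$high[nrow(x)]),
      ", overlap ", attr(x, "overlap"), " Da, cycle ",
      sprintf("%.3f", cycle_time(x)), " s\n", sep = "")
  invisible(x)
}

#' Write / read an isolation scheme as CSV
#'
#' The native format has columns index, low, high, ms2_ms. \code{read_scheme}
#' also accepts vendor-calculator-style two-column (start, stop) files.
#'
#' @param scheme a \code{window_scheme}.
#' @param path CSV path.
#' @param ms1_ms,ms2_ms,overhead_ms timing defaults applied when reading a
#'   two-column vendor file.
#' @export
write_scheme <- function(scheme, path) {
  out <- data.frame(index = scheme$index, low = scheme$low,
                    high = scheme$high, ms2_ms = attr(scheme, "ms2_ms"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path, ms1_ms = 100, ms2_ms = 10, overhead_ms = 5.6) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("low", "high") %in% names(df))) {
    ms2 <- if ("ms2_ms" %in% names(df)) df$ms2_ms else rep(ms2_ms, nrow(df))
  } else if (ncol(df) >= 2) { # vendor two-column start/stop
    names(df)[1:2] <- c("low", "high")
    ms2 <- rep(ms2_ms, nrow(df))
  } else stop("unrecognized scheme file: ", path)
  ord <- order(df$low)
  ov <- if (nrow(df) > 1)
    stats::median(df$high[ord][-nrow(df)] - df$low[ord][-1]) else 0
  .new_scheme(df$low[ord], df$high[ord], ov, ms1_ms, ms2[ord], overhead_ms)
}
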