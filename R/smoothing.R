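# Locally weighted (LOWESS) smoothing of the 8-position structural
# profiles, and equal-width discretization into bins.
#
# The smoother fits, for each window position i, a weighted straight line
# through a neighbourhood S of positions and evaluates it at i.  The
# neighbourhood and the tricube weight normalizer depend on whether i is
# near the left boundary, the right boundary, or interior:
#
#   left   (i - range < 1):      S = [1, 2*range],          h = 2*range - i + 1
#   right  (i + range > len):    S = [len - 2*range, len],  h = i - len + 2*range + 1
#   interior:                    S = [i - range, i + range], h = 2*range + 1
#
# with windows clipped to [1, len].  Weights are tricube,
# w = (1 - (|i - j| / h)^3)^3, clamped to [0, 1].  The boundary
# normalizers are isolated in `lowess_weight_normalizer()` so an
# alternative reading is a one-line change.

lowess_weight_normalizer <- function(i, range, len, case) {
  switch(case,
         left = 2 * range - i + 1,
         right = i - len + 2 * range + 1,
         interior = 2 * range + 1)
}

lowess_window <- function(i, range, len) {
  if (i - range < 1) {
    list(S = seq(1, min(2 * range, len)), case = "left")
  } else if (i + range > len) {
    list(S = seq(max(len - 2 * range, 1), len), case = "right")
  } else {
    list(S = seq(i - range, i + range), case = "interior")
  }
}

tricube_weight <- function(d, h) {
  w <- 1 - (d / h)^3
  pmin(pmax(w, 0), 1)^3
}

#' LOWESS smoothing of an 8-position feature vector
#'
#' Locally weighted linear regression over window positions: for each
#' position a weighted least-squares line is fitted through a
#' neighbourhood (tricube weights, boundary-aware windows, see the module
#' header) and evaluated at that position.  Constant and exactly linear
#' inputs are reproduced unchanged; a degenerate neighbourhood (zero
#' weighted variance) falls back to the weighted mean.
#'
#' @param v numeric vector (a per-feature P4-P4' profile; any length
#'   >= 2 is accepted, 8 in normal use).  Must be free of `NA`; profiles
#'   with missing positions bypass smoothing upstream.
#' @param range smoothing half-width, an integer in 1..5; `0` returns the
#'   input unchanged.
#' @return numeric vector of the same length.
#' @export
#' @examples
#' lowess_smooth(c(1, 2, 3, 4, 5, 6, 7, 8), range = 2)  # a line: unchanged
lowess_smooth <- function(v, range) {
  stopifnot(is.numeric(v), length(v) >= 2)
  if (range == 0) return(v)
  if (anyNA(v)) stop("lowess_smooth input must not contain NA")
  len <- length(v)
  out <- numeric(len)
  for (i in seq_len(len)) {
    win <- lowess_window(i, range, len)
    S <- win$S
    h <- lowess_weight_normalizer(i, range, len, win$case)
    w <- tricube_weight(abs(i - S), h)
    if (sum(w) <= 0 || length(S) < 2) {
      out[i] <- mean(v[S])
      next
    }
    avex <- sum(w * S) / sum(w)
    avey <- sum(w * v[S]) / sum(w)
    mbot <- sum(w * (S - avex)^2)
    if (mbot <= 0) {
      out[i] <- avey
    } else {
      m <- sum(w * (S - avex) * (v[S] - avey)) / mbot
      out[i] <- m * i + (avey - m * avex)
    }
  }
  out
}

#' Fit equal-width bin edges on training values
#'
#' @param training_values numeric vector (NAs ignored).
#' @param bins number of bins, an integer in 1..10.
#' @return numeric vector of `bins - 1` strictly increasing interior
#'   edges spanning the training range; empty for `bins = 1` or for a
#'   degenerate (constant) training set (with a warning).
#' @export
fit_bins <- function(training_values, bins) {
  stopifnot(bins >= 1)
  v <- training_values[is.finite(training_values)]
  if (!length(v)) stop("no finite training values to fit bins on")
  if (bins == 1) return(numeric(0))
  lo <- min(v); hi <- max(v)
  if (lo == hi) {
    warning("all training values identical; collapsing to a single bin")
    return(numeric(0))
  }
  seq(lo, hi, length.out = bins + 1)[seq(2, bins)]
}

#' Discretize values against fitted bin edges
#'
#' Values below the first edge map to bin 0 and values at or above the
#' last edge to the top bin (out-of-training-range values are clipped);
#' a value equal to an edge goes to the upper bin.  Missing values map to
#' `NA` (encoded downstream as an explicit NA category).
#'
#' @param v numeric vector.
#' @param bin_edges sorted interior edges from [fit_bins()].
#' @return integer bin ids in `0 .. length(bin_edges)` (`NA` for missing
#'   input values).
#' @export
discretize <- function(v, bin_edges) {
  if (!length(bin_edges)) {
    out <- rep(0L, length(v))
    out[is.na(v)] <- NA_integer_
    return(out)
  }
  out <- findInterval(v, bin_edges)
  as.integer(out)
}
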