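# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "chromamech_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

#' Trapezoidal integral of sampled values
#'
#' @param x strictly monotonic sample positions
#' @param y values at `x`
#' @return the trapezoid-rule integral, positive when `x` ascends
#' @keywords internal
trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# Linear interpolation at a single point; errors outside the sampled range.
interp_at <- function(x, y, x0) {
  if (x0 < min(x) || x0 > max(x)) {
    stopf("position %g outside sampled range [%g, %g]", x0, min(x), max(x),
          class = "chromamech_range_error")
  }
  stats::approx(x, y, xout = x0, rule = 1)$y
}

# Run code with a temporarily-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Rescale a matrix to [0, 1]; errors on constant input.
rescale01 <- function(x) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) {
    stopf("image is constant; no threshold can be computed",
          class = "chromamech_degenerate_image")
  }
  (x - rng[1]) / diff(rng)
}

# Indices of samples with lo <= x <= hi; errors when the window is empty.
window_idx <- function(x, lo, hi, what = "window") {
  idx <- which(x >= lo & x <= hi)
  if (length(idx) == 0L) {
    stopf("%s [%g, %g] cm^-1 contains no sample points", what, lo, hi,
          class = "chromamech_empty_window")
  }
  idx
}
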