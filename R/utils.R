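# Shared helpers: unit conversions, RNG scoping, small numerics.

# Physical constants (CODATA)
.GAS_CONSTANT <- 8.31446261815324   # J / (mol K)
.FARADAY      <- 96485.33212331001  # C / mol

#' Unit conversion table
#'
#' All internal computation is done in SI; user-facing values use the units
#' conventional in patch-clamp and imaging work (pA, pF, MOhm, mV, ms, um).
#' This table centralises the multiplicative factors from each working unit
#' to its SI base unit.
#'
#' @return Named numeric vector of factors: value_in_SI = value * factor.
#' @examples
#' unit_factors()[["pA"]]  # 1e-12
#' @export
unit_factors <- function() {
  c(
    pA = 1e-12,  pF = 1e-12, MOhm = 1e6, mV = 1e-3, ms = 1e-3,
    um = 1e-6, um2 = 1e-12, pC = 1e-12, nM = 1e-9, mM = 1e-3,
    ohm_cm = 1e-2,          # Ohm*cm -> Ohm*m
    uF_per_cm2 = 1e-2       # uF/cm^2 -> F/m^2
  )
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. Used by every synthetic generator so that identical
# configs give bit-identical output regardless of surrounding code.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_positive <- function(..., .what = NULL) {
  vals <- list(...)
  nms <- if (is.null(.what)) names(vals) else .what
  for (i in seq_along(vals)) {
    if (!is.numeric(vals[[i]]) || any(!is.finite(vals[[i]])) || any(vals[[i]] <= 0)) {
      stop(sprintf("`%s` must be finite and strictly positive", nms[[i]]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# linear interpolation into a matrix at fractional (row, col); 0-based
# pixel-centre convention is handled by callers.
bilinear_sample <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  y0 <- floor(y); x0 <- floor(x)
  y0 <- pmin(pmax(y0, 1L), ny - 1L)
  x0 <- pmin(pmax(x0, 1L), nx - 1L)
  fy <- pmin(pmax(y - y0, 0), 1)
  fx <- pmin(pmax(x - x0, 0), 1)
  i00 <- img[cbind(y0, x0)]
  i01 <- img[cbind(y0, x0 + 1L)]
  i10 <- img[cbind(y0 + 1L, x0)]
  i11 <- img[cbind(y0 + 1L, x0 + 1L)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# local maxima with a prominence and minimum-separation criterion.
# Returns indices into `x`. Prominence of a peak is its height above the
# higher of the two minima separating it from taller neighbours.
find_peaks <- function(x, min_prominence = 0, min_separation = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    left <- x[seq_len(i - 1L)]
    right <- x[seq((i + 1L), n)]
    higher_l <- which(left >= x[i])
    higher_r <- which(right >= x[i])
    lmin <- if (length(higher_l)) min(x[seq(max(higher_l), i - 1L)]) else min(left)
    rmin <- if (length(higher_r)) min(x[seq(i + 1L, i + min(higher_r))]) else min(right)
    x[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (!length(keep)) return(integer(0))
  # enforce separation, keeping taller peaks first
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord) {
    if (!length(sel) || all(abs(sel - i) >= min_separation)) sel <- c(sel, i)
  }
  sort(sel)
}
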