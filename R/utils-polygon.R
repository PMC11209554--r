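# Planar geometry primitives shared by the generator (exact, vector side) and
# the trait extractor (pixel side). The convex hull is deliberately authored
# here (Andrew's monotone chain); tests cross-check it against grDevices::chull
# and a brute-force oracle.

#' Convex hull of a 2-D point set (monotone chain)
#'
#' @param pts numeric matrix with two columns (x, y).
#' @return matrix of hull vertices in counter-clockwise order, without the
#'   closing vertex repeated. Returns fewer than 3 rows for degenerate input
#'   (all points collinear or coincident).
#' @keywords internal
#' @noRd
monotone_chain_hull <- function(pts) {
  stopifnot(is.matrix(pts), ncol(pts) == 2)
  pts <- akl_toussaint_filter(pts)
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3) return(pts)
  ord <- order(pts[, 1], pts[, 2])
  p <- pts[ord, , drop = FALSE]
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(p[h[length(h) - 1], ], p[h[length(h)], ], p[i, ]) <= 0) {
        h <- h[-length(h)]
      }
      h <- c(h, i)
    }
    h
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  hull <- c(lower[-length(lower)], upper[-length(upper)])
  if (length(hull) < 3) return(p[unique(hull), , drop = FALSE])
  p[hull, , drop = FALSE]
}

# Discard points strictly inside the octagon spanned by the extremes of
# x, y, x+y and x-y; hull vertices are never discarded. Cuts the monotone
# chain's sequential loop down to the outer ring of points.
akl_toussaint_filter <- function(pts) {
  n <- nrow(pts)
  if (n <= 16) return(pts)
  x <- pts[, 1]; y <- pts[, 2]
  s <- x + y; d <- x - y
  oct <- pts[c(which.min(x), which.min(s), which.min(y), which.max(d),
               which.max(x), which.max(s), which.max(y), which.min(d)), ,
             drop = FALSE]
  oct <- unique(oct)
  m <- nrow(oct)
  if (m < 3) return(pts)
  inside <- rep(TRUE, n)
  for (i in seq_len(m)) {
    a <- oct[i, ]; b <- oct[if (i == m) 1 else i + 1, ]
    cr <- (b[1] - a[1]) * (y - a[2]) - (b[2] - a[2]) * (x - a[1])
    inside <- inside & (cr > 1e-12)
    if (!any(inside)) break
  }
  pts[!inside, , drop = FALSE]
}

#' Shoelace area of a simple polygon (absolute value)
#' @keywords internal
#' @noRd
polygon_area <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Boundary length of a closed polygon
#' @keywords internal
#' @noRd
polygon_perimeter <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 2) return(0)
  d <- xy - xy[c(2:n, 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' Circular mean of angles in degrees, result in [0, 360)
#' @keywords internal
#' @noRd
circular_mean_deg <- function(deg, w = NULL) {
  if (length(deg) == 0) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(deg))
  rad <- deg * pi / 180
  m <- atan2(sum(w * sin(rad)) / sum(w), sum(w * cos(rad)) / sum(w))
  (m * 180 / pi) %% 360
}

# Derive a child RNG seed from a base seed and stream offsets; stays a valid
# 32-bit integer.
child_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  s <- 0
  for (k in ks) s <- (s * 69069 + as.numeric(k) + 1) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
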