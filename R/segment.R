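#' HSB threshold ranges for shoot segmentation
#'
#' Foreground pixels must fall inside all three ranges. The hue range is in
#' degrees and may wrap through 0 (a range with `lo > hi` means
#' `[lo, 360) U [0, hi]`). Defaults are calibrated to the synthetic color
#' model (green shoots on a brown substrate).
#'
#' @param hue,sat,bri two-element `c(lo, hi)` ranges; hue in degrees
#'   `[0, 360)`, saturation and brightness in `[0, 1]`.
#' @return list of class `hsb_thresholds`.
#' @export
hsb_thresholds <- function(hue = c(60, 180), sat = c(0.15, 1),
                           bri = c(0.12, 0.98)) {
  stopifnot(length(hue) == 2, length(sat) == 2, length(bri) == 2,
            all(hue >= 0 & hue < 360),
            all(sat >= 0 & sat <= 1), sat[1] <= sat[2],
            all(bri >= 0 & bri <= 1), bri[1] <= bri[2])
  structure(list(hue = hue, sat = sat, bri = bri), class = "hsb_thresholds")
}

#' Segment shoot from substrate by HSB thresholding
#'
#' Converts the RGB frame to HSB (hue in degrees) and marks a pixel as
#' foreground iff its hue, saturation and brightness each fall inside the
#' configured range. The operation is strictly pointwise.
#'
#' @param image numeric array `h x w x 3` in `[0, 1]`.
#' @param thr an [hsb_thresholds()].
#' @return logical matrix (the mask) with attribute `thresholds`.
#' @export
segment_hsb <- function(image, thr = hsb_thresholds()) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("segment_hsb needs a 3-channel RGB image")
  }
  stopifnot(inherits(thr, "hsb_thresholds"))
  d <- dim(image)
  hsv <- grDevices::rgb2hsv(rbind(as.vector(image[, , 1]),
                                  as.vector(image[, , 2]),
                                  as.vector(image[, , 3])),
                            maxColorValue = 1)
  h <- hsv[1, ] * 360; s <- hsv[2, ]; v <- hsv[3, ]
  in_hue <- if (thr$hue[1] <= thr$hue[2]) {
    h >= thr$hue[1] & h <= thr$hue[2]
  } else {
    h >= thr$hue[1] | h <= thr$hue[2]
  }
  mask <- matrix(in_hue &
                   s >= thr$sat[1] & s <= thr$sat[2] &
                   v >= thr$bri[1] & v <= thr$bri[2],
                 d[1], d[2])
  attr(mask, "thresholds") <- thr
  mask
}

#' 8-connected component labeling
#'
#' EBImage's labeling is 4-connected; diagonally adjacent components are
#' merged here (via a component graph) so that thin petioles stay connected.
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  k <- max(lab)
  if (k <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]    # down-left diagonal
  pick <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    cbind(a[sel], b[sel])
  }
  edges <- rbind(pick(a1, b1), pick(a2, b2))
  if (nrow(edges) == 0) return(lab)
  g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, k - igraph::vcount(g)))
  mem <- igraph::components(g)$membership
  out <- lab
  out[lab > 0L] <- as.integer(mem[lab[lab > 0L]])
  out
}

#' Morphological cleanup of a segmentation mask
#'
#' Applies a morphological closing (disc brush) and then removes 8-connected
#' components smaller than `min_component_px`. With both parameters zero the
#' operation is the identity. If every component is removed the (empty) mask
#' is returned with attribute `all_removed = TRUE` and a warning, not an
#' error.
#'
#' @param mask logical matrix.
#' @param min_component_px minimum component size kept, pixels.
#' @param closing_radius_px radius of the closing brush, pixels (0 = none).
#' @return logical matrix with attributes `n_components_kept`,
#'   `n_components_removed` and (possibly) `all_removed`.
#' @export
clean_mask <- function(mask, min_component_px = 40, closing_radius_px = 0) {
  stopifnot(is.matrix(mask), min_component_px >= 0, closing_radius_px >= 0)
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius_px + 1, shape = "disc")
    m <- EBImage::closing(matrix(as.numeric(m), nrow(m), ncol(m)),
                          kern = brush) > 0.5
  }
  lab <- label_components(m)
  k <- max(lab)
  kept <- removed <- 0L
  if (k > 0) {
    sizes <- tabulate(lab[lab > 0L], nbins = k)
    keep <- which(sizes >= min_component_px)
    kept <- length(keep); removed <- k - kept
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  out <- m
  attr(out, "n_components_kept") <- kept
  attr(out, "n_components_removed") <- removed
  if (kept == 0L && any(mask)) {
    attr(out, "all_removed") <- TRUE
    warning("clean_mask removed every component; returning an empty mask")
  }
  out
}
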