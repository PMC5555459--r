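# Threshold segmentation of nuclei and chromocenters from 8-bit fields,
# mirroring the outline-then-measure order of the original imaging macro.

#' Segmentation parameters
#'
#' @param smoothing_sigma Gaussian pre-smoothing SD in pixels (0 disables).
#' @param nucleus_threshold_method "otsu" (default) or "fixed".
#' @param nucleus_threshold Intensity cutoff used when the method is "fixed".
#' @param min_nucleus_area Minimum nucleus size in pixels.
#' @param drop_border_objects Remove nuclei touching the image border
#'   (truncated objects bias area and perimeter).
#' @param cc_threshold_k Chromocenter cutoff is mean + k*SD of nucleus
#'   pixel intensities (dimensionless, > 0).
#' @param min_cc_area Minimum chromocenter size in pixels.
#' @param cc_threshold_scope "per_nucleus" (default; each nucleus gets its
#'   own cutoff) or "global" (one cutoff from all nucleus pixels pooled).
#' @return A \code{segmentation_config} list.
#' @export
segmentation_config <- function(smoothing_sigma = 2,
                                nucleus_threshold_method = c("otsu", "fixed"),
                                nucleus_threshold = NULL,
                                min_nucleus_area = 200,
                                drop_border_objects = TRUE,
                                cc_threshold_k = 2,
                                min_cc_area = 4,
                                cc_threshold_scope = c("per_nucleus", "global")) {
  stopifnot(smoothing_sigma >= 0, min_nucleus_area >= 1,
            cc_threshold_k > 0, min_cc_area >= 1)
  method <- match.arg(nucleus_threshold_method)
  if (method == "fixed" && is.null(nucleus_threshold)) {
    stop("fixed method needs nucleus_threshold")
  }
  structure(list(smoothing_sigma = smoothing_sigma,
                 nucleus_threshold_method = method,
                 nucleus_threshold = nucleus_threshold,
                 min_nucleus_area = min_nucleus_area,
                 drop_border_objects = drop_border_objects,
                 cc_threshold_k = cc_threshold_k,
                 min_cc_area = min_cc_area,
                 cc_threshold_scope = match.arg(cc_threshold_scope)),
            class = "segmentation_config")
}

validate_image <- function(image) {
  if (!is.matrix(image) || nrow(image) < 16 || ncol(image) < 16) {
    stop("image must be a matrix of at least 16 x 16 pixels")
  }
  if (min(image) < 0 || max(image) > 255) stop("image values must lie in [0, 255]")
  invisible(image)
}

# Otsu threshold on the integer 0-255 histogram (maximise between-class
# variance; smallest maximiser on ties). Operating on whole-intensity bins
# makes the split exactly equivariant under integer intensity shifts.
otsu_threshold <- function(v) {
  h <- tabulate(pmin(255, pmax(0, v)) + 1, 256)
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(as.numeric(h))
  m0 <- cumsum(as.numeric(h) * lev)
  mt <- m0[256]
  w1 <- n - w0
  between <- ifelse(w0 > 0 & w1 > 0, (mt * w0 - m0 * n)^2 / (w0 * w1), 0)
  lev[which.max(between)]
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally and relabel contiguously in raster order.
label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  mx <- max(lab)
  if (mx <= 1) return(matrix(as.integer(lab), nrow(mask), ncol(mask)))
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]      # down-right neighbours
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]     # down-left neighbours
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  parent <- seq_len(mx)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  merge_pairs <- function(p, q) {
    for (i in seq_along(p)) {
      rp <- find(p[i]); rq <- find(q[i])
      if (rp != rq) parent[max(rp, rq)] <<- min(rp, rq)
    }
  }
  merge_pairs(a1[sel1], b1[sel1])
  merge_pairs(a2[sel2], b2[sel2])
  root <- vapply(seq_len(mx), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- matrix(0L, nr, nc)
  nz <- lab > 0
  out[nz] <- relab[lab[nz]]
  out
}

relabel_sequential <- function(mask) {
  keep <- sort(unique(mask[mask > 0]))
  if (!length(keep)) return(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  nz <- mask > 0
  out[nz] <- match(mask[nz], keep)
  out
}

#' Segment nuclei in an 8-bit field
#'
#' Gaussian smoothing, a global intensity threshold (Otsu by default), hole
#' filling of the nucleus outlines, removal of small and (optionally)
#' border-touching objects, then 8-connected labeling. A featureless
#' (constant) image yields an empty mask rather than an error.
#'
#' @param image Numeric matrix, 8-bit scale (0-255), at least 16 x 16.
#' @param config A \code{\link{segmentation_config}}.
#' @return Integer label matrix, 0 = background, labels contiguous from 1.
#' @export
segment_nuclei <- function(image, config = segmentation_config()) {
  validate_image(image)
  if (max(image) == min(image)) {
    return(matrix(0L, nrow(image), ncol(image)))
  }
  sm <- image
  if (config$smoothing_sigma > 0) {
    sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(image / 255),
                                            sigma = config$smoothing_sigma)) * 255
  }
  fg <- if (config$nucleus_threshold_method == "otsu") {
    floor(sm) > otsu_threshold(floor(sm))
  } else {
    sm > config$nucleus_threshold
  }
  fg <- EBImage::imageData(EBImage::fillHull(EBImage::Image(fg + 0))) > 0
  lab <- label8(fg)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < config$min_nucleus_area)
    if (config$drop_border_objects) {
      border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
      drop <- union(drop, border[border > 0])
    }
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab <- relabel_sequential(lab)
  }
  lab
}

#' Segment chromocenters within segmented nuclei
#'
#' Inside each nucleus, pixels brighter than mean + k*SD of that nucleus's
#' intensities (k = \code{cc_threshold_k}) are chromocenter candidates;
#' 8-connected blobs below \code{min_cc_area} are discarded. With scope
#' "global", one cutoff is computed from all nucleus pixels pooled.
#' Chromocenter pixels are by construction a subset of their parent nucleus.
#'
#' @param image The image passed to \code{\link{segment_nuclei}}.
#' @param nucleus_mask Label mask from \code{\link{segment_nuclei}}.
#' @param config A \code{\link{segmentation_config}}.
#' @return Integer label matrix with attribute \code{parent}: integer vector
#'   mapping each chromocenter label to its parent nucleus label.
#' @export
segment_chromocenters <- function(image, nucleus_mask,
                                  config = segmentation_config()) {
  validate_image(image)
  if (!all(dim(image) == dim(nucleus_mask))) {
    stop("image and nucleus_mask shapes differ")
  }
  out <- matrix(0L, nrow(image), ncol(image))
  parent <- integer(0)
  n_nuc <- max(nucleus_mask)
  if (n_nuc == 0) return(structure(out, parent = parent))
  global_thr <- NULL
  if (config$cc_threshold_scope == "global") {
    px <- image[nucleus_mask > 0]
    global_thr <- mean(px) + config$cc_threshold_k * stats::sd(px)
  }
  nxt <- 0L
  for (l in seq_len(n_nuc)) {
    inside <- nucleus_mask == l
    px <- image[inside]
    thr <- if (is.null(global_thr)) {
      s <- stats::sd(px)
      if (is.na(s)) s <- 0
      mean(px) + config$cc_threshold_k * s
    } else global_thr
    cand <- inside & image > thr
    if (!any(cand)) next
    lab <- label8(cand)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= config$min_cc_area)
    for (k in keep) {
      nxt <- nxt + 1L
      out[lab == k] <- nxt
      parent[nxt] <- l
    }
  }
  structure(out, parent = parent)
}

#' Estimate the image background intensity
#'
#' Median intensity of pixels outside every nucleus, after excluding a 2-px
#' dilation rim around the nuclei so halo pixels do not bias the estimate.
#'
#' @param image Numeric matrix, 8-bit scale.
#' @param nucleus_mask Label mask from \code{\link{segment_nuclei}} (ground
#'   truth masks work equally).
#' @return Scalar background intensity on the 0-255 scale.
#' @export
estimate_background <- function(image, nucleus_mask) {
  validate_image(image)
  if (!all(dim(image) == dim(nucleus_mask))) {
    stop("image and nucleus_mask shapes differ")
  }
  fg <- nucleus_mask > 0
  if (any(fg)) {
    brush <- EBImage::makeBrush(5, shape = "disc")  # radius-2 rim
    fg <- EBImage::imageData(EBImage::dilate(EBImage::Image(fg + 0), brush)) > 0
  }
  if (all(fg)) stop("no background pixels left after excluding nuclei")
  stats::median(image[!fg])
}
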