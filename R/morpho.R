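# Per-object morphometry: area, mean DAPI intensity ("density"), perimeter,
# roundness, heterogeneity, and the relative heterochromatin fraction (RHF).

# Crofton 4-direction perimeter: P = pi/4 * sum over directions of
# (run count * line spacing); spacing is 1 for the axis directions and
# 1/sqrt(2) for the two diagonals. Near-unbiased on digital discs, so the
# isoperimetric bound roundness >= ~1 holds.
crofton_perimeter <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  pad_l <- cbind(FALSE, fg[, -nc, drop = FALSE])
  pad_u <- rbind(FALSE, fg[-nr, , drop = FALSE])
  runs_h <- sum(fg & !pad_l)
  runs_v <- sum(fg & !pad_u)
  pad_ul <- rbind(FALSE, cbind(FALSE, fg[-nr, -nc, drop = FALSE]))
  pad_ur <- rbind(FALSE, cbind(fg[-nr, -1, drop = FALSE], FALSE))
  runs_d1 <- sum(fg & !pad_ul)
  runs_d2 <- sum(fg & !pad_ur)
  pi / 4 * (runs_h + runs_v + (runs_d1 + runs_d2) / sqrt(2))
}

# Macro-compatible alternative: number of object pixels with at least one
# 4-neighbour outside the object ("length of the outline in pixels").
boundary_pixel_perimeter <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  up <- rbind(FALSE, fg[-nr, , drop = FALSE])
  dn <- rbind(fg[-1, , drop = FALSE], FALSE)
  lf <- cbind(FALSE, fg[, -nc, drop = FALSE])
  rt <- cbind(fg[, -1, drop = FALSE], FALSE)
  sum(fg & !(up & dn & lf & rt))
}

#' Measure one object's morphometric parameters
#'
#' Computes, for the pixels carrying \code{label} in \code{label_mask}:
#' area (pixel count), intensity (mean 8-bit level; the trait some tables
#' call "density"), perimeter (Crofton 4-direction estimate by default, or
#' the macro-compatible boundary-pixel count), roundness =
#' Perimeter^2 / (4 * pi * Area) (1 for an ideal circle), and heterogeneity
#' = fraction of the object's pixels whose intensity deviates strictly more
#' than 10% from the object mean.
#'
#' @param image Numeric matrix, 8-bit scale.
#' @param label_mask Integer label matrix, same shape.
#' @param label Positive label present in the mask.
#' @param perimeter_method "crofton" or "boundary_pixels".
#' @return One-row \code{data.frame}: \code{object_id, area, intensity,
#'   perimeter, roundness, heterogeneity}.
#' @export
measure_object <- function(image, label_mask, label,
                           perimeter_method = c("crofton", "boundary_pixels")) {
  perimeter_method <- match.arg(perimeter_method)
  if (!all(dim(image) == dim(label_mask))) stop("image and mask shapes differ")
  fg <- label_mask == label
  if (!any(fg)) stop("label ", label, " not present in mask")
  px <- image[fg]
  area <- sum(fg)
  intensity <- mean(px)
  per <- if (perimeter_method == "crofton") crofton_perimeter(fg) else
    boundary_pixel_perimeter(fg)
  het <- if (intensity > 0) mean(abs(px - intensity) > 0.10 * intensity) else 0
  data.frame(object_id = label, area = area, intensity = intensity,
             perimeter = per, roundness = per^2 / (4 * pi * area),
             heterogeneity = het)
}

#' Relative heterochromatin fraction of one nucleus
#'
#' RHF = sum over the nucleus's chromocenters of
#' Area_cc * (Intensity_cc - background), divided by
#' Area_nu * (Intensity_nu - background): the background-corrected share of
#' the nucleus's DAPI fluorescence held in chromocenters. Noise can push
#' per-object estimates outside [0, 1]; the value is clipped with a warning.
#'
#' @param nucleus_record One-row measurement of the nucleus
#'   (\code{\link{measure_object}}).
#' @param cc_records Measurements of the nucleus's chromocenters (0 or more
#'   rows).
#' @param background Background intensity (\code{\link{estimate_background}}).
#' @return RHF in [0, 1]; 0 when there are no chromocenters.
#' @export
compute_rhf <- function(nucleus_record, cc_records, background) {
  denom <- nucleus_record$area * (nucleus_record$intensity - background)
  if (denom <= 0) stop("nucleus intensity does not exceed background")
  if (is.null(cc_records) || nrow(cc_records) == 0) return(0)
  num <- sum(cc_records$area * (cc_records$intensity - background))
  rhf <- num / denom
  if (rhf < 0 || rhf > 1) {
    warning("RHF outside [0, 1]; clipping")
    rhf <- min(1, max(0, rhf))
  }
  rhf
}

#' Summarise one nucleus with its chromocenters
#'
#' Chromocenter traits are averaged per nucleus by an unweighted arithmetic
#' mean, the chromocenter count and RHF are attached; a nucleus without
#' chromocenters gets NA averages, count 0 and RHF 0.
#'
#' @param nucleus_record One-row nucleus measurement; may carry a
#'   \code{parent check} via \code{nucleus_record$object_id}.
#' @param cc_records Chromocenter measurements with a
#'   \code{parent_nucleus_id} column (all equal to the nucleus id).
#' @param background Background intensity.
#' @return One-row \code{data.frame}: nucleus traits prefixed \code{nuc_},
#'   \code{cc_count}, \code{cc_mean_*} averages, \code{rhf},
#'   \code{background}.
#' @export
summarize_nucleus <- function(nucleus_record, cc_records, background) {
  if (!is.null(cc_records) && nrow(cc_records) > 0 &&
      "parent_nucleus_id" %in% names(cc_records) &&
      any(cc_records$parent_nucleus_id != nucleus_record$object_id)) {
    stop("chromocenter records belong to a different nucleus")
  }
  n_cc <- if (is.null(cc_records)) 0L else nrow(cc_records)
  avg <- function(col) if (n_cc > 0) mean(cc_records[[col]]) else NA_real_
  data.frame(
    nucleus_id = nucleus_record$object_id,
    nuc_area = nucleus_record$area,
    nuc_intensity = nucleus_record$intensity,
    nuc_perimeter = nucleus_record$perimeter,
    nuc_roundness = nucleus_record$roundness,
    nuc_heterogeneity = nucleus_record$heterogeneity,
    cc_count = n_cc,
    cc_mean_area = avg("area"),
    cc_mean_intensity = avg("intensity"),
    cc_mean_perimeter = avg("perimeter"),
    cc_mean_roundness = avg("roundness"),
    cc_mean_heterogeneity = avg("heterogeneity"),
    rhf = compute_rhf(nucleus_record, cc_records, background),
    background = background
  )
}

#' Measure every nucleus and chromocenter in a field
#'
#' Convenience wrapper running \code{\link{measure_object}} over all labels
#' of both masks and \code{\link{summarize_nucleus}} per nucleus.
#'
#' @param image Numeric matrix, 8-bit scale.
#' @param nucleus_mask Nucleus label mask.
#' @param cc_mask Chromocenter label mask with a \code{parent} attribute
#'   (as from \code{\link{segment_chromocenters}}), or ground truth with an
#'   explicit \code{cc_parent} argument.
#' @param cc_parent Optional integer vector mapping chromocenter labels to
#'   nucleus labels (overrides the mask attribute).
#' @param background Background intensity; estimated from the image when
#'   NULL.
#' @param perimeter_method Passed to \code{\link{measure_object}}.
#' @return List with \code{nuclei} (one \code{\link{summarize_nucleus}} row
#'   per nucleus) and \code{chromocenters} (per-object rows with
#'   \code{parent_nucleus_id}).
#' @export
measure_image <- function(image, nucleus_mask, cc_mask,
                          cc_parent = NULL, background = NULL,
                          perimeter_method = "crofton") {
  if (is.null(cc_parent)) cc_parent <- attr(cc_mask, "parent")
  if (is.null(background)) background <- estimate_background(image, nucleus_mask)
  n_nuc <- max(nucleus_mask)
  cc_labels <- if (max(cc_mask) > 0) seq_len(max(cc_mask)) else integer(0)
  cc_tab <- NULL
  if (length(cc_labels)) {
    if (is.null(cc_parent) || length(cc_parent) < length(cc_labels)) {
      stop("cc_parent mapping required for chromocenter labels")
    }
    cc_tab <- do.call(rbind, lapply(cc_labels, function(l) {
      r <- measure_object(image, cc_mask, l, perimeter_method)
      r$parent_nucleus_id <- cc_parent[l]
      r
    }))
  }
  nuclei <- do.call(rbind, lapply(seq_len(n_nuc), function(l) {
    rec <- measure_object(image, nucleus_mask, l, perimeter_method)
    ccs <- if (!is.null(cc_tab)) cc_tab[cc_tab$parent_nucleus_id == l, ] else NULL
    summarize_nucleus(rec, ccs, background)
  }))
  list(nuclei = nuclei, chromocenters = cc_tab)
}
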