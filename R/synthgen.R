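# Synthetic data: genetic maps, selfed-RIL genotypes, trait tables with
# planted QTL, and rendered nucleus images with ground-truth label masks.

#' Haldane map function
#'
#' Converts a genetic map distance to a recombination fraction assuming no
#' interference: r = (1 - exp(-2d/100))/2 for d in centimorgan.
#'
#' @param d_cM Map distance in cM (vectorised, >= 0).
#' @return Recombination fraction in [0, 0.5).
#' @export
haldane_r <- function(d_cM) {
  stopifnot(all(d_cM >= 0))
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' Selfed-RIL recombination fraction
#'
#' For recombinant inbred lines derived by repeated selfing, the observed
#' fraction of recombinant lines between two loci with per-meiosis
#' recombination fraction r is R = 2r/(1 + 2r) (Haldane-Waddington).
#'
#' @param r Per-meiosis recombination fraction in [0, 0.5].
#' @return RIL recombination fraction in [0, 0.5].
#' @export
ril_R <- function(r) {
  stopifnot(all(r >= 0), all(r <= 0.5))
  2 * r / (1 + 2 * r)
}

#' Build an evenly spaced genetic map
#'
#' Markers are placed every \code{marker_step_cM} from 0 to the chromosome
#' length; both chromosome ends always carry a marker. A step larger than the
#' chromosome length degenerates to end markers only.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param chrom_lengths_cM Numeric vector of chromosome lengths in cM
#'   (length 1 is recycled).
#' @param marker_step_cM Inter-marker distance in cM (> 0).
#' @return A \code{data.frame} with columns \code{marker}, \code{chromosome},
#'   \code{position_cM}, of class \code{c("genetic_map", "data.frame")}.
#' @examples
#' make_genetic_map(5, 100, 5)
#' @export
make_genetic_map <- function(n_chrom, chrom_lengths_cM, marker_step_cM) {
  if (n_chrom < 1) stop("n_chrom must be >= 1")
  if (any(chrom_lengths_cM <= 0)) stop("chromosome lengths must be positive")
  if (marker_step_cM <= 0) stop("marker_step_cM must be positive")
  lens <- rep_len(chrom_lengths_cM, n_chrom)
  rows <- lapply(seq_len(n_chrom), function(ch) {
    pos <- seq(0, lens[ch], by = marker_step_cM)
    if (max(pos) < lens[ch]) pos <- c(pos, lens[ch])
    pos <- unique(pos)
    data.frame(
      marker = sprintf("c%dm%02d", ch, seq_along(pos)),
      chromosome = ch,
      position_cM = pos,
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, rows)
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}

validate_map <- function(map) {
  req <- c("marker", "chromosome", "position_cM")
  if (!all(req %in% names(map))) {
    stop("genetic map needs columns ", paste(req, collapse = ", "))
  }
  if (nrow(map) == 0) stop("genetic map is empty")
  if (anyDuplicated(map$marker)) stop("duplicate marker names in map")
  for (ch in unique(map$chromosome)) {
    p <- map$position_cM[map$chromosome == ch]
    if (is.unsorted(p)) stop("marker positions not nondecreasing on chromosome ", ch)
  }
  invisible(map)
}

#' Simulate genotypes of a selfed RIL population
#'
#' Each line is an independent Markov chain along each chromosome: the first
#' marker is A or B with probability 1/2 and the genotype switches between
#' adjacent markers with probability R = 2r/(1+2r), where r is the Haldane
#' recombination fraction for the inter-marker distance. A is the
#' recurrent-parent-type allele, B the donor-type allele; selfed RILs carry
#' only homozygous codes.
#'
#' @param map A genetic map from \code{\link{make_genetic_map}}.
#' @param n_lines Number of lines (>= 1).
#' @param seed Integer seed; all randomness flows from it.
#' @return Character matrix (lines x markers) with entries "A"/"B";
#'   rownames are line ids, colnames marker names.
#' @export
simulate_ril_genotypes <- function(map, n_lines, seed = 1) {
  validate_map(map)
  if (n_lines < 1) stop("n_lines must be >= 1")
  set.seed(seed)
  geno <- matrix(NA_character_, n_lines, nrow(map),
                 dimnames = list(sprintf("RIL%03d", seq_len(n_lines)), map$marker))
  for (ch in unique(map$chromosome)) {
    idx <- which(map$chromosome == ch)
    d <- diff(map$position_cM[idx])
    Rsw <- ril_R(haldane_r(d))
    cur <- ifelse(stats::runif(n_lines) < 0.5, "A", "B")
    geno[, idx[1]] <- cur
    for (k in seq_along(d)) {
      flip <- stats::runif(n_lines) < Rsw[k]
      cur <- ifelse(flip, ifelse(cur == "A", "B", "A"), cur)
      geno[, idx[k + 1]] <- cur
    }
  }
  geno
}

#' Simulate per-nucleus trait values with planted QTL
#'
#' Each line's genetic value is the sum of planted additive effects: a QTL
#' with effect \code{a} contributes \code{+a} to lines carrying A and
#' \code{-a} to lines carrying B at the marker nearest the QTL position
#' (so the two genotype class means differ by \code{2a}). A line-level
#' residual N(0, sigma_line^2) is added, and every nucleus observes the line
#' value plus N(0, sigma_nucleus^2). Nuclei are assigned to plants
#' round-robin.
#'
#' @param genotypes Matrix from \code{\link{simulate_ril_genotypes}}.
#' @param map The genetic map the genotypes were simulated on.
#' @param qtl_spec \code{data.frame} with columns \code{chromosome},
#'   \code{position_cM}, \code{effect} (sign = effect of the A allele
#'   relative to the population mean); may have zero rows.
#' @param sigma_line Between-line residual SD (>= 0).
#' @param sigma_nucleus Within-line (per-nucleus) SD (>= 0).
#' @param n_nuclei_per_line Nuclei measured per line (>= 1).
#' @param n_plants_per_line Plants per line the nuclei are spread over.
#' @param seed Integer seed.
#' @param trait Name of the trait column in the output.
#' @return Long trait table: \code{data.frame(line_id, plant_id, nucleus_id,
#'   <trait>)}. Attributes: \code{line_values} (named numeric),
#'   \code{h2_true} (ground-truth between/total variance ratio,
#'   \code{(sum(a^2) + sigma_line^2) / (sum(a^2) + sigma_line^2 +
#'   sigma_nucleus^2)}), and \code{qtl_markers} (nearest marker per QTL).
#' @export
simulate_trait_values <- function(genotypes, map, qtl_spec,
                                  sigma_line, sigma_nucleus,
                                  n_nuclei_per_line = 30,
                                  n_plants_per_line = 2,
                                  seed = 1, trait = "trait") {
  validate_map(map)
  stopifnot(sigma_line >= 0, sigma_nucleus >= 0, n_nuclei_per_line >= 1)
  n_lines <- nrow(genotypes)
  set.seed(seed)

  g <- numeric(n_lines)
  qtl_markers <- character(0)
  if (!is.null(qtl_spec) && nrow(qtl_spec) > 0) {
    for (i in seq_len(nrow(qtl_spec))) {
      on_ch <- map$chromosome == qtl_spec$chromosome[i]
      if (!any(on_ch)) stop("QTL chromosome not in map")
      pos <- map$position_cM[on_ch]
      q <- qtl_spec$position_cM[i]
      if (q < min(pos) || q > max(pos)) stop("QTL position off the map")
      nearest <- map$marker[on_ch][which.min(abs(pos - q))]
      qtl_markers <- c(qtl_markers, nearest)
      x <- ifelse(genotypes[, nearest] == "A", 1, -1)
      g <- g + qtl_spec$effect[i] * x
    }
  }
  line_val <- g + stats::rnorm(n_lines, 0, sigma_line)
  names(line_val) <- rownames(genotypes)

  var_gen <- if (length(qtl_markers)) sum(qtl_spec$effect^2) else 0
  s2b <- var_gen + sigma_line^2
  h2_true <- if (s2b + sigma_nucleus^2 > 0) s2b / (s2b + sigma_nucleus^2) else 0

  n_tot <- n_lines * n_nuclei_per_line
  tab <- data.frame(
    line_id = rep(rownames(genotypes), each = n_nuclei_per_line),
    plant_id = rep(sprintf("p%d", ((seq_len(n_nuclei_per_line) - 1) %%
                                     n_plants_per_line) + 1), n_lines),
    nucleus_id = rep(seq_len(n_nuclei_per_line), n_lines),
    stringsAsFactors = FALSE
  )
  noise <- stats::rnorm(n_tot, 0, sigma_nucleus)
  tab[[trait]] <- rep(line_val, each = n_nuclei_per_line) + noise
  attr(tab, "line_values") <- line_val
  attr(tab, "h2_true") <- h2_true
  # realized components of this dataset: the sample variance the draw
  # actually planted (the chi-square spread of a finite line panel makes
  # these differ from the population sigmas)
  s2b_real <- if (n_lines > 1) stats::var(line_val) else 0
  s2w_real <- if (n_tot > 1) stats::var(noise) else 0
  attr(tab, "h2_realized") <- if (s2b_real + s2w_real > 0) {
    s2b_real / (s2b_real + s2w_real)
  } else 0
  attr(tab, "qtl_markers") <- qtl_markers
  tab
}

#' Describe one synthetic nucleus
#'
#' Ground truth for the image renderer: an elliptical nucleus with optional
#' brighter circular chromocenters. All chromocenter discs must lie inside
#' the nucleus ellipse and intensities must satisfy
#' chromocenter > nucleus > background.
#'
#' @param center Numeric length-2, (row, col) pixel coordinates of the
#'   ellipse center.
#' @param axes Numeric length-2 semi-axis lengths in pixels (> 0).
#' @param orientation Rotation of the first axis, radians.
#' @param nucleus_intensity Mean 8-bit level of the nucleus body.
#' @param chromocenters \code{data.frame(row, col, radius, intensity)}, one
#'   row per chromocenter (0 rows allowed).
#' @param background_level 8-bit background level.
#' @param noise_sd SD of the additive Gaussian noise, intensity units.
#' @return A \code{nucleus_truth} list.
#' @export
nucleus_truth <- function(center, axes, orientation = 0,
                          nucleus_intensity = 100,
                          chromocenters = empty_chromocenters(),
                          background_level = 10, noise_sd = 2) {
  stopifnot(length(center) == 2, length(axes) == 2, all(axes > 0))
  if (!(nucleus_intensity > background_level)) {
    stop("nucleus_intensity must exceed background_level")
  }
  cc <- as.data.frame(chromocenters)
  if (nrow(cc)) {
    stopifnot(all(c("row", "col", "radius", "intensity") %in% names(cc)))
    if (any(cc$intensity <= nucleus_intensity)) {
      stop("chromocenter intensity must exceed nucleus_intensity")
    }
    # disc inside ellipse: check the disc's bounding reach along the ellipse
    # frame conservatively via the scaled center distance plus radius margin
    for (i in seq_len(nrow(cc))) {
      dr <- cc$row[i] - center[1]; dc <- cc$col[i] - center[2]
      u <- dr * cos(orientation) + dc * sin(orientation)
      v <- -dr * sin(orientation) + dc * cos(orientation)
      m <- sqrt((u / (axes[1] - cc$radius[i]))^2 +
                  (v / (axes[2] - cc$radius[i]))^2)
      if (!is.finite(m) || m > 1) stop("chromocenter disc not inside nucleus ellipse")
    }
  }
  structure(list(center = center, axes = axes, orientation = orientation,
                 nucleus_intensity = nucleus_intensity, chromocenters = cc,
                 background_level = background_level, noise_sd = noise_sd),
            class = "nucleus_truth")
}

#' @rdname nucleus_truth
#' @export
empty_chromocenters <- function() {
  data.frame(row = numeric(0), col = numeric(0),
             radius = numeric(0), intensity = numeric(0))
}

ellipse_mask <- function(truth, shape) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dr <- rr - truth$center[1]; dc <- cc - truth$center[2]
  th <- truth$orientation
  u <- dr * cos(th) + dc * sin(th)
  v <- -dr * sin(th) + dc * cos(th)
  (u / truth$axes[1])^2 + (v / truth$axes[2])^2 <= 1
}

disc_mask <- function(center, radius, shape) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

#' Render a field of synthetic nuclei with ground-truth masks
#'
#' Paints non-overlapping elliptical nuclei and their chromocenter discs on a
#' uniform background, adds i.i.d. Gaussian noise, and rounds/clips to the
#' 8-bit range. The returned label masks are the exact painted geometry
#' (noise-free ground truth). Fields of spread nuclei do not overlap;
#' overlapping truths are an error.
#'
#' @param truths List of \code{\link{nucleus_truth}} objects. Background
#'   level and noise SD are taken from the first truth and must agree across
#'   truths.
#' @param image_shape Integer length-2 (rows, cols), at least 16 x 16.
#' @param seed Integer seed for the noise.
#' @return List: \code{image} (integer matrix, 0-255), \code{nucleus_mask}
#'   and \code{cc_mask} (integer label matrices, 0 = background), and
#'   \code{cc_parent} (integer vector mapping each chromocenter label to its
#'   parent nucleus label).
#' @export
render_nucleus_image <- function(truths, image_shape, seed = 1) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 16))
  if (inherits(truths, "nucleus_truth")) truths <- list(truths)
  stopifnot(length(truths) >= 1)
  bg <- truths[[1]]$background_level
  nsd <- truths[[1]]$noise_sd
  for (t in truths) {
    if (t$background_level != bg || t$noise_sd != nsd) {
      stop("all truths must share background_level and noise_sd")
    }
  }
  img <- matrix(bg, image_shape[1], image_shape[2])
  nuc_mask <- matrix(0L, image_shape[1], image_shape[2])
  cc_mask <- matrix(0L, image_shape[1], image_shape[2])
  cc_parent <- integer(0)
  cc_label <- 0L
  for (i in seq_along(truths)) {
    t <- truths[[i]]
    em <- ellipse_mask(t, image_shape)
    if (!any(em)) stop("nucleus ", i, " lies outside the image")
    if (any(nuc_mask[em] != 0L)) stop("nuclei overlap; fields must be spread")
    nuc_mask[em] <- i
    img[em] <- t$nucleus_intensity
    if (nrow(t$chromocenters)) {
      for (j in seq_len(nrow(t$chromocenters))) {
        b <- t$chromocenters[j, ]
        dm <- disc_mask(c(b$row, b$col), b$radius, image_shape)
        cc_label <- cc_label + 1L
        cc_mask[dm] <- cc_label
        cc_parent[cc_label] <- i
        img[dm] <- b$intensity
      }
    }
  }
  set.seed(seed)
  img <- img + stats::rnorm(length(img), 0, nsd)
  img <- matrix(as.integer(pmin(255, pmax(0, round(img)))),
                image_shape[1], image_shape[2])
  list(image = img, nucleus_mask = nuc_mask, cc_mask = cc_mask,
       cc_parent = cc_parent)
}

#' Lay out random non-overlapping nucleus truths on a grid
#'
#' Convenience generator for test fixtures: nuclei are centred in grid cells
#' with jitter, guaranteeing non-overlap, each with a random chromocenter
#' count in \code{n_cc_range} placed inside the ellipse.
#'
#' @param n Number of nuclei.
#' @param image_shape Image shape the truths must fit in.
#' @param radius_range Nucleus semi-axis range, pixels.
#' @param n_cc_range Integer range of chromocenter counts per nucleus.
#' @param nucleus_intensity,cc_intensity,background_level,noise_sd Intensity
#'   model (8-bit units).
#' @param cc_radius Chromocenter disc radius, pixels.
#' @param seed Integer seed.
#' @return List of \code{\link{nucleus_truth}}.
#' @export
random_nucleus_truths <- function(n, image_shape = c(192, 192),
                                  radius_range = c(22, 28),
                                  n_cc_range = c(0, 12),
                                  nucleus_intensity = 90, cc_intensity = 180,
                                  background_level = 10, noise_sd = 2,
                                  cc_radius = 2.5, seed = 1) {
  set.seed(seed)
  cell <- 2 * max(radius_range) + 8
  ncol_g <- max(1L, floor((image_shape[2] - 4) / cell))
  nrow_g <- max(1L, floor((image_shape[1] - 4) / cell))
  if (n > ncol_g * nrow_g) stop("too many nuclei for image_shape")
  slots <- sample(ncol_g * nrow_g, n)
  lapply(seq_len(n), function(i) {
    gi <- (slots[i] - 1) %/% ncol_g
    gj <- (slots[i] - 1) %% ncol_g
    ctr <- c(4 + gi * cell + cell / 2 + stats::runif(1, -2, 2),
             4 + gj * cell + cell / 2 + stats::runif(1, -2, 2))
    ax <- sort(stats::runif(2, radius_range[1], radius_range[2]),
               decreasing = TRUE)
    k <- if (n_cc_range[1] == n_cc_range[2]) n_cc_range[1] else
      sample(seq(n_cc_range[1], n_cc_range[2]), 1)
    cc <- empty_chromocenters()
    if (k > 0) {
      # jittered hexagonal lattice inside the (shrunk) ellipse: guarantees
      # well-separated discs at densities rejection sampling cannot reach
      sp <- 2 * cc_radius + 2.5
      au <- 0.85 * (ax[1] - cc_radius - 2)
      av <- 0.85 * (ax[2] - cc_radius - 2)
      gu <- seq(-au, au, by = sp * sqrt(3) / 2)
      cand <- do.call(rbind, lapply(seq_along(gu), function(r) {
        off <- if (r %% 2 == 0) sp / 2 else 0
        gv <- seq(-av + off, av, by = sp)
        cbind(gu[r], gv)
      }))
      inside <- (cand[, 1] / au)^2 + (cand[, 2] / av)^2 <= 1
      cand <- cand[inside, , drop = FALSE]
      if (nrow(cand) < k) stop("could not place ", k, " chromocenters")
      pick <- cand[sample(nrow(cand), k), , drop = FALSE]
      jit <- matrix(stats::runif(2 * k, -0.5, 0.5), k, 2)
      cc <- data.frame(row = ctr[1] + pick[, 1] + jit[, 1],
                       col = ctr[2] + pick[, 2] + jit[, 2],
                       radius = cc_radius, intensity = cc_intensity)
    }
    nucleus_truth(center = ctr, axes = ax, orientation = 0,
                  nucleus_intensity = nucleus_intensity, chromocenters = cc,
                  background_level = background_level, noise_sd = noise_sd)
  })
}
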