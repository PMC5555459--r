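# Composite interval mapping for selfed RIL populations: conditional
# genotype probabilities on a cM grid, forward-backward stepwise cofactor
# selection, Haley-Knott regression scans with a cofactor exclusion window,
# permutation-derived genome-wide LOD thresholds, and interval calls.

#' Composite-interval-mapping configuration
#'
#' Defaults follow the classical CIM parameterisation: a 10 cM cofactor
#' exclusion window, stepwise entry/exit p-values of 0.05, a 1 cM walking
#' step, and a genome-wide threshold from 1000 permutations at alpha 0.05.
#'
#' @param window_cM Cofactors within this distance of the tested position
#'   (same chromosome) are dropped from the model.
#' @param p_in,p_out Entry/exit p-values of the forward-backward search.
#' @param step_cM Evaluation grid step.
#' @param n_permutations Permutations for the genome-wide threshold (>= 20).
#' @param alpha Genome-wide significance level.
#' @param max_cofactors Cap on selected cofactors; NULL means
#'   floor(sqrt(n_lines)), guarding rank deficiency in small panels.
#' @param seed Seed for the permutation stream.
#' @param r2_denominator "tss" (explained variance relative to the total
#'   phenotypic variance of line means) or "rss_reduced".
#' @param reselect_cofactors Re-run cofactor selection within each
#'   permutation (statistically exact null); FALSE reuses the unpermuted
#'   cofactors — faster but approximate.
#' @return A \code{cim_config} list.
#' @export
cim_config <- function(window_cM = 10, p_in = 0.05, p_out = 0.05,
                       step_cM = 1, n_permutations = 1000, alpha = 0.05,
                       max_cofactors = NULL, seed = 1,
                       r2_denominator = c("tss", "rss_reduced"),
                       reselect_cofactors = TRUE) {
  stopifnot(window_cM > 0, p_in > 0, p_in < 1, p_out > 0, p_out < 1,
            step_cM > 0, alpha > 0, alpha < 1)
  structure(list(window_cM = window_cM, p_in = p_in, p_out = p_out,
                 step_cM = step_cM, n_permutations = n_permutations,
                 alpha = alpha, max_cofactors = max_cofactors, seed = seed,
                 r2_denominator = match.arg(r2_denominator),
                 reselect_cofactors = reselect_cofactors),
            class = "cim_config")
}

trans_prob_A <- function(g_is_A, R) {
  # P(genotype A at the target | genotype g at a marker R away)
  ifelse(g_is_A, 1 - R, R)
}

#' Conditional genotype probabilities on an evaluation grid
#'
#' For every line and grid position, the probability of carrying the A
#' genotype given the nearest non-missing flanking markers, under the
#' Markov model along the chromosome with inter-locus switch probability
#' R = 2r/(1+2r), r from the Haldane map function. At an observed marker
#' the probability is the 0/1 indicator; beyond the terminal markers the
#' single nearest marker is used; a line with no observed marker on a
#' chromosome gets probability 1/2 everywhere (with a warning).
#'
#' @param map Genetic map (\code{\link{make_genetic_map}} layout).
#' @param genotypes Character matrix lines x markers, codes "A"/"B", NA or
#'   "-" for missing.
#' @param step_cM Grid step; marker positions are always included.
#' @return A \code{prob_grid}: list with \code{positions}
#'   (\code{chromosome, position_cM, marker}), \code{probs} (lines x
#'   positions matrix of P(A)), \code{line_ids}, \code{map}.
#' @export
genotype_probs <- function(map, genotypes, step_cM = 1) {
  validate_map(map)
  stopifnot(step_cM > 0)
  if (is.null(colnames(genotypes)) || !all(map$marker %in% colnames(genotypes))) {
    stop("genotypes must have the map's markers as columns")
  }
  chroms <- unique(map$chromosome)
  pos_list <- lapply(chroms, function(ch) {
    mp <- map$position_cM[map$chromosome == ch]
    grid <- sort(unique(c(seq(min(mp), max(mp), by = step_cM), mp)))
    mk <- map$marker[map$chromosome == ch][match(grid, mp)]
    data.frame(chromosome = ch, position_cM = grid, marker = mk,
               stringsAsFactors = FALSE)
  })
  positions <- do.call(rbind, pos_list)
  n_lines <- nrow(genotypes)
  probs <- matrix(NA_real_, n_lines, nrow(positions))
  all_missing_warned <- FALSE
  for (ch in chroms) {
    mi <- which(map$chromosome == ch)
    mpos <- map$position_cM[mi]
    gcols <- match(map$marker[mi], colnames(genotypes))
    pcols <- which(positions$chromosome == ch)
    gp <- positions$position_cM[pcols]
    G <- genotypes[, gcols, drop = FALSE]
    G[G == "-"] <- NA
    for (ln in seq_len(n_lines)) {
      obs <- which(!is.na(G[ln, ]))
      if (!length(obs)) {
        if (!all_missing_warned) {
          warning("line(s) with all markers missing on a chromosome; using P(A) = 1/2")
          all_missing_warned <- TRUE
        }
        probs[ln, pcols] <- 0.5
        next
      }
      opos <- mpos[obs]
      oA <- G[ln, obs] == "A"
      iv <- findInterval(gp, opos)
      pA <- numeric(length(gp))
      left_only <- iv >= length(obs)
      right_only <- iv == 0
      both <- !left_only & !right_only
      if (any(right_only)) {
        d <- opos[1] - gp[right_only]
        pA[right_only] <- trans_prob_A(oA[1], ril_R(haldane_r(d)))
      }
      if (any(left_only)) {
        d <- gp[left_only] - opos[length(obs)]
        pA[left_only] <- trans_prob_A(oA[length(obs)], ril_R(haldane_r(d)))
      }
      if (any(both)) {
        i <- iv[both]
        dL <- gp[both] - opos[i]
        dR <- opos[i + 1] - gp[both]
        RL <- ril_R(haldane_r(dL)); RR <- ril_R(haldane_r(dR))
        a <- trans_prob_A(oA[i], RL) * trans_prob_A(oA[i + 1], RR)
        b <- (1 - trans_prob_A(oA[i], RL)) * (1 - trans_prob_A(oA[i + 1], RR))
        pA[both] <- a / (a + b)
      }
      probs[ln, pcols] <- pA
    }
  }
  structure(list(positions = positions, probs = probs,
                 line_ids = rownames(genotypes), map = map),
            class = "prob_grid")
}

# Expected genotype scores (2*P(A) - 1) at every grid position / at markers.
grid_scores <- function(prob_grid) 2 * prob_grid$probs - 1

marker_score_matrix <- function(prob_grid) {
  at <- !is.na(prob_grid$positions$marker)
  s <- grid_scores(prob_grid)[, at, drop = FALSE]
  colnames(s) <- prob_grid$positions$marker[at]
  s
}

align_phenotype <- function(prob_grid, phenotype) {
  if (!is.null(names(phenotype)) && !is.null(prob_grid$line_ids)) {
    if (!all(prob_grid$line_ids %in% names(phenotype))) {
      stop("phenotype names do not cover the genotyped lines")
    }
    phenotype <- phenotype[prob_grid$line_ids]
  }
  if (length(phenotype) != nrow(prob_grid$probs)) {
    stop("phenotype length does not match the number of lines")
  }
  as.vector(unname(phenotype))
}

#' Forward-backward stepwise cofactor selection
#'
#' Stepwise linear regression of the line-mean phenotype on marker genotype
#' scores (+1 for A, -1 for B; expected scores where the genotype is
#' missing): the most significant marker is added while its partial F-test
#' p-value is below \code{p_in}; after every addition any included marker
#' whose p-value exceeds \code{p_out} is dropped. Deterministic given the
#' inputs: ties break to the smaller p-value, then the lower marker index.
#' Markers collinear with the current model are skipped.
#'
#' @param prob_grid From \code{\link{genotype_probs}}.
#' @param phenotype Numeric per-line phenotype (named by line id or in line
#'   order).
#' @param config A \code{\link{cim_config}}.
#' @return Character vector of selected marker names, in map order.
#' @export
select_cofactors <- function(prob_grid, phenotype, config = cim_config()) {
  y <- align_phenotype(prob_grid, phenotype)
  X <- marker_score_matrix(prob_grid)
  n <- length(y)
  m <- ncol(X)
  if (stats::sd(y) == 0) return(character(0))
  max_cof <- config$max_cofactors
  if (is.null(max_cof)) max_cof <- floor(sqrt(n))
  inc <- integer(0)
  repeat {
    added <- FALSE
    if (length(inc) < max_cof) {
      Q <- qr.Q(qr(cbind(1, X[, inc, drop = FALSE])))
      ry <- y - Q %*% crossprod(Q, y)
      rss0 <- sum(ry^2)
      df2 <- n - (1 + length(inc)) - 1
      if (df2 >= 1 && rss0 > 1e-12) {
        cand <- setdiff(seq_len(m), inc)
        RX <- X[, cand, drop = FALSE] -
          Q %*% crossprod(Q, X[, cand, drop = FALSE])
        sxx <- colSums(RX^2)
        sxy <- colSums(RX * as.vector(ry))
        ok <- sxx > 1e-10
        rss1 <- rss0 - ifelse(ok, sxy^2 / sxx, 0)
        Fst <- (rss0 - rss1) / (rss1 / df2)
        p <- stats::pf(Fst, 1, df2, lower.tail = FALSE)
        p[!ok] <- Inf
        if (any(is.finite(p)) && min(p) < config$p_in) {
          pick <- cand[order(p, cand)[1]]
          inc <- c(inc, pick)
          added <- TRUE
        }
      }
    }
    # backward elimination after each forward step (and once at the end)
    repeat {
      if (length(inc) == 0) break
      Xf <- cbind(1, X[, inc, drop = FALSE])
      qrf <- qr(Xf)
      if (qrf$rank < ncol(Xf)) {
        # drop the most recently added collinear marker
        inc <- inc[-length(inc)]
        next
      }
      beta <- qr.coef(qrf, y)
      res <- y - Xf %*% beta
      dfres <- n - ncol(Xf)
      if (dfres < 1) { inc <- inc[-length(inc)]; next }
      s2 <- sum(res^2) / dfres
      XtXi <- chol2inv(qr.R(qrf))
      se <- sqrt(pmax(s2 * diag(XtXi), 0))
      tstat <- beta / se
      pt2 <- 2 * stats::pt(abs(tstat[-1]), dfres, lower.tail = FALSE)
      if (max(pt2) > config$p_out) {
        worst <- order(-pt2, inc)[1]
        inc <- inc[-worst]
      } else break
    }
    if (!added) break
  }
  colnames(X)[sort(inc)]
}

# positions x cofactors exclusion matrix (same chromosome, within window)
cofactor_exclusion <- function(cof_pos, positions, window) {
  same_ch <- outer(positions$chromosome, cof_pos$chromosome, "==")
  near <- abs(outer(positions$position_cM, cof_pos$position_cM, "-")) <= window
  same_ch & near
}

#' Composite-interval-mapping LOD scan
#'
#' Haley-Knott regression at every grid position: the phenotype is
#' regressed on the active cofactor scores plus the expected genotype score
#' 2*P(A) - 1; cofactors within \code{window_cM} of the tested position on
#' the same chromosome are excluded. LOD = (n/2) * log10(RSS_reduced /
#' RSS_full) where the reduced model omits the genotype score; ADD is the
#' genotype-score coefficient (A-class deviation from the genotype midpoint,
#' so fitted class means differ by 2*ADD); R2 = 100 * (RSS_reduced -
#' RSS_full) / TSS by default.
#'
#' @param prob_grid From \code{\link{genotype_probs}}.
#' @param phenotype Per-line phenotype.
#' @param cofactors Marker names from \code{\link{select_cofactors}} (may be
#'   empty).
#' @param config A \code{\link{cim_config}}.
#' @return A \code{lod_profile} data.frame: \code{chromosome, position_cM,
#'   lod, add, r2}; attribute \code{n_lines}. Positions with too few
#'   residual degrees of freedom are NA (with one warning).
#' @export
cim_scan <- function(prob_grid, phenotype, cofactors = character(0),
                     config = cim_config()) {
  y <- align_phenotype(prob_grid, phenotype)
  n <- length(y)
  S <- grid_scores(prob_grid)
  pos <- prob_grid$positions
  if (length(cofactors) && !all(cofactors %in% prob_grid$map$marker)) {
    stop("unknown cofactor marker")
  }
  Xc <- if (length(cofactors)) {
    marker_score_matrix(prob_grid)[, cofactors, drop = FALSE]
  } else matrix(numeric(0), n, 0)
  cof_pos <- prob_grid$map[match(cofactors, prob_grid$map$marker),
                           c("chromosome", "position_cM")]
  tss <- sum((y - mean(y))^2)
  lod <- add <- r2 <- rep(NA_real_, nrow(pos))
  if (length(cofactors)) {
    ex <- cofactor_exclusion(cof_pos, pos, config$window_cM)
    keys <- as.vector(ex %*% 2^(seq_along(cofactors) - 1))
  } else {
    ex <- matrix(FALSE, nrow(pos), 0)
    keys <- rep(0, nrow(pos))
  }
  skipped <- FALSE
  for (key in unique(keys)) {
    jj <- which(keys == key)
    act <- which(!ex[jj[1], ])
    Xr <- cbind(1, Xc[, act, drop = FALSE])
    p_act <- ncol(Xr)  # includes intercept
    if (n <= p_act + 2) { skipped <- TRUE; next }
    Q <- qr.Q(qr(Xr))
    ry <- y - Q %*% crossprod(Q, y)
    rss_red <- sum(ry^2)
    Sg <- S[, jj, drop = FALSE]
    RS <- Sg - Q %*% crossprod(Q, Sg)
    sxx <- colSums(RS^2)
    sxy <- colSums(RS * as.vector(ry))
    ok <- sxx > 1e-10
    beta <- ifelse(ok, sxy / sxx, 0)
    rss_full <- rss_red - ifelse(ok, sxy^2 / sxx, 0)
    l <- if (rss_red <= 1e-12) rep(0, length(jj)) else {
      lv <- (n / 2) * log10(rss_red / pmax(rss_full, 1e-300))
      lv[rss_full <= 1e-12] <- Inf
      lv
    }
    lod[jj] <- pmax(0, l)
    add[jj] <- beta
    r2[jj] <- if (config$r2_denominator == "tss") {
      if (tss > 0) 100 * (rss_red - rss_full) / tss else rep(0, length(jj))
    } else {
      if (rss_red > 0) 100 * (rss_red - rss_full) / rss_red else rep(0, length(jj))
    }
  }
  if (skipped) warning("positions skipped: too few lines for the active cofactor model")
  out <- data.frame(chromosome = pos$chromosome, position_cM = pos$position_cM,
                    lod = lod, add = add, r2 = r2)
  attr(out, "n_lines") <- n
  attr(out, "cofactors") <- cofactors
  class(out) <- c("lod_profile", "data.frame")
  out
}

#' Permutation-derived genome-wide LOD threshold
#'
#' Permutes the phenotype across lines, re-runs cofactor selection (unless
#' \code{reselect_cofactors} is FALSE, which reuses the unpermuted
#' selection — the fast, approximate mode) and the CIM scan, and records the
#' genome-wide maximum LOD of each permutation. The threshold is the order
#' statistic of the B permutation maxima with index
#' ceiling((B + 1) * (1 - alpha)): by exchangeability a fresh null scan
#' exceeds it with probability at most alpha, so the genome-wide test is
#' level-calibrated without interpolation bias.
#'
#' @param prob_grid From \code{\link{genotype_probs}}.
#' @param phenotype Per-line phenotype.
#' @param config A \code{\link{cim_config}} (supplies permutation count,
#'   alpha, seed, reselect mode).
#' @return List of class \code{perm_threshold}: \code{threshold},
#'   \code{max_lods}, \code{alpha}, \code{n_permutations},
#'   \code{reselected}.
#' @export
permutation_threshold <- function(prob_grid, phenotype, config = cim_config()) {
  if (config$n_permutations < 20) {
    stop("need at least 20 permutations for a stable percentile")
  }
  y <- align_phenotype(prob_grid, phenotype)
  set.seed(config$seed)
  base_cof <- if (!config$reselect_cofactors) {
    select_cofactors(prob_grid, y, config)
  } else NULL
  maxl <- vapply(seq_len(config$n_permutations), function(b) {
    yp <- sample(y)
    cof <- if (config$reselect_cofactors) {
      select_cofactors(prob_grid, yp, config)
    } else base_cof
    prof <- suppressWarnings(cim_scan(prob_grid, yp, cof, config))
    m <- suppressWarnings(max(prof$lod, na.rm = TRUE))
    if (!is.finite(m)) 0 else m
  }, numeric(1))
  k <- min(config$n_permutations,
           ceiling((config$n_permutations + 1) * (1 - config$alpha)))
  structure(list(threshold = sort(maxl)[k],
                 max_lods = maxl, alpha = config$alpha,
                 n_permutations = config$n_permutations,
                 reselected = config$reselect_cofactors),
            class = "perm_threshold")
}

#' Call QTL intervals from a LOD profile
#'
#' Maximal runs of contiguous grid positions at or above the threshold
#' become one call each: start/end are the run borders (cM), top the
#' position of the maximum LOD in the run (leftmost on ties), and LOD, ADD
#' and R2 are reported at the top. Runs on different chromosomes never
#' merge.
#'
#' @param profile A \code{lod_profile}.
#' @param threshold Numeric LOD threshold or a \code{perm_threshold}.
#' @return \code{data.frame} with columns \code{chromosome, start_cM,
#'   end_cM, top_cM, lod, add, r2}; zero rows when nothing exceeds the
#'   threshold.
#' @export
call_qtl <- function(profile, threshold) {
  if (inherits(threshold, "perm_threshold")) threshold <- threshold$threshold
  out <- list()
  for (ch in unique(profile$chromosome)) {
    sub <- profile[profile$chromosome == ch, ]
    sub <- sub[order(sub$position_cM), ]
    above <- !is.na(sub$lod) & sub$lod >= threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      run <- seq(starts[k], ends[k])
      top <- run[which.max(sub$lod[run])]
      out[[length(out) + 1]] <- data.frame(
        chromosome = ch,
        start_cM = sub$position_cM[run[1]],
        end_cM = sub$position_cM[run[length(run)]],
        top_cM = sub$position_cM[top],
        lod = sub$lod[top], add = sub$add[top], r2 = sub$r2[top])
    }
  }
  if (!length(out)) {
    return(data.frame(chromosome = integer(0), start_cM = numeric(0),
                      end_cM = numeric(0), top_cM = numeric(0),
                      lod = numeric(0), add = numeric(0), r2 = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Do two QTL calls colocate?
#'
#' True when the calls lie on the same chromosome and their closed
#' [start, end] intervals intersect; the shared interval is returned.
#'
#' @param call_a,call_b One-row QTL calls (\code{\link{call_qtl}} rows). If
#'   both carry a \code{map_id} attribute the ids must agree.
#' @return List: \code{overlap} (logical), \code{interval} (c(start, end) or
#'   NULL).
#' @export
colocate <- function(call_a, call_b) {
  ma <- attr(call_a, "map_id"); mb <- attr(call_b, "map_id")
  if (!is.null(ma) && !is.null(mb) && !identical(ma, mb)) {
    stop("QTL calls come from different maps")
  }
  if (call_a$chromosome != call_b$chromosome) {
    return(list(overlap = FALSE, interval = NULL))
  }
  lo <- max(call_a$start_cM, call_b$start_cM)
  hi <- min(call_a$end_cM, call_b$end_cM)
  if (lo > hi) return(list(overlap = FALSE, interval = NULL))
  list(overlap = TRUE, interval = c(lo, hi))
}

#' One-trait CIM pipeline: cofactors, scan, threshold, calls
#'
#' @param prob_grid From \code{\link{genotype_probs}}.
#' @param phenotype Per-line phenotype.
#' @param config A \code{\link{cim_config}}.
#' @param permute Compute the permutation threshold (FALSE skips it; calls
#'   are then not made).
#' @return List: \code{cofactors}, \code{profile}, \code{threshold}
#'   (\code{perm_threshold} or NULL), \code{calls}.
#' @export
qtl_scan <- function(prob_grid, phenotype, config = cim_config(),
                     permute = TRUE) {
  cof <- select_cofactors(prob_grid, phenotype, config)
  prof <- cim_scan(prob_grid, phenotype, cof, config)
  thr <- NULL
  calls <- NULL
  if (permute) {
    thr <- permutation_threshold(prob_grid, phenotype, config)
    calls <- call_qtl(prof, thr)
  }
  list(cofactors = cof, profile = prof, threshold = thr, calls = calls)
}
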