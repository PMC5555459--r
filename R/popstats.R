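# Population statistics for RIL trait tables: outlier filtering, per-line
# aggregation, broad-sense heritability, correlation networks, transgression
# and the two-group tests used in the study's figures.

#' Remove trait-value outliers
#'
#' Two single-pass rules: \code{percentile95} keeps values inside the
#' central 95% empirical interval (2.5th-97.5th percentile); \code{sd2}
#' keeps values within mean +/- 2 SD, with mean and SD computed once on the
#' input (no iteration, so the rule is idempotent when reapplied with the
#' original statistics).
#'
#' @param values Numeric vector, length >= 3.
#' @param rule "percentile95" or "sd2".
#' @return The values that pass the rule, order preserved.
#' @export
remove_outliers <- function(values, rule = c("percentile95", "sd2")) {
  rule <- match.arg(rule)
  if (length(values) < 3) stop("need at least 3 values")
  if (rule == "percentile95") {
    q <- stats::quantile(values, c(0.025, 0.975), names = FALSE)
    values[values >= q[1] & values <= q[2]]
  } else {
    m <- mean(values); s <- stats::sd(values)
    values[abs(values - m) <= 2 * s]
  }
}

#' Per-line trait summaries
#'
#' Lines with fewer nuclei or plants than the thresholds are excluded with a
#' warning; per line and trait, outliers are removed before the mean and SD
#' are taken. The defaults mirror the study design of at least 26 nuclei
#' from at least two plants per line.
#'
#' @param trait_table Long table with \code{line_id, plant_id, nucleus_id}
#'   and one numeric column per trait.
#' @param traits Trait columns to summarise (default: all numeric non-id
#'   columns).
#' @param min_nuclei,min_plants Inclusion thresholds per line.
#' @param outlier_rule Passed to \code{\link{remove_outliers}}; NULL skips
#'   outlier removal.
#' @return Long \code{data.frame}: \code{line_id, trait, mean, sd, n_nuclei,
#'   n_plants}.
#' @export
line_summary <- function(trait_table, traits = NULL,
                         min_nuclei = 26, min_plants = 2,
                         outlier_rule = "percentile95") {
  if (is.null(trait_table) || nrow(trait_table) == 0) stop("empty trait table")
  ids <- c("line_id", "plant_id", "nucleus_id")
  if (!all(ids %in% names(trait_table))) {
    stop("trait table needs columns ", paste(ids, collapse = ", "))
  }
  if (is.null(traits)) {
    traits <- setdiff(names(trait_table)[vapply(trait_table, is.numeric,
                                                logical(1))], ids)
  }
  if (!length(traits)) stop("no trait columns found")
  counts <- tapply(trait_table$nucleus_id, trait_table$line_id, length)
  plants <- tapply(trait_table$plant_id, trait_table$line_id,
                   function(p) length(unique(p)))
  keep <- names(counts)[counts >= min_nuclei & plants >= min_plants]
  dropped <- setdiff(names(counts), keep)
  if (length(dropped)) {
    warning(length(dropped), " line(s) below the nucleus/plant thresholds excluded: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  if (!length(keep)) stop("no line passes the inclusion thresholds")
  out <- do.call(rbind, lapply(keep, function(l) {
    sub <- trait_table[trait_table$line_id == l, , drop = FALSE]
    do.call(rbind, lapply(traits, function(tr) {
      v <- sub[[tr]]
      v <- v[is.finite(v)]
      if (!is.null(outlier_rule) && length(v) >= 3) {
        v <- remove_outliers(v, outlier_rule)
      }
      data.frame(line_id = l, trait = tr, mean = mean(v), sd = stats::sd(v),
                 n_nuclei = length(v),
                 n_plants = length(unique(sub$plant_id)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Wide matrix of per-line trait means
#'
#' @param summaries Output of \code{\link{line_summary}}.
#' @return Numeric matrix, lines x traits.
#' @export
line_means_matrix <- function(summaries) {
  lines <- unique(summaries$line_id)
  traits <- unique(summaries$trait)
  m <- matrix(NA_real_, length(lines), length(traits),
              dimnames = list(lines, traits))
  m[cbind(match(summaries$line_id, lines), match(summaries$trait, traits))] <-
    summaries$mean
  m
}

#' Broad-sense heritability from one-way variance components
#'
#' Treats lines as a random factor. With k lines and group sizes n_i
#' (total N), the unbalanced correction n0 = (N - sum(n_i^2)/N)/(k - 1) is
#' used in the method-of-moments components: sigma2_within = MSW,
#' sigma2_between = max(0, (MSB - MSW)/n0), and H2 =
#' sigma2_between / (sigma2_between + sigma2_within) — the between-line
#' trait variance over the total, using the within-line (per-nucleus)
#' spread as the environmental term.
#'
#' @param trait_table Long trait table (see \code{\link{line_summary}}).
#' @param trait Name of the trait column (default: the single trait found).
#' @return One-row \code{data.frame}: \code{trait, sigma2_between,
#'   sigma2_within, H2, n_lines, N_total}.
#' @export
heritability <- function(trait_table, trait = NULL) {
  ids <- c("line_id", "plant_id", "nucleus_id")
  if (is.null(trait)) {
    cand <- setdiff(names(trait_table)[vapply(trait_table, is.numeric,
                                              logical(1))], ids)
    if (length(cand) != 1) stop("specify the trait column")
    trait <- cand
  }
  y <- trait_table[[trait]]
  g <- factor(trait_table$line_id)
  ok <- is.finite(y)
  y <- y[ok]; g <- droplevels(g[ok])
  k <- nlevels(g)
  if (k < 2) stop("need at least 2 lines")
  ni <- as.vector(table(g))
  if (max(ni) < 2) stop("need replicate nuclei within at least one line")
  N <- length(y)
  fit <- stats::aov(y ~ g)
  ss <- summary(fit)[[1]]
  msb <- ss[["Mean Sq"]][1]
  msw <- ss[["Mean Sq"]][2]
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  s2w <- msw
  s2b <- max(0, (msb - msw) / n0)
  h2 <- if (s2b + s2w > 0) s2b / (s2b + s2w) else 0
  data.frame(trait = trait, sigma2_between = s2b, sigma2_within = s2w,
             H2 = h2, n_lines = k, N_total = N, stringsAsFactors = FALSE)
}

stars_for_p <- function(p, alpha_levels = c(0.05, 0.01, 0.001, 0.0001)) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    paste(rep("*", sum(pp < alpha_levels)), collapse = "")
  }, character(1))
}

#' Pairwise Pearson correlation network over line means
#'
#' Pearson r and its two-sided p-value for every unordered trait pair over
#' per-line means (parental lines and the F1 may be pooled with the RILs as
#' extra rows). Star levels follow the conventional 0.05 / 0.01 / 0.001 /
#' 0.0001 thresholds; the edge list keeps pairs significant at the loosest
#' level. A trait constant across lines has no defined correlation; its
#' pairs are reported with NA and excluded from the edge list.
#'
#' @param line_means Numeric matrix or data.frame, lines x traits
#'   (\code{\link{line_means_matrix}}).
#' @param traits Columns to use (default all).
#' @param alpha_levels Decreasing significance thresholds for the stars.
#' @return List: \code{edges} (significant pairs: \code{trait_a, trait_b, r,
#'   p, stars}), \code{all_pairs} (every pair incl. NA), \code{r_matrix}.
#' @export
correlation_network <- function(line_means, traits = NULL,
                                alpha_levels = c(0.05, 0.01, 0.001, 0.0001)) {
  m <- as.matrix(line_means)
  if (!is.null(traits)) m <- m[, traits, drop = FALSE]
  if (nrow(m) < 4) stop("need at least 4 lines")
  tn <- colnames(m)
  pairs <- utils::combn(length(tn), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ok <- stats::complete.cases(m[, c(a, b)])
    xa <- m[ok, a]; xb <- m[ok, b]
    if (stats::sd(xa) == 0 || stats::sd(xb) == 0) {
      return(data.frame(trait_a = tn[a], trait_b = tn[b], r = NA_real_,
                        p = NA_real_, stars = NA_character_,
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(xa, xb, method = "pearson"))
    data.frame(trait_a = tn[a], trait_b = tn[b], r = unname(ct$estimate),
               p = ct$p.value, stars = stars_for_p(ct$p.value, alpha_levels),
               stringsAsFactors = FALSE)
  })
  all_pairs <- do.call(rbind, rows)
  edges <- all_pairs[!is.na(all_pairs$p) & all_pairs$p < max(alpha_levels), ]
  rownames(edges) <- NULL
  rmat <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  list(edges = edges, all_pairs = all_pairs, r_matrix = rmat)
}

#' Transgression ratio of per-line means
#'
#' 100 * min / max of the per-line means: the span of the population
#' relative to its extreme line (100% = no variation). Defined only for
#' strictly positive means.
#'
#' @param means Numeric vector of per-line means (> 0).
#' @return Percentage in (0, 100].
#' @export
transgression_ratio <- function(means) {
  means <- means[is.finite(means)]
  if (!length(means)) stop("no finite means")
  if (any(means <= 0)) stop("transgression ratio undefined for nonpositive means")
  100 * min(means) / max(means)
}

#' Welch two-sample t-test
#'
#' Two-sided t-test assuming unequal variances (Satterthwaite degrees of
#' freedom), plus the direction of the mean difference.
#'
#' @param values_a,values_b Numeric vectors, each >= 2 values with positive
#'   variance in at least one group.
#' @return List: \code{t}, \code{df}, \code{p}, \code{direction} (sign of
#'   mean(a) - mean(b): -1, 0, or 1).
#' @export
welch_test <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) stop("need >= 2 values per group")
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) stop("both groups constant and equal")
    stop("both groups constant; Welch statistic undefined")
  }
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       direction = sign(mean(values_a) - mean(values_b)))
}

#' Chi-squared comparison of object size classes
#'
#' Builds the 2 x 2 contingency table (group x below/above \code{cutoff})
#' and applies Pearson's chi-squared test, without continuity correction by
#' default.
#'
#' @param values_a,values_b Numeric vectors (e.g. nucleus areas of two
#'   genotypes).
#' @param cutoff Size-class boundary; values <= cutoff form the small class.
#' @param correct Apply the Yates continuity correction.
#' @return List: \code{chi2}, \code{p}, \code{table}.
#' @export
chi2_size_classes <- function(values_a, values_b, cutoff, correct = FALSE) {
  if (!length(values_a) || !length(values_b)) stop("both groups must be nonempty")
  tab <- rbind(a = c(small = sum(values_a <= cutoff), large = sum(values_a > cutoff)),
               b = c(small = sum(values_b <= cutoff), large = sum(values_b > cutoff)))
  if (any(colSums(tab) == 0)) stop("a size class is empty in both groups")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(ct$statistic), p = ct$p.value, table = tab)
}

#' Normality test for a trait distribution
#'
#' Shapiro-Wilk on the raw values.
#'
#' @param values Numeric vector, 8 <= n <= 5000, non-constant.
#' @return List: \code{statistic}, \code{p}.
#' @export
test_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 8) stop("need at least 8 values")
  if (stats::sd(values) == 0) stop("constant input")
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p = sw$p.value)
}

#' Compact letter display over pairwise Welch tests
#'
#' Reporting utility for figure-style group labels: groups sharing a letter
#' are not significantly different at \code{alpha} in a pairwise Welch test.
#' Greedy insert-and-absorb construction; letters are assigned in group
#' order.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor/character of group membership, same length.
#' @param alpha Significance level for the pairwise tests.
#' @return Named character vector of letter codes, one per group.
#' @export
significance_letters <- function(values, groups, alpha = 0.01) {
  groups <- as.character(groups)
  gs <- unique(groups)
  k <- length(gs)
  differ <- matrix(FALSE, k, k, dimnames = list(gs, gs))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    p <- welch_test(values[groups == gs[i]], values[groups == gs[j]])$p
    differ[i, j] <- differ[j, i] <- p < alpha
  }
  sets <- list()
  for (i in seq_len(k)) {
    placed <- FALSE
    for (s in seq_along(sets)) {
      if (!any(differ[i, sets[[s]]])) {
        sets[[s]] <- c(sets[[s]], i); placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- i
  }
  out <- setNames(rep("", k), gs)
  for (s in seq_along(sets)) {
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  }
  out
}
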