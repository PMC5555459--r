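test_that("conditional genotype probabilities honour the Markov model", {
  map <- make_genetic_map(1, 20, 10)  # markers at 0, 10, 20
  g <- rbind(L1 = c("A", "A", "A"), L2 = c("A", "B", "B"),
             L3 = c("A", NA, "A"), L4 = c("A", NA, "B"))
  colnames(g) <- map$marker
  grid <- genotype_probs(map, g, step_cM = 1)
  pos <- grid$positions$position_cM

  # indicator at observed markers
  at10 <- which(pos == 10)
  expect_equal(grid$probs[1, at10], 1)
  expect_equal(grid$probs[2, at10], 0)

  # midpoint flanked by A (at 0) and B (at 10) is exactly 1/2
  at5 <- which(pos == 5)
  expect_equal(grid$probs[2, at5], 0.5)
  # midpoint flanked by A and A (markers 10 apart on each side, line 3 has
  # the middle marker missing): enumeration oracle over the middle genotype
  R10 <- ril_R(haldane_r(10))
  pAA <- (1 - R10) * (1 - R10)
  pAB <- R10 * R10
  expect_equal(grid$probs[3, at10], pAA / (pAA + pAB))
  # flanked by A and B at 10 cM each: symmetry gives 1/2
  expect_equal(grid$probs[4, at10], 0.5)

  # a line with a whole chromosome missing gets 1/2 with a warning
  g2 <- rbind(L1 = c(NA, NA, NA)); colnames(g2) <- map$marker
  expect_warning(grid2 <- genotype_probs(map, g2, 5), "missing")
  expect_true(all(grid2$probs == 0.5))
})

test_that("midpoint of a 20 cM A-A interval matches the two-step oracle", {
  map <- make_genetic_map(1, 20, 20)  # markers at 0 and 20 only
  g <- rbind(L1 = c("A", "A")); colnames(g) <- map$marker
  grid <- genotype_probs(map, g, step_cM = 10)
  at10 <- which(grid$positions$position_cM == 10)
  R <- ril_R(haldane_r(10))
  oracle <- ((1 - R)^2) / ((1 - R)^2 + R^2)
  expect_equal(grid$probs[1, at10], oracle)
})

test_that("cofactor selection is sparse under the null and finds real loci", {
  map <- study_map()
  cfg <- cim_config()

  g <- simulate_ril_genotypes(map, 100, seed = 61)
  grid <- genotype_probs(map, g, 2)

  # constant phenotype: nothing to select
  expect_equal(select_cofactors(grid, rep(3, 100), cfg), character(0))

  # planted QTL with a = 1 residual SD: the marker (or a neighbour within
  # 10 cM) is picked in nearly all seeds
  hits <- 0
  for (s in 1:25) {
    tt <- simulate_trait_values(g, map,
                                data.frame(chromosome = 4, position_cM = 60,
                                           effect = 1),
                                sigma_line = 1, sigma_nucleus = 0,
                                n_nuclei_per_line = 1, seed = 900 + s)
    cof <- select_cofactors(grid, attr(tt, "line_values"), cfg)
    mpos <- map[match(cof, map$marker), ]
    hits <- hits + any(mpos$chromosome == 4 &
                         abs(mpos$position_cM - 60) <= 10)
  }
  expect_gte(hits, 23)

  # pure noise: the selected set stays small
  counts <- vapply(1:25, function(s) {
    set.seed(1200 + s)
    length(select_cofactors(grid, rnorm(100), cfg))
  }, numeric(1))
  expect_lte(median(counts), 2)
})

test_that("the scan equals single-marker regression with no cofactors", {
  map <- study_map()
  g <- simulate_ril_genotypes(map, 46, seed = 62)
  grid <- genotype_probs(map, g, 1)
  set.seed(63)
  y <- rnorm(46) + ifelse(g[, "c2m09"] == "A", 0.8, -0.8)
  prof <- cim_scan(grid, y, character(0), cim_config())
  mk <- which(!is.na(grid$positions$marker))
  for (j in mk[seq(1, length(mk), by = 10)]) {
    x <- 2 * grid$probs[, j] - 1
    rss0 <- sum(resid(lm(y ~ 1))^2)
    rss1 <- sum(resid(lm(y ~ x))^2)
    expect_equal(prof$lod[j], (46 / 2) * log10(rss0 / rss1),
                 tolerance = 1e-8)
    expect_equal(prof$add[j], unname(coef(lm(y ~ x))[2]), tolerance = 1e-8)
  }
})

test_that("LOD profiles are invariant under affine phenotype transforms", {
  map <- study_map()
  g <- simulate_ril_genotypes(map, 46, seed = 64)
  grid <- genotype_probs(map, g, 2)
  set.seed(65); y <- rnorm(46)
  cfg <- cim_config()
  cof <- select_cofactors(grid, y, cfg)
  p1 <- cim_scan(grid, y, cof, cfg)
  p2 <- cim_scan(grid, 10 - 3 * y, cof, cfg)
  expect_equal(p1$lod, p2$lod, tolerance = 1e-9)
  expect_equal(p1$r2, p2$r2, tolerance = 1e-9)
  expect_equal(p1$add, -p2$add / 3, tolerance = 1e-9)
})

test_that("a planted effect is estimated within 2 SE at 200 lines", {
  map <- study_map()
  g <- simulate_ril_genotypes(map, 200, seed = 66)
  grid <- genotype_probs(map, g, 1)
  a <- 0.6
  tt <- simulate_trait_values(g, map,
                              data.frame(chromosome = 1, position_cM = 50,
                                         effect = a),
                              sigma_line = 1, sigma_nucleus = 0,
                              n_nuclei_per_line = 1, seed = 67)
  y <- attr(tt, "line_values")
  prof <- cim_scan(grid, y, character(0), cim_config())
  at <- which(grid$positions$chromosome == 1 &
                grid$positions$position_cM == 50)
  se <- 1 / sqrt(200)  # residual SD 1, scores +-1
  expect_lt(abs(prof$add[at] - a), 2 * se)
})

test_that("permutation thresholds are deterministic and sane", {
  map <- study_map()
  g <- simulate_ril_genotypes(map, 46, seed = 68)
  grid <- genotype_probs(map, g, 2)
  cfg <- cim_config(n_permutations = 30, seed = 7)

  # constant phenotype: every permuted max LOD is 0
  thr0 <- permutation_threshold(grid, rep(2, 46), cfg)
  expect_equal(thr0$threshold, 0)

  set.seed(69); y <- rnorm(46)
  t1 <- permutation_threshold(grid, y, cfg)
  t2 <- permutation_threshold(grid, y, cfg)
  expect_identical(t1$max_lods, t2$max_lods)
  expect_identical(t1$threshold, t2$threshold)

  expect_error(permutation_threshold(grid, y,
                                     cim_config(n_permutations = 10)),
               "20")
})

test_that("QTL calls are contiguous runs with leftmost-tie tops", {
  prof <- data.frame(
    chromosome = c(rep(2, 6), rep(4, 3)),
    position_cM = c(163:168, 10:12),
    lod = c(1, 3.1, 3.5, 3.2, 1, 0.5, 3.1, 3.1, 0.2),
    add = 1, r2 = 5)
  class(prof) <- c("lod_profile", "data.frame")

  calls <- call_qtl(prof, 3.0)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$start_cM[1], 164)
  expect_equal(calls$end_cM[1], 166)
  expect_equal(calls$top_cM[1], 165)
  expect_equal(calls$top_cM[2], 10)  # leftmost of the tie

  expect_equal(nrow(call_qtl(prof, 10)), 0)

  # a below-threshold valley splits one chromosome into two calls
  prof2 <- data.frame(chromosome = 1, position_cM = 1:7,
                      lod = c(4, 4, 1, 1, 4, 5, 4), add = 0, r2 = 0)
  calls2 <- call_qtl(prof2, 3)
  expect_equal(nrow(calls2), 2)
  expect_equal(calls2$top_cM, c(1, 6))
})

test_that("colocation is closed-interval intersection on one chromosome", {
  a <- data.frame(chromosome = 2, start_cM = 158, end_cM = 164,
                  top_cM = 161, lod = 4.9, add = 0.01, r2 = 15.7)
  b <- data.frame(chromosome = 2, start_cM = 164, end_cM = 166,
                  top_cM = 165, lod = 4, add = -1, r2 = 12)
  cl <- colocate(a, b)
  expect_true(cl$overlap)
  expect_equal(cl$interval, c(164, 164))

  d <- b; d$chromosome <- 4
  expect_false(colocate(a, d)$overlap)
  expect_equal(colocate(a, a)$interval, c(158, 164))

  attr(a, "map_id") <- "m1"; attr(b, "map_id") <- "m2"
  expect_error(colocate(a, b), "different maps")
})
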