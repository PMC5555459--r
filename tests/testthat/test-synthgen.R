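test_that("genetic map places evenly spaced markers including both ends", {
  m1 <- make_genetic_map(1, 10, 10)
  expect_equal(m1$position_cM, c(0, 10))

  m2 <- make_genetic_map(5, rep(100, 5), 5)
  expect_equal(nrow(m2), 5 * 21)
  expect_equal(as.numeric(tapply(m2$position_cM, m2$chromosome, max)),
               rep(100, 5))

  # step larger than the chromosome degenerates to the two ends
  m3 <- make_genetic_map(1, 10, 25)
  expect_equal(m3$position_cM, c(0, 10))

  expect_error(make_genetic_map(1, -5, 1))
  expect_error(make_genetic_map(1, 10, 0))
})

test_that("RIL genotypes follow the Haldane-Waddington switch rate", {
  # zero distance: perfectly linked markers share the code in every line
  map0 <- data.frame(marker = c("a", "b"), chromosome = 1,
                     position_cM = c(5, 5))
  class(map0) <- c("genetic_map", "data.frame")
  g0 <- simulate_ril_genotypes(map0, 200, seed = 4)
  expect_true(all(g0[, 1] == g0[, 2]))

  # 20 cM apart: observed switch frequency matches R = 2r/(1+2r), r Haldane
  map1 <- data.frame(marker = c("a", "b"), chromosome = 1,
                     position_cM = c(0, 20))
  class(map1) <- c("genetic_map", "data.frame")
  n <- 2000
  g1 <- simulate_ril_genotypes(map1, n, seed = 5)
  R <- ril_R(haldane_r(20))
  expect_equal(R, 2 * ((1 - exp(-0.4)) / 2) / (1 + 2 * (1 - exp(-0.4)) / 2))
  obs <- mean(g1[, 1] != g1[, 2])
  expect_lt(abs(obs - R), 3 * sqrt(R * (1 - R) / n))

  # allele frequency is 1/2 at every marker (3 SE binomial band)
  fA <- colMeans(g1 == "A")
  expect_true(all(abs(fA - 0.5) < 3 * sqrt(0.25 / n)))

  expect_error(simulate_ril_genotypes(map1[0, ], 10))
})

test_that("planted QTL effects and variance components are honoured", {
  map <- study_map()
  g <- simulate_ril_genotypes(map, 60, seed = 6)

  # one QTL at a marker, no noise: class means differ by exactly 2a
  tt <- simulate_trait_values(g, map,
                              data.frame(chromosome = 2, position_cM = 40,
                                         effect = 1),
                              sigma_line = 0, sigma_nucleus = 0,
                              n_nuclei_per_line = 1, seed = 7)
  y <- attr(tt, "line_values")
  cls <- g[, "c2m09"]
  expect_equal(unname(mean(y[cls == "A"]) - mean(y[cls == "B"])), 2)

  # no genetics, no line noise: line means collapse with growing n
  tt0 <- simulate_trait_values(g, map, NULL, sigma_line = 0,
                               sigma_nucleus = 1, n_nuclei_per_line = 400,
                               seed = 8)
  lm0 <- tapply(tt0$trait, tt0$line_id, mean)
  expect_lt(stats::var(lm0), 0.01)

  # ground-truth variance ratio is recoverable
  tt1 <- simulate_trait_values(g[1:50, ], map, NULL, sigma_line = 1,
                               sigma_nucleus = 1, n_nuclei_per_line = 50,
                               seed = 9)
  expect_equal(attr(tt1, "h2_true"), 0.5)
  h <- heritability(tt1, "trait")
  expect_lt(abs(h$H2 - 0.5), 0.1)

  expect_error(simulate_trait_values(g, map,
                                     data.frame(chromosome = 2,
                                                position_cM = 500,
                                                effect = 1),
                                     1, 1, 5, seed = 1),
               "off the map")
})

test_that("single-marker regression recovers a planted additive effect", {
  map <- study_map()
  g <- simulate_ril_genotypes(map, 200, seed = 10)
  a <- 0.8
  tt <- simulate_trait_values(g, map,
                              data.frame(chromosome = 3, position_cM = 50,
                                         effect = a),
                              sigma_line = 1, sigma_nucleus = 0,
                              n_nuclei_per_line = 1, seed = 11)
  y <- attr(tt, "line_values")
  x <- ifelse(g[, attr(tt, "qtl_markers")] == "A", 1, -1)
  fit <- summary(stats::lm(y ~ x))
  expect_lt(abs(fit$coefficients["x", "Estimate"] - a),
            2 * fit$coefficients["x", "Std. Error"])
})

test_that("rendered images carry exact ground-truth masks", {
  # no chromocenters -> empty chromocenter mask
  t0 <- single_nucleus_truth(radius = 20, k = 0)
  f0 <- render_nucleus_image(t0, c(96, 96), seed = 12)
  expect_equal(max(f0$cc_mask), 0)

  # circular nucleus: mask area = pixels whose centre lies in the disc
  t1 <- single_nucleus_truth(radius = 40, shape = c(112, 112))
  f1 <- render_nucleus_image(t1, c(112, 112), seed = 13)
  rr <- matrix(seq_len(112), 112, 112); cc <- t(rr)
  expect_equal(sum(f1$nucleus_mask > 0),
               sum((rr - 56)^2 + (cc - 56)^2 <= 40^2))

  # planted chromocenter counts are summed across nuclei
  truths <- random_nucleus_truths(3, c(192, 256), n_cc_range = c(9, 9),
                                  seed = 14)
  truths[[2]]$chromocenters <- truths[[2]]$chromocenters[1:8, ]
  truths[[3]]$chromocenters <-
    random_nucleus_truths(3, c(192, 256), n_cc_range = c(10, 10),
                          seed = 15)[[3]]$chromocenters
  f2 <- render_nucleus_image(truths, c(192, 256), seed = 16)
  expect_equal(max(f2$cc_mask), 9 + 8 + 10)
  expect_equal(as.integer(table(f2$cc_parent)), c(9L, 8L, 10L))

  # overlapping nuclei are rejected
  t2 <- list(single_nucleus_truth(radius = 20),
             single_nucleus_truth(radius = 22))
  expect_error(render_nucleus_image(t2, c(96, 96), seed = 1), "overlap")

  # masks fed to morphometry reproduce planted areas and intensities
  t3 <- single_nucleus_truth(radius = 25, k = 5, noise_sd = 2, seed = 17)
  f3 <- render_nucleus_image(t3, c(96, 96), seed = 18)
  rec <- measure_object(f3$image, f3$nucleus_mask, 1)
  cc_area <- sum(f3$cc_mask > 0)
  expect_equal(rec$area, sum(f3$nucleus_mask > 0))
  expect_lt(abs(rec$intensity -
                  (90 * (rec$area - cc_area) + 180 * cc_area) / rec$area),
            3 * 2 / sqrt(rec$area))
})

test_that("nucleus truths validate geometry and intensity ordering", {
  expect_error(nucleus_truth(c(10, 10), c(5, 5), nucleus_intensity = 5,
                             background_level = 10),
               "background")
  bad_cc <- data.frame(row = 30, col = 10, radius = 2, intensity = 200)
  expect_error(nucleus_truth(c(10, 10), c(5, 5), chromocenters = bad_cc),
               "inside")
  dim_cc <- data.frame(row = 10, col = 10, radius = 2, intensity = 50)
  expect_error(nucleus_truth(c(10, 10), c(5, 5), chromocenters = dim_cc),
               "exceed")
})
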