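test_that("outlier rules behave as single-pass filters", {
  expect_equal(remove_outliers(rep(5, 10), "sd2"), rep(5, 10))

  v <- c(1:10, 1000)
  expect_false(1000 %in% remove_outliers(v, "sd2"))
  expect_true(all(1:10 %in% remove_outliers(v, "sd2")))

  # N(0,1): the 2 SD rule removes about 2*(1 - pnorm(2)) = 4.55%
  set.seed(51)
  x <- rnorm(1e4)
  frac <- 1 - length(remove_outliers(x, "sd2")) / length(x)
  expect_lt(abs(frac - 2 * (1 - pnorm(2))), 0.01)

  # central 95% interval keeps exactly the inner mass
  kept <- remove_outliers(x, "percentile95")
  expect_lt(abs(length(kept) / length(x) - 0.95), 0.01)

  expect_error(remove_outliers(x, "sd3"))
  expect_error(remove_outliers(c(1, 2), "sd2"))
})

test_that("line summaries enforce sampling thresholds and recover means", {
  tab <- data.frame(
    line_id = rep(c("L1", "L2"), c(25, 30)),
    plant_id = c(rep("p1", 25), rep(c("p1", "p2"), 15)),
    nucleus_id = c(1:25, 1:30),
    area = c(rnorm(25, 10), rnorm(30, 20)))
  expect_warning(s <- line_summary(tab), "excluded")
  expect_equal(unique(s$line_id), "L2")  # 25 nuclei / 1 plant fails both

  tiny <- data.frame(line_id = "L1", plant_id = "p1", nucleus_id = 1:3,
                     v = c(2, 4, 6))
  s2 <- line_summary(tiny, min_nuclei = 1, min_plants = 1,
                     outlier_rule = NULL)
  expect_equal(s2$mean, 4)

  expect_error(line_summary(tab[0, ]), "empty")

  # synthetic table: per-line means near planted line values
  map <- study_map()
  g <- simulate_ril_genotypes(map, 20, seed = 52)
  tt <- simulate_trait_values(g, map, NULL, sigma_line = 1,
                              sigma_nucleus = 2, n_nuclei_per_line = 40,
                              seed = 53)
  s3 <- line_summary(tt, outlier_rule = NULL)
  lv <- attr(tt, "line_values")
  expect_true(all(abs(s3$mean - lv[s3$line_id]) < 3 * 2 / sqrt(40)))
})

test_that("heritability is a truncated one-way variance ratio", {
  # identical line means, noise within: H2 truncates to 0
  set.seed(54)
  t0 <- data.frame(line_id = rep(sprintf("L%d", 1:10), each = 20),
                   plant_id = "p1", nucleus_id = 1:20,
                   y = rep(5, 200) + rnorm(200))
  h0 <- heritability(t0, "y")
  expect_lt(h0$H2, 0.2)

  # zero within-line variance, distinct means: H2 = 1
  t1 <- data.frame(line_id = rep(c("L1", "L2", "L3"), each = 5),
                   plant_id = "p1", nucleus_id = 1:5,
                   y = rep(c(1, 2, 3), each = 5))
  expect_equal(heritability(t1, "y")$H2, 1)

  expect_error(heritability(t1[t1$line_id == "L1", ], "y"), "2 lines")

  # affine invariance of the ratio
  map <- study_map()
  g <- simulate_ril_genotypes(map, 30, seed = 55)
  tt <- simulate_trait_values(g, map, NULL, 1, 1.5, 25, seed = 56)
  h <- heritability(tt, "trait")
  tt$trait <- 100 + 7 * tt$trait
  h2 <- heritability(tt, "trait")
  expect_equal(h$H2, h2$H2, tolerance = 1e-10)

  # planted ratio 0.3 recovered at 50 lines x 30 nuclei
  g50 <- simulate_ril_genotypes(map, 50, seed = 57)
  sl <- sqrt(0.3); sn <- sqrt(0.7)
  errs <- vapply(1:10, function(s) {
    t3 <- simulate_trait_values(g50, map, NULL, sl, sn, 30, seed = 600 + s)
    heritability(t3, "trait")$H2 - 0.3
  }, numeric(1))
  expect_true(all(abs(errs) < 0.15))
  expect_lt(abs(mean(errs)), 0.1)
})

test_that("correlation networks report r, p and star levels over line means", {
  # hand oracle via the textbook formula
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  m <- cbind(a = x, b = y)
  net <- correlation_network(m)
  expect_equal(net$all_pairs$r, r_hand)

  # exact negative correlation
  m2 <- cbind(u = 1:6, v = -(1:6), w = rnorm(6))
  net2 <- correlation_network(m2)
  uv <- net2$all_pairs[net2$all_pairs$trait_a == "u" &
                         net2$all_pairs$trait_b == "v", ]
  expect_equal(uv$r, -1)
  expect_equal(uv$stars, "****")

  # symmetric matrix with unit diagonal; no self edges in the pair list
  expect_equal(net2$r_matrix, t(net2$r_matrix))
  expect_equal(unname(diag(net2$r_matrix)), rep(1, 3))
  expect_false(any(net2$all_pairs$trait_a == net2$all_pairs$trait_b))

  # constant trait: undefined pairs reported missing
  m3 <- cbind(a = 1:8, b = rep(3, 8))
  net3 <- correlation_network(m3)
  expect_true(is.na(net3$all_pairs$r[1]))
  expect_equal(nrow(net3$edges), 0)

  expect_error(correlation_network(m2[1:3, ]), "4 lines")
})

test_that("transgression ratio is min over max of line means", {
  expect_equal(transgression_ratio(c(5, 5, 5)), 100)
  expect_equal(transgression_ratio(c(20, 50, 100)), 20)
  expect_equal(transgression_ratio(c(17.4, 100)), 17.4)
  expect_error(transgression_ratio(c(-1, 5)), "nonpositive")
})

test_that("Welch test matches the textbook statistic", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  w <- welch_test(a, b)
  t_hand <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(w$t, t_hand)
  expect_equal(w$direction, -1)

  same <- c(1, 2, 3, 4)
  w0 <- welch_test(same, same)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)

  set.seed(58)
  w1 <- welch_test(rnorm(200), rnorm(200, 3))
  expect_lt(w1$p, 1e-6)

  expect_error(welch_test(1, c(2, 3)))
  expect_error(welch_test(c(2, 2), c(3, 3)), "constant")
})

test_that("size-class chi-squared uses the 2x2 Pearson statistic", {
  # identical class proportions: statistic 0
  r0 <- chi2_size_classes(c(rep(1, 5), rep(9, 5)), c(rep(2, 5), rep(8, 5)), 5)
  expect_equal(r0$chi2, 0)

  # [[10,0],[0,10]] has the closed-form value 20
  r1 <- chi2_size_classes(rep(1, 10), rep(9, 10), 5)
  expect_equal(r1$chi2, 20)

  # hand oracle for [[30,10],[20,20]]
  a <- c(rep(1, 30), rep(9, 10)); b <- c(rep(1, 20), rep(9, 20))
  tab <- rbind(c(30, 10), c(20, 20))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi2_size_classes(a, b, 5)$chi2, sum((tab - e)^2 / e))

  expect_error(chi2_size_classes(numeric(0), b, 5), "nonempty")
  expect_error(chi2_size_classes(rep(1, 5), rep(2, 5), 10), "empty")
})

test_that("normality screening has reasonable level and power", {
  level <- mean(vapply(1:20, function(s) {
    set.seed(700 + s); test_normality(rnorm(500))$p > 0.05
  }, logical(1)))
  expect_gte(level, 0.9)
  power <- mean(vapply(1:20, function(s) {
    set.seed(800 + s); test_normality(rexp(500))$p < 0.05
  }, logical(1)))
  expect_gte(power, 0.95)
  expect_error(test_normality(rnorm(7)), "8")
  expect_error(test_normality(rep(1, 20)), "constant")
})

test_that("significance letters separate clearly different groups", {
  set.seed(59)
  vals <- c(rnorm(40, 0), rnorm(40, 0.1), rnorm(40, 5))
  grp <- rep(c("g1", "g2", "g3"), each = 40)
  let <- significance_letters(vals, grp, alpha = 0.01)
  expect_equal(let[["g1"]], let[["g2"]])
  expect_false(grepl(let[["g3"]], let[["g1"]], fixed = TRUE))
})
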