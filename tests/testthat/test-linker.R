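test_that("toroidal distance wraps on both axes", {
  expect_equal(torus_distance(c(0, 0), c(99, 99), 100), sqrt(2))
  expect_equal(torus_distance(c(0, 0), c(50, 0), 100), 50)
  expect_equal(torus_distance(c(10, 20), c(13, 24), 100), 5)
  # symmetric and zero on the diagonal
  expect_equal(torus_distance(c(3, 7), c(90, 2), 100),
               torus_distance(c(90, 2), c(3, 7), 100))
  expect_equal(torus_distance(c(5, 5), c(5, 5), 100), 0)
})

test_that("kernel kurtosis inverts exactly over the usable shape range", {
  expect_equal(kernel_kurtosis(1), 10 / 3, tolerance = 1e-14)
  expect_equal(kernel_kurtosis(2), 2, tolerance = 1e-14)
  expect_equal(solve_kernel_shape(10 / 3), 1, tolerance = 1e-6)
  expect_equal(solve_kernel_shape(2), 2, tolerance = 1e-6)
  # kappa(0.5) = Gamma(12) Gamma(4) / Gamma(8)^2 = 66/7
  expect_equal(kernel_kurtosis(0.5), gamma(12) * gamma(4) / gamma(8)^2)
  expect_equal(solve_kernel_shape(gamma(12) * gamma(4) / gamma(8)^2), 0.5,
               tolerance = 1e-6)
  for (b in seq(0.3, 4, by = 0.37))
    expect_equal(solve_kernel_shape(kernel_kurtosis(b)), b, tolerance = 1e-6)
  expect_error(solve_kernel_shape(1.2), "attainable")
})

test_that("kernel scale matches the second-moment identity", {
  expect_equal(solve_kernel_scale(3, 1), 3 / sqrt(6))
  expect_equal(solve_kernel_scale(3, 2), 3)
  expect_error(solve_kernel_scale(0, 1), "sigma")
  ks <- kernel_spec(kappa = 10 / 3, sigma_d = 0.1, l_size = 100)
  expect_equal(ks$b, 1, tolerance = 1e-6)
  expect_equal(ks$sigma, 0.1 * 100 * sqrt(2))
  expect_equal(ks$a, ks$sigma / sqrt(6), tolerance = 1e-6)
})

test_that("num_links rounds half-up and respects bounds", {
  expect_identical(num_links(500, 0.1), 12475L)
  expect_identical(num_links(500, 0.01), 1248L)   # 1247.5 rounds up
  expect_identical(num_links(2539, 0.0009), 2900L)
  expect_identical(num_links(10, 0), 0L)
  expect_identical(num_links(10, 1), 45L)
  expect_error(num_links(10, 1.2), "l_d")
})

test_that("focal assignment flags exactly round(F n) nodes, reproducibly", {
  fo <- assign_focal(500, 0.2, seed = 1)
  expect_equal(sum(fo), 100)
  expect_identical(fo, assign_focal(500, 0.2, seed = 1))
  expect_equal(sum(assign_focal(50, 0)), 0)
  expect_equal(sum(assign_focal(10, 0.25, seed = 2)), 3)  # 2.5 -> 3
})

test_that("pair weights follow the kernel and focal amplification", {
  # 3 collinear nodes on a 9-torus are mutually at distance 3; one focal,
  # fsf = 10: the two mixed pairs carry 10/21 each, the regular pair 1/21
  coords <- rbind(c(0, 0), c(3, 0), c(6, 0))
  l <- structure(list(coords = coords, l_size = 9), class = "specnet_landscape")
  kern <- kernel_spec(sigma = 2)
  w <- pair_weights(l, focal = c(FALSE, FALSE, TRUE), kern, fsf = 10)
  expect_equal(sum(w$w), 1)
  expect_equal(w$w[w$pairs[, 1] == 1 & w$pairs[, 2] == 2], 1 / 21)
  expect_equal(sort(w$w), c(1 / 21, 10 / 21, 10 / 21))

  # no focal nodes, equal distances: uniform
  w0 <- pair_weights(l, focal = c(FALSE, FALSE, FALSE), kern, fsf = 10)
  expect_equal(w0$w, rep(1 / 3, 3))
})

test_that("draw_links matches the sequential renormalisation distribution", {
  # degenerate cases
  expect_identical(draw_links(c(0, 1, 0), 1), 2L)
  full <- draw_links(list(pairs = cbind(c(1, 1, 2), c(2, 3, 3)),
                          w = rep(1 / 3, 3)), 3, seed = 1)
  expect_equal(nrow(full), 3)
  expect_error(draw_links(c(1, 0, 0), 2), "positive weight")

  # first-draw marginal equals the weights (chi-square, alpha = 0.01)
  w <- c(0.5, 0.3, 0.2)
  set.seed(99)
  picks <- vapply(1:10000, function(i) draw_links(w, 1), integer(1))
  expect_gt(chisq.test(tabulate(picks, 3), p = w)$p.value, 0.01)

  # joint L=2 distribution against the literal sequential oracle
  set.seed(7)
  mine <- replicate(6000, paste(sort(draw_links(w, 2)), collapse = "-"))
  orac <- replicate(6000, paste(sort(sequential_draw_oracle(w, 2)), collapse = "-"))
  tab <- table(factor(mine, c("1-2", "1-3", "2-3")),
               factor(orac, c("1-2", "1-3", "2-3")))
  expect_gt(chisq.test(rowSums(tab), p = colSums(tab) / 6000)$p.value, 0.01)
})

test_that("small-instance selection probabilities match pair_weights", {
  set.seed(123)
  l <- node_landscape(5, 12, gamma = 1, seed = 4)
  focal <- c(TRUE, FALSE, FALSE, FALSE, TRUE)
  w <- pair_weights(l, focal, kernel_spec(sigma = 4), fsf = 5)
  picks <- vapply(1:10000, function(i) draw_links(w$w, 1), integer(1))
  expect_gt(chisq.test(tabulate(picks, length(w$w)), p = w$w)$p.value, 0.01)
})

test_that("generated networks have the exact requested size and structure", {
  net <- specnet(n = 500, l_d = 0.01, gamma = 0, sigma_d = 0.1, fsf = 10,
                 f = 0, seed = 2)
  expect_equal(nrow(net$edges), 1248)
  expect_equal(sum(net$focal), 0)
  expect_equal(mean(degree_sequence_of(net)), 2 * 1248 / 500)

  net2 <- specnet(n = 2539, l_d = 0.0009, gamma = 1.3247, sigma_d = 0.3,
                  fsf = 15, f = 0.2, l_size = 175, seed = 3)
  expect_equal(nrow(net2$edges), 2900)
  expect_equal(sum(net2$focal), round(0.2 * 2539))

  expect_identical(specnet(n = 80, l_d = 0.05, seed = 9)$edges,
                   specnet(n = 80, l_d = 0.05, seed = 9)$edges)
})

test_that("simple-graph and edge-count invariants hold over random configs", {
  set.seed(2024)
  for (i in 1:60) {
    n <- sample(10:60, 1)
    cfg <- list(n = n, l_d = runif(1, 0.01, 0.3), gamma = runif(1, 0, 2),
                sigma_d = runif(1, 0.01, 0.3), fsf = sample(c(1, 10, 100), 1),
                f = runif(1, 0, 0.3), l_size = sample(20:50, 1))
    net <- do.call(specnet, c(cfg, seed = i))
    e <- net$edges
    expect_equal(nrow(e), num_links(n, cfg$l_d))
    if (nrow(e)) {
      expect_true(all(e[, 1] < e[, 2]))          # no self-loops, ordered
      expect_equal(anyDuplicated(e), 0L)         # no duplicate links
      expect_true(all(e >= 1 & e <= n))
    }
  }
})

test_that("with F = 0 the focal scale factor has no influence", {
  a <- specnet(n = 100, l_d = 0.05, gamma = 1, sigma_d = 0.1, fsf = 10,
               f = 0, seed = 11)
  b <- specnet(n = 100, l_d = 0.05, gamma = 1, sigma_d = 0.1, fsf = 1000,
               f = 0, seed = 11)
  expect_identical(a$edges, b$edges)
})

test_that("clustering falls and assortativity falls as sigma grows", {
  lo <- replicate_measures(10, 500, n = 200, l_d = 0.05, gamma = 1,
                           sigma_d = 0.01, fsf = 10, f = 0.1)
  hi <- replicate_measures(10, 900, n = 200, l_d = 0.05, gamma = 1,
                           sigma_d = 0.3, fsf = 10, f = 0.1)
  expect_gt(mean(lo$clustering), mean(hi$clustering))
  expect_gt(mean(lo$assortativity, na.rm = TRUE),
            mean(hi$assortativity, na.rm = TRUE))
})

test_that("assortativity falls as fsf and f grow", {
  base <- replicate_measures(10, 100, n = 200, l_d = 0.05, gamma = 0,
                             sigma_d = 0.2, fsf = 10, f = 0.1)
  hi_fsf <- replicate_measures(10, 300, n = 200, l_d = 0.05, gamma = 0,
                               sigma_d = 0.2, fsf = 1000, f = 0.1)
  expect_gt(mean(base$assortativity, na.rm = TRUE),
            mean(hi_fsf$assortativity, na.rm = TRUE))
  no_f <- replicate_measures(10, 700, n = 200, l_d = 0.05, gamma = 0,
                             sigma_d = 0.2, fsf = 1000, f = 0)
  expect_gt(mean(no_f$assortativity, na.rm = TRUE),
            mean(hi_fsf$assortativity, na.rm = TRUE))
})
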