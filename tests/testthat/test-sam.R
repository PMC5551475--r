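test_that("two-class numerator/denominator match hand arithmetic", {
  th <- theta_fixture(mean = cbind(c(2), c(4)), variance = cbind(c(1), c(1)))
  st <- sam_two_class_stats(th, c(3, 3))
  expect_equal(st$r, -2)
  expect_equal(st$s, sqrt((1 / 6) * (2 * 1 + 2 * 1)))
  expect_equal(st$r / st$s, -2.449489742783178)
  # equal means -> r = 0; balanced equal variances -> s = sqrt(2 v / n)
  th2 <- theta_fixture(mean = cbind(c(3, 1), c(3, 5)),
                       variance = cbind(c(0.4, 0.7), c(0.4, 0.7)))
  st2 <- sam_two_class_stats(th2, c(4, 4))
  expect_equal(st2$r[1], 0)
  expect_equal(st2$s, sqrt(2 * c(0.4, 0.7) / 4))
  expect_error(sam_two_class_stats(th, c(3, 3, 3)), "wrong arity")
})

test_that("multiclass score matches brute-force arithmetic and the two-class case", {
  # m = 3, n_k = 2, means (0, 1, 2): r = sqrt(6/8 * 2 * ((0-1)^2 + 0 + (2-1)^2))
  th <- theta_fixture(mean = matrix(c(0, 1, 2), 1), variance = matrix(0.5, 1, 3))
  st <- sam_multiclass_stats(th, c(2, 2, 2))
  expect_equal(st$r, sqrt(6 / 8 * 2 * 2))
  expect_equal(st$s, sqrt((3 / 2) / 3 * 0.5 * 3))
  # all means equal -> r = 0
  th0 <- theta_fixture(mean = matrix(4, 1, 3), variance = matrix(1, 1, 3))
  expect_equal(sam_multiclass_stats(th0, c(3, 3, 3))$r, 0)
  # m = 2: multiclass numerator equals |two-class numerator|, any n_k
  th2 <- theta_fixture(mean = cbind(c(3.2, 4.4), c(4.0, 3.1)),
                       variance = cbind(c(0.3, 0.5), c(0.2, 0.4)))
  two <- sam_two_class_stats(th2, c(3, 5))
  multi <- sam_multiclass_stats(th2, c(3, 5))
  expect_equal(multi$r, abs(two$r))
  expect_equal(multi$s, two$s)
  expect_error(sam_multiclass_stats(th, c(2, 1, 2)), "insufficient data")
})

test_that("multiclass numerator grows with any single mean's deviation", {
  base <- c(3.5, 4, 4.5, 4)
  r_of <- function(mu1) {
    th <- theta_fixture(mean = matrix(c(mu1, base[-1]), 1),
                        variance = matrix(0.1, 1, 4))
    sam_multiclass_stats(th, rep(3, 4))$r
  }
  shifts <- seq(0, 1.5, by = 0.5)
  rs <- vapply(base[1] - shifts, r_of, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("s0 selection follows the declared percentile convention", {
  expect_equal(choose_s0(rep(3, 50)), 3)
  expect_equal(choose_s0(1:100, q = 5), 5.95)
  set.seed(71)
  s <- rchisq(500, 3)
  r <- rnorm(500)
  for (rule in c("percentile", "samr_cv")) {
    s0 <- choose_s0(s, r, rule = rule)
    expect_gte(s0, 0)
    expect_lte(s0, max(s))
  }
})

test_that("scores equal the plain statistic at s0 = 0 and match the oracle path", {
  fx <- toy_two_class(G = 50, seed = 81)
  sc <- sam_scores(fx$es, config = sam_config(robust = FALSE))
  d_oracle <- oracle_two_class_d(fx$es$x, 1:5, 6:10, sc$s0)
  expect_equal(sc$d, unname(d_oracle))
  expect_equal(sc$r / sc$s, unname(oracle_two_class_d(fx$es$x, 1:5, 6:10, 0)))
})

test_that("robust and classical scores agree on clean data", {
  fx <- toy_two_class(G = 300, seed = 91)
  sc_r <- sam_scores(fx$es, config = sam_config(robust = TRUE))
  sc_c <- sam_scores(fx$es, config = sam_config(robust = FALSE))
  unflagged <- rowSums(sc_r$report$gene_condition_flags) == 0
  expect_gt(mean(unflagged), 0.98)
  expect_equal(sc_r$d[unflagged], sc_c$d[unflagged], tolerance = 1e-6)
})

test_that("a single injected outlier wrecks the classical score but not the robust one", {
  fx <- toy_two_class(G = 300, n1 = 6, n2 = 6, seed = 95)
  sc0 <- sam_scores(fx$es, config = sam_config(robust = TRUE))
  x <- fx$es$x
  g <- 3  # a DE gene
  x[g, 2] <- 7.5 + 2 * max(x[g, ])
  es2 <- expression_set(x, fx$es$labels)
  sc_r <- sam_scores(es2, config = sam_config(robust = TRUE))
  sc_c <- sam_scores(es2, config = sam_config(robust = FALSE))
  expect_gt(abs(sc_c$d[g] - sc0$d[g]) / abs(sc0$d[g]), 0.5)
  expect_lt(abs(sc_r$d[g] - sc0$d[g]) / abs(sc0$d[g]), 0.1)
})

test_that("two-class scores are antisymmetric under label swap and scale invariant", {
  fx <- toy_two_class(G = 80, seed = 105)
  d1 <- sam_scores(fx$es, config = sam_config(robust = TRUE))$d
  es_swap <- expression_set(fx$es$x,
                            factor(fx$es$labels, levels = c("b", "a")))
  d2 <- sam_scores(es_swap, config = sam_config(robust = TRUE))$d
  expect_equal(d2, -d1)
  es_scaled <- expression_set(3 * fx$es$x, fx$es$labels)
  d3 <- sam_scores(es_scaled, config = sam_config(robust = TRUE))$d
  expect_equal(d3, d1, tolerance = 1e-6)
  # permuting samples together with their labels leaves scores unchanged
  p <- sample(ncol(fx$es$x))
  es_p <- expression_set(fx$es$x[, p], fx$es$labels[p])
  expect_equal(sam_scores(es_p, config = sam_config(robust = TRUE))$d, d1)
})

test_that("permutation expected order stats match exhaustive enumeration at 3+3", {
  fx <- toy_two_class(G = 40, n1 = 3, n2 = 3, n_de = 5, seed = 115)
  sc <- sam_scores(fx$es, config = sam_config(robust = FALSE))
  perm <- permutation_order_stats(fx$es, sc$s0,
                                  config = sam_config(robust = FALSE,
                                                      n_permutations = 100))
  expect_equal(nrow(perm$perm_scores), choose(6, 3))
  # independent enumeration oracle
  combs <- combn(6, 3)
  sorted <- sapply(seq_len(ncol(combs)), function(b) {
    idx1 <- combs[, b]
    sort(oracle_two_class_d(fx$es$x, idx1, setdiff(1:6, idx1), sc$s0))
  })
  expect_equal(perm$expected, unname(rowMeans(sorted)))
})

test_that("constant rows score zero under every permutation", {
  x <- matrix(rep(c(1, 5, 2), each = 8), 3, 8, byrow = TRUE)
  es <- expression_set(x, rep(c("a", "b"), each = 4))
  sc <- sam_scores(es, config = sam_config(robust = FALSE))
  expect_equal(sc$d, rep(0, 3))
  perm <- permutation_order_stats(es, sc$s0,
                                  config = sam_config(robust = FALSE,
                                                      n_permutations = 100))
  expect_true(all(perm$perm_scores == 0))
})

test_that("Delta-calling walks the Q-Q pairs as specified", {
  d <- c(-5, 0, 0, 4)
  expected <- c(-1, 0, 0, 1)
  call <- delta_calling(d, expected, delta = 2)
  expect_equal(call$called_down, 1L)
  expect_equal(call$called_up, 4L)
  # delta beyond the largest deviation calls nothing
  call0 <- delta_calling(d, expected, delta = 10)
  expect_length(call0$called_up, 0)
  expect_length(call0$called_down, 0)
  expect_equal(call0$cut_up, Inf)
  # observed equal to expected calls nothing at any positive delta
  call1 <- delta_calling(sort(expected), expected, delta = 1e-9)
  expect_length(c(call1$called_up, call1$called_down), 0)
})

test_that("permutation FDR counts false calls like a direct count", {
  perm <- matrix(c(-3, -1, 0, 1, 2.5, 4), 1)
  expect_equal(estimate_fdr(perm, cut_low = -2, cut_up = 2, n_called = 4),
               3 / 4)  # -3, 2.5, 4 beyond the cutoffs
  expect_equal(estimate_fdr(perm, cut_low = -Inf, cut_up = Inf, n_called = 0), 0)
  expect_equal(estimate_fdr(perm, cut_low = -10, cut_up = 10, n_called = 5), 0)
})

test_that("the full pipeline is seed-reproducible and classical on clean data", {
  fx <- toy_two_class(G = 120, seed = 125)
  cfg <- sam_config(robust = TRUE, n_permutations = 30, delta = 0.5, seed = 9)
  res1 <- run_robust_sam(fx$es, config = cfg)
  res2 <- run_robust_sam(fx$es, config = cfg)
  expect_identical(res1$d, res2$d)
  expect_identical(res1$expected, res2$expected)
  expect_identical(res1$called_up, res2$called_up)
  res_c <- run_robust_sam(fx$es, config = sam_config(robust = FALSE,
                                                     n_permutations = 30,
                                                     delta = 0.5, seed = 9))
  expect_equal(sort(res1$called_up), sort(res_c$called_up))
  expect_equal(sort(res1$called_down), sort(res_c$called_down))
  # called genes lie beyond the cutoffs; up/down sets disjoint
  expect_true(all(res1$d[res1$called_up] >= res1$cut_up))
  expect_true(all(res1$d[res1$called_down] <= res1$cut_low))
  expect_length(intersect(res1$called_up, res1$called_down), 0)
})
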