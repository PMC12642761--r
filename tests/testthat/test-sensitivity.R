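# analytic and brute-force oracles for the Sobol estimators

test_that("a single active factor takes all the variance", {
  res <- sobol_indices(function(M) M[, 1],
                       ranges = list(x1 = c(0, 1), x2 = c(0, 1)),
                       n_base = 1024, seed = 1, n_boot = 0)
  expect_lt(max(abs(res$S1 - c(1, 0))), 0.02)
  expect_lt(max(abs(res$ST - c(1, 0))), 0.02)
})

test_that("additive model: analytic variance shares, vanishing interactions", {
  a <- 2
  b <- 1
  res <- sobol_indices(function(M) a * M[, 1] + b * M[, 2],
                       ranges = list(x1 = c(0, 1), x2 = c(0, 1)),
                       n_base = 1024, second_order = TRUE, seed = 2,
                       n_boot = 0)
  expect_lt(abs(res$S1[[1]] - a^2 / (a^2 + b^2)), 0.03)
  expect_lt(abs(res$S1[[2]] - b^2 / (a^2 + b^2)), 0.03)
  expect_lt(abs(res$S2[1, 2]), 0.03)
  # total and first-order agree for additive models
  expect_lt(max(abs(res$ST - res$S1)), 0.03)
})

test_that("pure product on [-1,1]^2: all variance is interaction", {
  res <- sobol_indices(function(M) M[, 1] * M[, 2],
                       ranges = list(x1 = c(-1, 1), x2 = c(-1, 1)),
                       n_base = 1024, second_order = TRUE, seed = 3,
                       n_boot = 0)
  expect_lt(max(abs(res$S1)), 0.05)
  expect_lt(max(abs(res$ST - 1)), 0.05)
  expect_lt(abs(res$S2[1, 2] - 1), 0.1)
})

test_that("estimates match brute-force conditional-variance quadrature", {
  # 3-factor nonlinear model; oracle by dense-grid quadrature
  f <- function(x1, x2, x3) x1 * x2 + 0.5 * x3^2 + 0.3 * x1
  m <- 41
  gr <- seq(0, 1, length.out = m)
  G <- expand.grid(x1 = gr, x2 = gr, x3 = gr)
  Y <- f(G$x1, G$x2, G$x3)
  V <- var(Y)
  S1_oracle <- vapply(1:3, function(i) {
    var(tapply(Y, G[[i]], mean)) / V
  }, numeric(1))
  ST_oracle <- vapply(1:3, function(i) {
    others <- interaction(G[setdiff(1:3, i)], drop = TRUE)
    mean(tapply(Y, others, var)) / V
  }, numeric(1))
  res <- sobol_indices(function(M) f(M[, 1], M[, 2], M[, 3]),
                       ranges = list(x1 = c(0, 1), x2 = c(0, 1),
                                     x3 = c(0, 1)),
                       n_base = 2048, seed = 4, n_boot = 0)
  expect_lt(max(abs(unname(res$S1) - S1_oracle)), 0.03)
  expect_lt(max(abs(unname(res$ST) - ST_oracle)), 0.03)
})

test_that("total indices dominate first-order indices on every run", {
  set.seed(5)
  for (rep in 1:5) {
    cf <- runif(3)
    res <- sobol_indices(
      function(M) cf[1] * M[, 1] + cf[2] * M[, 2] * M[, 3] + cf[3] * M[, 3],
      ranges = list(x1 = c(0, 1), x2 = c(0, 1), x3 = c(0, 1)),
      n_base = 512, seed = rep, n_boot = 0)
    expect_true(all(res$ST - res$S1 > -0.05))
    expect_lte(sum(res$S1), 1.05)
  }
})

test_that("fixed seed reproduces indices exactly; zero variance is flagged", {
  r1 <- sobol_indices(function(M) M[, 1]^2, list(x = c(0, 1), y = c(0, 1)),
                      n_base = 256, seed = 9, n_boot = 0)
  r2 <- sobol_indices(function(M) M[, 1]^2, list(x = c(0, 1), y = c(0, 1)),
                      n_base = 256, seed = 9, n_boot = 0)
  expect_identical(r1$S1, r2$S1)
  expect_identical(r1$ST, r2$ST)

  expect_warning(
    rz <- sobol_indices(function(M) rep(2, nrow(M)),
                        list(x = c(0, 1)), n_base = 128, seed = 1,
                        n_boot = 0),
    "variance")
  expect_equal(unname(rz$S1), 0)
})

test_that("level-1 screening: lone varying parameter takes ST = 1", {
  g <- toy_graph(4, seed = 2, density = 1)
  rng <- lapply(default_level1_ranges_fixture(), function(b) b)
  # collapse every range except the cognition logistic rate
  rng <- lapply(rng, function(b) c(mean(b), mean(b)))
  rng$lambda_C <- c(0.02, 0.3)
  res <- sobol_level1(g, ranges = rng, ages = c(80, 100), n_base = 512,
                      seed = 1)
  expect_lt(max(abs(res$ST["lambda_C", ] - 1)), 0.1)
  expect_true(all(res$ST[setdiff(rownames(res$ST), "lambda_C"), ] == 0))
})

test_that("level-1 screening: cutting the N-to-C coupling decouples upstream", {
  g <- toy_graph(4, seed = 2, density = 1)
  rng <- default_level1_ranges_fixture()
  rng$lambda_CN <- c(0, 0)  # C no longer senses N (or anything upstream)
  res <- sobol_level1(g, ranges = rng, ages = c(90), n_base = 256, seed = 2)
  upstream <- c("D_Abeta", "D_tau", "D_N", "lambda_Abeta", "lambda_tau",
                "lambda_N", "lambda_tauAbeta", "lambda_Ntau", "K_Abeta",
                "K_tau", "K_N")
  expect_true(all(abs(res$ST[upstream, 1]) < 0.1))
  expect_gt(res$ST["lambda_C", 1], 0.1)
})

test_that("level-1 output at the initial age is flagged as zero-variance", {
  g <- toy_graph(4, seed = 2, density = 1)
  res <- sobol_level1(g, ranges = default_level1_ranges_fixture(),
                      ages = c(50, 90), n_base = 64, seed = 3)
  expect_true(res$zero_variance[1])
  expect_false(res$zero_variance[2])
})

test_that("level-2 regional analysis: structural zeros and bookkeeping", {
  n <- 8
  g <- toy_graph(n, seed = 4, density = 0.8)
  lobes <- rep(c("A", "B"), each = 4)
  p <- toy_params(n)
  y0 <- toy_state(n)
  # only lobe-A regions vary
  rng <- cbind(rep(0.05, n), c(rep(0.3, 4), rep(0.05, 4)))
  res <- sobol_level2("lambda_Abeta", g, rng, lobes, p, y0,
                      stages = c(80), n_base = 256, seed = 5)
  r80 <- res$age80
  expect_equal(unname(r80$lobe_S1["B"]), 0)
  expect_equal(r80$lobe_S2["A", "B"], 0)
  expect_gt(r80$lobe_S1["A"], 0.3)
  # variance decomposition approximately closes. Second-order terms are
  # small differences of large estimates, so each of the 6 summed pairs
  # carries Monte-Carlo error ~0.05-0.1 even under low-discrepancy
  # sampling; the bound reflects that error budget.
  total <- sum(r80$lobe_S1) + sum(r80$lobe_S2[upper.tri(r80$lobe_S2, diag = TRUE)])
  expect_lt(abs(1 - total), 0.4)
  # lobe-B S1 and the cross-lobe interaction are structural zeros
  expect_lt(abs(r80$lobe_S1[["B"]]), 1e-12)

  # all regions in one lobe: lobe S1 equals the total first-order share
  res1 <- sobol_level2("lambda_Abeta", g, cbind(rep(0.05, n), rep(0.3, n)),
                       rep("A", n), p, y0, stages = c(80), n_base = 256,
                       seed = 6)
  expect_equal(unname(res1$age80$lobe_S1["A"]), sum(res1$age80$S1))
})

test_that("region ranking breaks S1 ties by total index and partitions lobes", {
  S1 <- c(0.5, 0.5, 0.3, 0.1)
  ST <- c(0.6, 0.9, 0.4, 0.2)
  lob <- c("A", "B", "A", "B")
  rk <- rank_regions(S1, ST, lob, k = 3)
  expect_equal(rk$regions$region, c(2, 1, 3))  # tie on S1 resolved by ST
  expect_equal(sum(rk$lobe_counts), 3)
  expect_warning(rank_regions(S1, ST, lob, k = 10), "clipping")
})

test_that("the shipped lobe map covers all 68 regions with six lobes", {
  lm <- dk68_lobe_map()
  expect_length(lm, 68)
  expect_setequal(unique(lm),
                  c("frontal", "temporal", "parietal", "occipital",
                    "limbic", "insular"))
})
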