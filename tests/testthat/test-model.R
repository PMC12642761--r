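test_that("the model exposes exactly 6 global and 8 regional parameters", {
  nm <- adbc_parameter_names()
  expect_length(nm$global, 6)
  expect_length(nm$regional, 8)
  p <- toy_params(n = 68)
  for (g in nm$global) expect_length(p[[g]], 1)
  for (r in nm$regional) expect_length(p[[r]], 68)
  # scalars broadcast; wrong lengths rejected
  expect_equal(adbc_params(n_regions = 5, lambda_Abeta = 0.2)$lambda_Abeta,
               rep(0.2, 5))
  expect_error(adbc_params(n_regions = 5, lambda_Abeta = c(1, 2)), "length")
  expect_error(adbc_params(D_Abeta = -1), "nonnegative")
  expect_error(adbc_params(K_C = 0), "positive")
})

test_that("uniform state at carrying capacity with zero couplings is a fixed point", {
  g <- toy_graph(6, seed = 2, density = 0.7)
  p <- toy_params(6, lambda_tauAbeta = 0, lambda_Ntau = 0, lambda_CN = 0)
  st <- adbc_state(p$K_Abeta, p$K_tau, p$K_N, p$K_C)
  d <- adbc_rhs(st, p, g)
  expect_equal(max(abs(c(d$Abeta, d$tau, d$N, d$C))), 0, tolerance = 1e-12)
})

test_that("zero diffusion reduces each region to an independent logistic", {
  g <- toy_graph(3, seed = 1)
  p <- toy_params(3, D_Abeta = 0, lambda_Abeta = c(0.2, 0, 0),
                  K_Abeta = c(1.5, 1, 1))
  st <- adbc_state(c(0.3, 0, 0), rep(0, 3), rep(0, 3), 0)
  d <- adbc_rhs(st, p, g)
  expect_equal(d$Abeta[1], 0.2 * 0.3 * (1.5 - 0.3))
  expect_equal(d$Abeta[2:3], c(0, 0))
})

test_that("rhs matches a central finite difference of the integrated flow", {
  set.seed(4)
  g <- toy_graph(5, seed = 3, density = 0.8)
  p <- toy_params(5, lambda_Abeta = runif(5, 0.1, 0.2),
                  lambda_tau = runif(5, 0.1, 0.2))
  st <- adbc_state(runif(5, 0, 0.5), runif(5, 0, 0.3), runif(5, 0, 0.3), 0.1)
  h <- 1e-4
  tr <- adbc_simulate(p, st, g, t0 = 60, t_end = 60 + 2 * h,
                      t_eval = c(60, 60 + 2 * h), rtol = 1e-10, atol = 1e-12)
  fd <- (c(tr$Abeta[, 2], tr$tau[, 2], tr$N[, 2], tr$C[2]) -
         c(tr$Abeta[, 1], tr$tau[, 1], tr$N[, 1], tr$C[1])) / (2 * h)
  d <- adbc_rhs(st, p, g)
  expect_equal(fd, c(d$Abeta, d$tau, d$N, d$C), tolerance = 1e-4)
})

test_that("single-node logistic matches the closed form", {
  # 1-node graph: L = 0, pure logistic growth
  g <- brain_graph(matrix(0, 1, 1))
  lam <- 0.15
  K <- 1.3
  y0 <- 0.08
  p <- adbc_params(n_regions = 1, lambda_Abeta = lam, K_Abeta = K)
  st <- adbc_state(y0, 0, 0, 0)
  ages <- seq(50, 100, by = 5)
  tr <- adbc_simulate(p, st, g, t_eval = ages, rtol = 1e-9, atol = 1e-11)
  tt <- ages - 50
  closed <- K * y0 * exp(lam * K * tt) / (K + y0 * (exp(lam * K * tt) - 1))
  expect_equal(as.numeric(tr$Abeta[1, ]), closed, tolerance = 1e-6)
})

test_that("pure diffusion conserves the field total and shrinks its variance", {
  set.seed(6)
  g <- toy_graph(8, seed = 5, density = 0.6)
  p <- adbc_params(n_regions = 8, D_Abeta = 0.4, D_tau = 0.2, D_N = 0.1)
  st <- adbc_state(runif(8), runif(8), runif(8), 0)
  tr <- adbc_simulate(p, st, g, t_eval = seq(50, 100, 5),
                      rtol = 1e-9, atol = 1e-11)
  for (b in c("Abeta", "tau", "N")) {
    sums <- colSums(tr[[b]])
    expect_lt(max(abs(sums - sums[1])), 1e-8)
    vars <- apply(tr[[b]], 2, var)
    expect_true(all(diff(vars) <= 1e-10))
  }
})

test_that("trajectories are nondecreasing for states below capacity", {
  # severity orientation: nonnegative couplings, y0 in (0, K)
  # sampled in the generator's regime: moderate rate heterogeneity and
  # initial spread, so logistic growth dominates diffusive outflow
  set.seed(8)
  for (rep in 1:5) {
    g <- toy_graph(6, seed = rep + 10, density = 0.7)
    base <- runif(1, 0.08, 0.25)
    p <- toy_params(6, lambda_Abeta = base * runif(6, 0.8, 1.2),
                    lambda_tau = base * runif(6, 0.8, 1.2),
                    lambda_N = base * runif(6, 0.8, 1.2))
    y0b <- runif(1, 0.03, 0.12)
    st <- adbc_state(y0b * runif(6, 0.8, 1.2), 0.6 * y0b * runif(6, 0.8, 1.2),
                     0.6 * y0b * runif(6, 0.8, 1.2), 0.01)
    tr <- adbc_simulate(p, st, g, t_eval = seq(50, 100, 2))
    for (b in c("Abeta", "tau", "N")) {
      expect_true(all(apply(tr[[b]], 1, function(v) all(diff(v) >= -1e-6))))
    }
    expect_true(all(diff(tr$C) >= -1e-6))
  }
})

test_that("cognition senses neurodegeneration only through its graph integral", {
  g <- toy_graph(4, seed = 9, density = 1)
  p <- toy_params(4)
  st <- adbc_state(rep(0.2, 4), rep(0.1, 4), c(0.4, 0.2, 0.1, 0.3), 0.05)
  base <- adbc_rhs(st, p, g)$C
  # redistribute N, preserving the degree-weighted mean
  d <- g$degree
  delta <- c(1, -d[1] / d[2], 0, 0) * 0.05
  st2 <- st
  st2$N <- st$N + delta
  expect_equal(graph_integral(st2$N, g), graph_integral(st$N, g))
  expect_equal(adbc_rhs(st2, p, g)$C, base, tolerance = 1e-12)
})

test_that("compiled integrator agrees with an independent solver", {
  skip_if_not_installed("deSolve")
  set.seed(12)
  g <- toy_graph(6, seed = 20, density = 0.7)
  p <- toy_params(6, lambda_Abeta = runif(6, 0.08, 0.25),
                  K_Abeta = runif(6, 1, 1.3))
  st <- adbc_state(runif(6, 0, 0.2), runif(6, 0, 0.1), runif(6, 0, 0.1),
                   0.02)
  ages <- seq(50, 100, 10)
  tr <- adbc_simulate(p, st, g, t_eval = ages)
  rhsf <- function(t, y, parms) {
    s <- adbcascade:::vec_to_state(y, 6)
    d <- adbc_rhs(s, p, g)
    list(c(d$Abeta, d$tau, d$N, d$C))
  }
  ref <- deSolve::ode(adbcascade:::state_to_vec(st), ages, rhsf, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  ours <- rbind(tr$Abeta, tr$tau, tr$N, tr$C)
  expect_lt(max(abs(ours - t(ref[, -1]))), 1e-5)
})

test_that("simulate validates its time arguments", {
  g <- toy_graph(3)
  p <- toy_params(3)
  st <- toy_state(3)
  expect_error(adbc_simulate(p, st, g, t0 = 60, t_end = 50), "earlier")
  expect_error(adbc_simulate(p, st, g, t_eval = c(40, 60)), "within")
})

test_that("accuracy scoring: perfect, null and scaled predictions", {
  g <- toy_graph(4, seed = 2)
  p <- toy_params(4, lambda_Abeta = 0.15)
  st <- toy_state(4)
  tr <- adbc_simulate(p, st, g, t_eval = seq(50, 100, 1))
  recs <- records_from_trajectory(tr, c(60, 70, 80))
  acc <- trajectory_accuracy(tr, recs)
  expect_equal(unname(acc["overall"]), 100, tolerance = 1e-6)

  # prediction identically zero against nonzero data scores 0
  p0 <- adbc_params(n_regions = 4)
  tr0 <- adbc_simulate(p0, adbc_state(rep(0, 4), rep(0, 4), rep(0, 4), 0),
                       g, t_eval = seq(50, 100, 1))
  acc0 <- trajectory_accuracy(tr0, recs)
  expect_equal(unname(acc0["Abeta"]), 0)

  # single-visit vector at 0.9 of the data: 90%
  one <- data.frame(subject_id = "X", age = 70, biomarker = "Abeta",
                    region = 1:4, value = 1)
  tr9 <- tr
  tr9$Abeta[, ] <- 0.9
  expect_equal(unname(trajectory_accuracy(tr9, one)["Abeta"]), 90)

  # biomarkers without records are omitted
  expect_false("tau" %in% names(trajectory_accuracy(tr, one)))
})
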