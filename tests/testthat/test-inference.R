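# fast inference-machinery tests; the cohort-scale recovery study lives in
# test-acceptance.R

test_that("homotopy schedules decay geometrically and validate inputs", {
  expect_equal(homotopy_schedule(1000, 10, 4), c(1000, 100, 10, 1))
  expect_equal(homotopy_schedule(1000, 10, 1), 1000)
  expect_error(homotopy_schedule(-1, 10, 4), "positive")
  expect_error(homotopy_schedule(1000, 1, 4), "exceed 1")
  expect_error(homotopy_schedule(1000, 10, 0), "at least one")
})

test_that("control settings validate bounds and record the holdout policy", {
  ctl <- adbc_control()
  expect_equal(ctl$bounds$D, c(0, 2))
  expect_equal(ctl$bounds$lambda, c(0, 2))
  expect_equal(ctl$bounds$K, c(1, 2))
  expect_equal(ctl$bounds$y0, c(0, 1))
  expect_equal(ctl$holdout, "last_visit")
  expect_error(adbc_control(bounds = list(D = c(2, 0), lambda = c(0, 2),
                                          K = c(1, 2), y0 = c(0, 1),
                                          cross = c(0, 2))),
               "lower <= upper")
})

test_that("loss is zero at a perfect fit and follows the stated arithmetic", {
  g <- toy_graph(4, seed = 2)
  p <- toy_params(4, K_Abeta = 1, K_tau = 1, K_N = 1, K_C = 1,
                  lambda_Abeta = 0.4, lambda_tau = 0.4, lambda_N = 0.4,
                  lambda_C = 0.4, lambda_tauAbeta = 0, lambda_Ntau = 0,
                  lambda_CN = 0)
  y0 <- toy_state(4, ab = 0.2, ta = 0.2, nn = 0.2, C = 0.2)
  tr <- adbc_simulate(p, y0, g, t_eval = seq(50, 100, 1))
  recs <- records_from_trajectory(tr, c(60, 70, 80))
  # logistic with K = 1 saturates: y(100) ~ 1, data fit exact -> loss ~ 0
  expect_lt(adbc_loss(p, y0, recs, g, w = 1), 1e-4)

  # single visit, prediction twice the observation, w = 0 -> loss 1
  one <- recs[recs$biomarker == "Abeta" & recs$age == 70, ]
  half <- one
  half$value <- half$value / 2
  expect_equal(adbc_loss(p, y0, half, g, w = 0), 1, tolerance = 1e-6)

  # a large endpoint weight dominates any unsaturated trajectory
  p2 <- toy_params(4, lambda_Abeta = 0.01)
  y02 <- adbc_state(rep(0.01, 4), rep(0, 4), rep(0, 4), 0)
  l1000 <- adbc_loss(p2, y02, recs[recs$biomarker == "Abeta", ], g, w = 1000)
  expect_gte(l1000, 1000 * 0.5)
})

test_that("homogenized stage recovers noiseless homogeneous dynamics", {
  # amyloid-only subject generated from known homogeneous parameters
  n <- 8
  set.seed(3)
  g <- toy_graph(n, seed = 3, density = 0.5)
  lam <- 0.18
  K <- 1.15
  y0v <- 0.07
  p <- adbc_params(n_regions = n, lambda_Abeta = lam, K_Abeta = K)
  st <- adbc_state(rep(y0v, n), rep(0, n), rep(0, n), 0)
  tr <- adbc_simulate(p, st, g, t_eval = seq(50, 100, 1))
  recs <- records_from_trajectory(tr, c(58, 66, 74, 85, 93), "Abeta")
  ctl <- adbc_control(seed = 42, holdout = "none")
  fit <- adbc_fit(recs, g, control = ctl, stages = 1)
  expect_lt(abs(coef(fit)$lambda_Abeta[1] - lam) / lam, 0.01)
  expect_lt(abs(coef(fit)$K_Abeta[1] - K) / K, 0.01)
  expect_lt(abs(fit$y0$Abeta[1] - y0v) / y0v, 0.05)
  # bounds respected
  expect_true(all(coef(fit)$lambda_Abeta >= 0 & coef(fit)$lambda_Abeta <= 2))
  expect_true(all(coef(fit)$K_Abeta >= 1 & coef(fit)$K_Abeta <= 2))
  # downstream equations without data are reported as skipped
  expect_match(fit$status["tau"], "skipped")
  expect_match(fit$status["C"], "skipped")
})

test_that("noisy homogenized recovery stays within 10%", {
  # median over replicate noise draws, so a single unlucky draw does not
  # decide the outcome
  n <- 8
  set.seed(17)
  g <- toy_graph(n, seed = 17, density = 0.5)
  lam <- 0.15
  K <- 1.2
  p <- adbc_params(n_regions = n, lambda_Abeta = lam, K_Abeta = K)
  st <- adbc_state(rep(0.08, n), rep(0, n), rep(0, n), 0)
  tr <- adbc_simulate(p, st, g, t_eval = seq(50, 100, 1))
  clean <- records_from_trajectory(tr, c(57, 64, 71, 79, 88, 94), "Abeta")
  errs <- vapply(1:3, function(r) {
    recs <- clean
    recs$value <- pmax(0, recs$value + rnorm(nrow(recs), 0, 0.02))
    fit <- adbc_fit(recs, g,
                    control = adbc_control(seed = 7, holdout = "none"),
                    stages = 1)
    c(abs(coef(fit)$lambda_Abeta[1] - lam) / lam,
      abs(coef(fit)$K_Abeta[1] - K) / K)
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.10)
  expect_lt(median(errs[2, ]), 0.10)
})

test_that("regional stage shrinks deviations to zero on homogeneous data", {
  n <- 6
  g <- toy_graph(n, seed = 5, density = 0.6)
  p <- adbc_params(n_regions = n, lambda_Abeta = 0.16, K_Abeta = 1.1)
  st <- adbc_state(rep(0.06, n), rep(0, n), rep(0, n), 0)
  tr <- adbc_simulate(p, st, g, t_eval = seq(50, 100, 1))
  recs <- records_from_trajectory(tr, c(60, 70, 80, 90), "Abeta")
  # a single large homotopy weight keeps the L1 term dominant
  ctl <- adbc_control(seed = 2, holdout = "none", homotopy_stages = 1,
                      w_reg = 1)
  fit <- adbc_fit(recs, g, control = ctl, stages = 1:2)
  eps <- unlist(fit$epsilons$Abeta)
  expect_lt(sum(abs(eps)), 1e-3)
})

test_that("regional stage localizes a single perturbed region", {
  n <- 6
  g <- toy_graph(n, seed = 6, density = 0.7)
  lam <- rep(0.15, n)
  lam[3] <- 0.30  # one region progresses twice as fast
  p <- adbc_params(n_regions = n, lambda_Abeta = lam, K_Abeta = 1.1)
  st <- adbc_state(rep(0.06, n), rep(0, n), rep(0, n), 0)
  tr <- adbc_simulate(p, st, g, t_eval = seq(50, 100, 1))
  recs <- records_from_trajectory(tr, c(58, 65, 72, 80, 88), "Abeta")
  ctl <- adbc_control(seed = 3, holdout = "none")
  fit <- adbc_fit(recs, g, control = ctl, stages = 1:2)
  eps_lam <- fit$epsilons$Abeta$lambda_Abeta
  expect_equal(which.max(abs(eps_lam)), 3)
  expect_gt(eps_lam[3], 0)
  # stage-2 final loss does not exceed the stage-1 warm start's
  h2 <- fit$stage_losses$Abeta_stage2
  expect_true(all(diff(h2) <= 1e-8))
})

test_that("initial-condition stage only improves the data fit", {
  n <- 6
  set.seed(9)
  g <- toy_graph(n, seed = 9, density = 0.7)
  y0r <- runif(n, 0.03, 0.15)  # heterogeneous true initial state
  p <- adbc_params(n_regions = n, lambda_Abeta = 0.15, K_Abeta = 1.1)
  st <- adbc_state(y0r, rep(0, n), rep(0, n), 0)
  tr <- adbc_simulate(p, st, g, t_eval = seq(50, 100, 1))
  recs <- records_from_trajectory(tr, c(58, 66, 75, 84, 92), "Abeta")
  ctl <- adbc_control(seed = 4, holdout = "none")
  f2 <- adbc_fit(recs, g, control = ctl, stages = 1:2)
  f3 <- adbc_fit(recs, g, control = ctl, stages = 1:3)
  l2 <- adbc_loss(f2$params, f2$y0, recs, g, w = 0)
  l3 <- adbc_loss(f3$params, f3$y0, recs, g, w = 0)
  expect_lte(l3, l2 + 1e-8)
  # learned initial conditions move toward the heterogeneous truth
  expect_lt(mean(abs(f3$y0$Abeta - y0r)), mean(abs(f2$y0$Abeta - y0r)) + 1e-8)
})

test_that("connectivity stage returns a feasible, audited perturbation", {
  spec <- cohort_spec(n_subjects = 1, n_regions = 6, sigma = 0,
                      pert_nonzero = 0, seed = 12, visits_min = 4,
                      visits_max = 4)
  co <- synth_cohort(spec)
  s <- co$subjects[[1]]
  ctl <- adbc_control(seed = 5, holdout = "none", maxit_homotopy = 30)
  fit <- adbc_fit(s$records, co$population, control = ctl, stages = 1:4)
  expect_s3_class(fit$pert, "low_rank_perturbation")
  expect_equal(nrow(check_weight_constraints(co$population, fit$pert,
                                             tol = 1e-6)), 0)
  # truth has no perturbation: few edge weights should move appreciably
  dA <- abs(patient_adjacency(co$population, fit$pert) -
            co$population$adjacency)
  expect_lt(mean(dA[upper.tri(dA)] > 0.01), 0.3)
})

test_that("identical seed, config and data reproduce the fit exactly", {
  n <- 5
  g <- toy_graph(n, seed = 8, density = 0.8)
  p <- adbc_params(n_regions = n, lambda_Abeta = 0.17, K_Abeta = 1.12)
  st <- adbc_state(rep(0.07, n), rep(0, n), rep(0, n), 0)
  tr <- adbc_simulate(p, st, g, t_eval = seq(50, 100, 1))
  recs <- records_from_trajectory(tr, c(60, 70, 82, 90), "Abeta")
  recs$value <- pmax(0, recs$value + rnorm(nrow(recs), 0, 0.02))
  ctl <- adbc_control(seed = 77, maxit_screen = 20, maxit_stage = 40,
                      maxit_homotopy = 20)
  f1 <- adbc_fit(recs, g, control = ctl, stages = 1:2)
  f2 <- adbc_fit(recs, g, control = ctl, stages = 1:2)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$y0, f2$y0)
  expect_identical(f1$stage_losses, f2$stage_losses)
})

test_that("subjects below the inclusion criterion are rejected", {
  recs <- data.frame(subject_id = "S1", age = c(60, 70),
                     biomarker = "Abeta", region = c(1L, 1L),
                     value = c(0.2, 0.4))
  g <- toy_graph(1)
  expect_error(adbc_fit(recs, g), "inclusion")
})

test_that("fitted models expose the standard S3 interface", {
  n <- 5
  g <- toy_graph(n, seed = 15, density = 0.8)
  p <- adbc_params(n_regions = n, lambda_Abeta = 0.18, K_Abeta = 1.1)
  st <- adbc_state(rep(0.07, n), rep(0, n), rep(0, n), 0)
  tr <- adbc_simulate(p, st, g, t_eval = seq(50, 100, 1))
  recs <- records_from_trajectory(tr, c(60, 68, 77, 85, 92), "Abeta")
  fit <- adbc_fit(recs, g, control = adbc_control(seed = 1), stages = 1)

  expect_s3_class(coef(fit), "adbc_params")
  expect_output(print(fit), "Fitted biomarker cascade")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.adbc_fit")
  expect_output(print(sm), "Global parameters")

  pr <- predict(fit, newdata = recs)
  expect_length(pr, nrow(recs))
  expect_lt(max(abs(pr - recs$value)), 0.05)

  res <- residuals(fit, which = "all")
  expect_equal(res$residual, res$value - res$fitted)

  sims <- simulate(fit, nsim = 2, seed = 3, sigma = 0.01)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$value, sims[[2]]$value))
  expect_true(all(sims[[1]]$value >= 0))

  tab <- predict(fit, ages = c(60, 80))
  expect_setequal(unique(tab$age), c(60, 80))

  pf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(pf)
  expect_silent(plot(fit))
  grDevices::dev.off()
})
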