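#' @export
print.adbc_params <- function(x, ...) {
  nm <- adbc_parameter_names()
  cat("Biomarker cascade parameters (", x$n_regions, " regions)\n", sep = "")
  cat("Global scalars:\n")
  for (p in nm$global) cat(sprintf("  %-16s %.4g\n", p, x[[p]]))
  cat("Region-specific vectors (mean [min, max]):\n")
  for (p in nm$regional) {
    v <- x[[p]]
    cat(sprintf("  %-16s %.4g [%.4g, %.4g]\n", p, mean(v), min(v), max(v)))
  }
  invisible(x)
}

#' @export
print.brain_graph <- function(x, ...) {
  ne <- sum(x$adjacency > 0) / 2
  cat("Brain graph: ", x$n, " regions, ", ne, " edges, mean degree ",
      signif(mean(x$degree), 4), "\n", sep = "")
  invisible(x)
}

#' @export
print.adbc_fit <- function(x, ...) {
  cat("Fitted biomarker cascade model (subject ", x$subject_id, ")\n",
      sep = "")
  cat("Stages run:", paste(x$stages, collapse = ", "), "\n")
  for (b in names(x$status)) {
    cat(sprintf("  %-6s %s\n", b, x$status[b]))
  }
  if (!is.null(x$train_accuracy)) {
    cat("Training accuracy (%):\n")
    print(round(x$train_accuracy, 2))
  }
  if (!is.null(x$test_accuracy)) {
    cat("Held-out accuracy (%):\n")
    print(round(x$test_accuracy, 2))
  }
  invisible(x)
}

#' Summarize a fitted cascade model
#'
#' @param object An [adbc_fit()].
#' @param ... Unused.
#' @return A list of class `summary.adbc_fit` with global parameters,
#'   regional parameter ranges, accuracies, stage loss trajectories and the
#'   perturbation norms (if stage 4 ran).
#' @export
summary.adbc_fit <- function(object, ...) {
  nm <- adbc_parameter_names()
  glob <- vapply(nm$global, function(p) object$params[[p]], numeric(1))
  reg <- t(vapply(nm$regional, function(p) {
    v <- object$params[[p]]
    c(mean = mean(v), min = min(v), max = max(v))
  }, numeric(3)))
  out <- list(subject_id = object$subject_id, global = glob, regional = reg,
              train_accuracy = object$train_accuracy,
              test_accuracy = object$test_accuracy,
              final_losses = vapply(
                Filter(length, object$stage_losses),
                function(h) h[length(h)], numeric(1)),
              pert_norms = if (!is.null(object$pert)) {
                c(u = sqrt(sum(object$pert$u^2)),
                  v = sqrt(sum(object$pert$v^2)))
              } else NULL,
              status = object$status)
  class(out) <- "summary.adbc_fit"
  out
}

#' @export
print.summary.adbc_fit <- function(x, ...) {
  cat("Subject:", x$subject_id, "\n\nGlobal parameters:\n")
  print(signif(x$global, 4))
  cat("\nRegional parameters (mean/min/max):\n")
  print(signif(x$regional, 4))
  if (!is.null(x$train_accuracy)) {
    cat("\nTraining accuracy (%):\n")
    print(round(x$train_accuracy, 2))
  }
  if (!is.null(x$test_accuracy)) {
    cat("Held-out accuracy (%):\n")
    print(round(x$test_accuracy, 2))
  }
  if (!is.null(x$pert_norms)) {
    cat("\nConnectivity perturbation norms: ||u|| =",
        signif(x$pert_norms["u"], 4), ", ||v|| =",
        signif(x$pert_norms["v"], 4), "\n")
  }
  invisible(x)
}

#' Extract fitted parameters
#'
#' @param object An [adbc_fit()].
#' @param ... Unused.
#' @return The fitted [adbc_params()].
#' @export
coef.adbc_fit <- function(object, ...) object$params

#' Predict biomarker values at given ages
#'
#' Re-evaluates the fitted trajectory. With `newdata` a records-style data
#' frame (columns `age`, `biomarker`, `region`), returns predictions aligned
#' with its rows; otherwise returns the tidy trajectory table at `ages`.
#'
#' @param object An [adbc_fit()].
#' @param newdata Optional data frame with `age`, `biomarker`, `region`.
#' @param ages Evaluation ages used when `newdata` is NULL.
#' @param ... Unused.
#' @return Numeric vector (with `newdata`) or a tidy data frame.
#' @export
predict.adbc_fit <- function(object, newdata = NULL, ages = NULL, ...) {
  ctl <- object$control
  if (is.null(newdata)) {
    if (is.null(ages)) ages <- seq(ctl$t0, ctl$t_end, by = 1)
    traj <- adbc_simulate(object$params, object$y0, object$graph,
                          t0 = ctl$t0, t_end = max(ctl$t_end, max(ages)),
                          t_eval = ages, rtol = ctl$rtol, atol = ctl$atol)
    return(trajectory_to_table(traj))
  }
  traj <- adbc_simulate(object$params, object$y0, object$graph,
                        t0 = ctl$t0,
                        t_end = max(ctl$t_end, max(newdata$age)),
                        t_eval = sort(unique(newdata$age)),
                        rtol = ctl$rtol, atol = ctl$atol)
  vapply(seq_len(nrow(newdata)), function(i) {
    b <- newdata$biomarker[i]
    v <- trajectory_at(traj, b, newdata$age[i])
    if (b == "C") v[1] else v[newdata$region[i], 1]
  }, numeric(1))
}

#' Residuals of a fitted cascade model
#'
#' Observed minus fitted values at the training (or all) visits.
#'
#' @param object An [adbc_fit()].
#' @param which `"train"` (default), `"test"` or `"all"`.
#' @param ... Unused.
#' @return The records data frame with extra columns `fitted` and `residual`.
#' @export
residuals.adbc_fit <- function(object, which = c("train", "test", "all"),
                               ...) {
  which <- match.arg(which)
  rec <- switch(which, train = object$train_records,
                test = object$test_records, all = object$records)
  if (nrow(rec) == 0) {
    rec$fitted <- numeric(0)
    rec$residual <- numeric(0)
    return(rec)
  }
  rec$fitted <- predict(object, newdata = rec)
  rec$residual <- rec$value - rec$fitted
  rec
}

#' Simulate new observations from a fitted cascade model
#'
#' Draws observation sets at the fitted subject's visit ages by adding
#' Gaussian noise to the fitted trajectory (values clipped at 0).
#'
#' @param object An [adbc_fit()].
#' @param nsim Number of simulated replicates.
#' @param seed Optional seed.
#' @param sigma Observation noise standard deviation.
#' @param ... Unused.
#' @return A list of `nsim` records data frames.
#' @export
simulate.adbc_fit <- function(object, nsim = 1, seed = NULL, sigma = 0.02,
                              ...) {
  if (!is.null(seed)) set.seed(seed)
  base <- object$records
  mu <- predict(object, newdata = base)
  lapply(seq_len(nsim), function(i) {
    out <- base
    out$value <- pmax(0, mu + rnorm(length(mu), 0, sigma))
    out
  })
}

#' Plot a fitted cascade model against its data
#'
#' One panel per biomarker: fitted regional trajectories (grey), their mean
#' (black), training observations (filled) and held-out observations (open).
#'
#' @param x An [adbc_fit()].
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.adbc_fit <- function(x, ...) {
  traj <- x$trajectory
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (b in c("Abeta", "tau", "N", "C")) {
    if (b == "C") {
      ymat <- matrix(traj$C, ncol = 1)
    } else {
      ymat <- t(traj[[b]])
    }
    graphics::matplot(traj$ages, ymat, type = "l", lty = 1,
                      col = grDevices::grey(0.7), xlab = "age (years)",
                      ylab = b, main = b, ...)
    graphics::lines(traj$ages, rowMeans(ymat), lwd = 2)
    tr <- x$train_records[x$train_records$biomarker == b, ]
    te <- x$test_records[x$test_records$biomarker == b, ]
    if (nrow(tr)) graphics::points(tr$age, tr$value, pch = 16, cex = 0.6)
    if (nrow(te)) graphics::points(te$age, te$value, pch = 1, cex = 0.8)
  }
  invisible(x)
}

#' @export
print.adbc_trajectory <- function(x, ...) {
  cat("Cascade trajectory: ", nrow(x$Abeta), " regions, ages ",
      min(x$ages), "-", max(x$ages), " (", length(x$ages), " points)\n",
      sep = "")
  invisible(x)
}
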