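# first k primes (Halton bases)
first_primes <- function(k) {
  out <- integer(0)
  x <- 2L
  while (length(out) < k) {
    if (x == 2L || all(x %% out[out <= sqrt(x)] != 0)) out <- c(out, x)
    x <- x + 1L
  }
  out
}

# digit-scrambled Halton sequence: radical-inverse points with one random
# digit permutation per base. Low-discrepancy sampling makes the Saltelli
# estimators converge far faster than plain Monte Carlo at the same N.
halton_scrambled <- function(n, d, seed) {
  pr <- first_primes(d)
  set.seed(seed)
  out <- matrix(0, n, d)
  idx <- seq_len(n)
  for (j in seq_len(d)) {
    b <- pr[j]
    L <- ceiling(log(n + 1) / log(b))
    perm <- sample.int(b) - 1L
    x <- numeric(n)
    f <- 1 / b
    i <- idx
    for (l in seq_len(L)) {
      x <- x + perm[i %% b + 1L] * f
      i <- i %/% b
      f <- f / b
    }
    out[, j] <- x
  }
  out
}

#' Variance-based (Sobol) sensitivity indices
#'
#' Saltelli-scheme Monte Carlo estimation of first-order (S1), optionally
#' second-order (S2), and total (ST) sensitivity indices of a scalar model
#' output with respect to independent uniformly distributed factors.
#' S1 measures the variance share explained by one factor alone, S2 the
#' additional share of a pair beyond its two main effects, and ST the share
#' including all interactions of any order.
#'
#' Estimators (all in centered covariance form, which has uniformly lower
#' error than the textbook mean-of-products forms under the quasi-random
#' design used here): S1 by `cov(fB, fAB_i) / V`, ST by Jansen's
#' `mean((fA - fAB_i)^2) / (2 V)`, and S2 from the cross blocks as
#' `cov(fBA_i, fAB_j) / V - S1_i - S1_j`. Sampling uses a digit-scrambled
#' Halton (low-discrepancy) design. Cost is `N (k + 2)` model evaluations,
#' or `N (2k + 2)` when second-order blocks are sampled. Confidence
#' half-widths are bootstrap percentiles over sample rows.
#'
#' @param model Function taking a numeric matrix (rows = parameter vectors)
#'   and returning a numeric vector of outputs, or taking a single numeric
#'   vector and returning a scalar (it is then applied row-wise).
#' @param ranges Named list of 2-vectors `c(lower, upper)`, one per factor.
#'   Degenerate ranges (`lower == upper`) are held fixed and get zero
#'   indices.
#' @param n_base Base sample size N (a power of 2 is customary; default
#'   1024).
#' @param second_order Sample the extra blocks needed for S2? Default FALSE.
#' @param seed Integer seed for the sampling.
#' @param n_boot Bootstrap resamples for confidence half-widths (default
#'   200; 0 disables).
#' @param conf Confidence level for the half-widths.
#' @return Object of class `sobol_result`: list with `S1`, `ST` (named
#'   vectors), `S2` (matrix or NULL), `S1_conf`, `ST_conf`, `variance`,
#'   `n_base`, `n_eval`.
#' @export
sobol_indices <- function(model, ranges, n_base = 1024,
                          second_order = FALSE, seed = 1, n_boot = 200,
                          conf = 0.95) {
  k <- length(ranges)
  stopifnot(k >= 1, !is.null(names(ranges)))
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  if (any(hi < lo)) stop("each range must satisfy lower <= upper")
  N <- n_base
  scale_mat <- function(U) sweep(sweep(U, 2, hi - lo, "*"), 2, lo, "+")
  U <- halton_scrambled(N, 2 * k, seed)
  A <- scale_mat(U[, seq_len(k), drop = FALSE])
  B <- scale_mat(U[, k + seq_len(k), drop = FALSE])
  set.seed(seed)  # bootstrap resampling reproducibility

  evalf <- function(M) {
    out <- tryCatch(model(M), error = function(e) NULL)
    if (is.null(out) || length(out) != nrow(M)) {
      out <- vapply(seq_len(nrow(M)), function(i) model(M[i, ]), numeric(1))
    }
    if (any(!is.finite(out))) {
      stop("non-finite model output at sample row ",
           which(!is.finite(out))[1])
    }
    out
  }

  fA <- evalf(A)
  fB <- evalf(B)
  fAB <- matrix(0, N, k)
  fBA <- if (second_order) matrix(0, N, k) else NULL
  for (i in seq_len(k)) {
    ABi <- A
    ABi[, i] <- B[, i]
    fAB[, i] <- evalf(ABi)
    if (second_order) {
      BAi <- B
      BAi[, i] <- A[, i]
      fBA[, i] <- evalf(BAi)
    }
  }

  est <- function(rows) {
    fa <- fA[rows]; fb <- fB[rows]
    V <- var(c(fa, fb))
    if (!is.finite(V) || V <= 1e-14) {
      return(list(S1 = rep(0, k), ST = rep(0, k),
                  S2 = if (second_order) matrix(0, k, k) else NULL,
                  V = 0))
    }
    # centered covariance form of the first-order estimator: uniformly
    # lower error than the difference form under the quasi-random design
    S1 <- vapply(seq_len(k), function(i) {
      cov(fb, fAB[rows, i]) / V
    }, numeric(1))
    ST <- vapply(seq_len(k), function(i) {
      mean((fa - fAB[rows, i])^2) / (2 * V)
    }, numeric(1))
    S2 <- NULL
    if (second_order) {
      # centered covariance form: cov(f(BA_i), f(AB_j)) estimates the
      # closed second-order variance Var(E[Y | X_i, X_j]) through the two
      # shared coordinates, and centering cancels mean-level sampling error
      S2 <- matrix(NA_real_, k, k)
      for (i in seq_len(k - 1)) {
        for (j in (i + 1):k) {
          Vij <- cov(fBA[rows, i], fAB[rows, j]) / V
          S2[i, j] <- S2[j, i] <- Vij - S1[i] - S1[j]
        }
      }
    }
    list(S1 = S1, ST = ST, S2 = S2, V = V)
  }

  full <- est(seq_len(N))
  degenerate <- hi - lo <= 0
  full$S1[degenerate] <- 0
  full$ST[degenerate] <- 0
  if (full$V == 0) {
    warning("model output variance is (near) zero; all indices set to 0")
  }

  S1_conf <- ST_conf <- rep(NA_real_, k)
  if (n_boot > 0 && full$V > 0) {
    bs1 <- matrix(0, n_boot, k)
    bst <- matrix(0, n_boot, k)
    for (r in seq_len(n_boot)) {
      rows <- sample.int(N, N, replace = TRUE)
      e <- est(rows)
      bs1[r, ] <- e$S1
      bst[r, ] <- e$ST
    }
    z <- (1 + conf) / 2
    S1_conf <- apply(bs1, 2, function(v) diff(quantile(v, c(1 - z, z))) / 2)
    ST_conf <- apply(bst, 2, function(v) diff(quantile(v, c(1 - z, z))) / 2)
  }

  structure(list(
    S1 = setNames(full$S1, names(ranges)),
    ST = setNames(full$ST, names(ranges)),
    S2 = if (second_order) {
      dimnames(full$S2) <- list(names(ranges), names(ranges))
      full$S2
    } else NULL,
    S1_conf = setNames(S1_conf, names(ranges)),
    ST_conf = setNames(ST_conf, names(ranges)),
    variance = full$V, n_base = N,
    n_eval = N * (k + 2 + if (second_order) k else 0)),
    class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, ...) {
  cat("Sobol sensitivity indices (N =", x$n_base, ",", x$n_eval,
      "model evaluations)\n")
  tab <- data.frame(S1 = round(x$S1, 4), ST = round(x$ST, 4))
  print(tab)
  invisible(x)
}

# default boxes for the 14 homogenized parameters used by level-1 screening
default_level1_ranges <- function() {
  list(D_Abeta = c(0, 0.2), D_tau = c(0, 0.2), D_N = c(0, 0.2),
       lambda_CN = c(0, 0.1), lambda_C = c(0.02, 0.3), K_C = c(1, 1.5),
       lambda_Abeta = c(0.02, 0.3), lambda_tau = c(0.02, 0.3),
       lambda_N = c(0.02, 0.3), lambda_tauAbeta = c(0, 0.1),
       lambda_Ntau = c(0, 0.1), K_Abeta = c(1, 1.5), K_tau = c(1, 1.5),
       K_N = c(1, 1.5))
}

#' Level-1 sensitivity screening of the 14 homogenized parameters
#'
#' Assumes region-homogeneous parameters, varies all 14 within the given
#' boxes, and computes total sensitivity indices of the cognitive-impairment
#' output C(t) at each evaluation age. The age-aggregated ST ranking is the
#' screening device for selecting the handful of influential parameters.
#'
#' @param graph A [brain_graph()].
#' @param ranges Named list of 14 boxes (names as in [adbc_params()]);
#'   defaults span a plausible progression regime.
#' @param ages Evaluation ages; default `c(60, 70, 80, 90, 100)`.
#' @param y0 Initial [adbc_state()] at age `t0`; default a mild uniform
#'   seed (`Abeta = 0.1, tau = 0.05, N = 0.05, C = 0.02`).
#' @param n_base Base sample size; default 1024.
#' @param seed Integer seed.
#' @param t0 Initial age.
#' @return List with `ages`, matrix `ST` (parameters x ages), matrix `S1`,
#'   `ranking` (parameters ordered by age-aggregated ST), and
#'   `zero_variance` (logical per age, flagging near-constant outputs).
#' @export
sobol_level1 <- function(graph, ranges = default_level1_ranges(),
                         ages = c(60, 70, 80, 90, 100), y0 = NULL,
                         n_base = 1024, seed = 1, t0 = 50) {
  stopifnot(length(ranges) == 14)
  n <- graph$n
  if (is.null(y0)) {
    y0 <- adbc_state(rep(0.1, n), rep(0.05, n), rep(0.05, n), 0.02)
  }
  yv <- state_to_vec(y0)
  L <- graph$laplacian
  ages <- sort(ages)
  crow <- 3 * n + 1

  model_multi <- function(M) {
    m <- apply(M, 1, function(x) {
      P <- list(D_Abeta = x[1], D_tau = x[2], D_N = x[3], lambda_CN = x[4],
                lambda_C = x[5], K_C = x[6],
                lambda_Abeta = rep(x[7], n), lambda_tau = rep(x[8], n),
                lambda_N = rep(x[9], n), lambda_tauAbeta = rep(x[10], n),
                lambda_Ntau = rep(x[11], n), K_Abeta = rep(x[12], n),
                K_tau = rep(x[13], n), K_N = rep(x[14], n))
      out <- integrate_quiet(ages, t0, yv, L, P, 1e-6, 1e-8)
      if (is.null(out)) rep(NA_real_, length(ages)) else out[crow, ]
    })
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    t(m)
  }

  # order the sampled columns as the ranges list
  ord <- c("D_Abeta", "D_tau", "D_N", "lambda_CN", "lambda_C", "K_C",
           "lambda_Abeta", "lambda_tau", "lambda_N", "lambda_tauAbeta",
           "lambda_Ntau", "K_Abeta", "K_tau", "K_N")
  ranges <- ranges[ord]

  # one shared Saltelli sample across ages: evaluate the multi-output model
  # once per sample row and form per-age indices
  k <- 14
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  N <- n_base
  scale_mat <- function(U) sweep(sweep(U, 2, hi - lo, "*"), 2, lo, "+")
  U <- halton_scrambled(N, 2 * k, seed)
  A <- scale_mat(U[, seq_len(k), drop = FALSE])
  B <- scale_mat(U[, k + seq_len(k), drop = FALSE])
  fA <- model_multi(A)
  fB <- model_multi(B)
  if (any(!is.finite(fA)) || any(!is.finite(fB))) {
    stop("non-finite model output in level-1 screening sample")
  }
  ST <- S1 <- matrix(0, k, length(ages),
                     dimnames = list(ord, paste0("age", ages)))
  zero_var <- logical(length(ages))
  fABs <- vector("list", k)
  for (i in seq_len(k)) {
    ABi <- A
    ABi[, i] <- B[, i]
    fABs[[i]] <- model_multi(ABi)
  }
  for (a in seq_along(ages)) {
    V <- var(c(fA[, a], fB[, a]))
    if (!is.finite(V) || V <= 1e-12) {
      zero_var[a] <- TRUE
      next
    }
    for (i in seq_len(k)) {
      S1[i, a] <- cov(fB[, a], fABs[[i]][, a]) / V
      ST[i, a] <- mean((fA[, a] - fABs[[i]][, a])^2) / (2 * V)
    }
  }
  degenerate <- hi - lo <= 0
  S1[degenerate, ] <- 0
  ST[degenerate, ] <- 0
  agg <- rowMeans(ST)
  list(ages = ages, ST = ST, S1 = S1,
       ranking = names(sort(agg, decreasing = TRUE)),
       zero_variance = zero_var)
}

#' Level-2 regional sensitivity analysis of one parameter
#'
#' Varies a single region-specific parameter across all regions (one factor
#' per region) with every other model parameter fixed, and computes per-
#' region S1 and pairwise S2 of the degree-weighted brain total of the
#' parameter's own biomarker at each stage age. Indices are aggregated to
#' anatomical lobes by summation: lobe S1 is the sum of member-region S1,
#' and the lobe-pair interaction matrix sums S2 over member pairs
#' (diagonal = intra-lobe interactions).
#'
#' @param param_name One of the 8 region-specific parameter names.
#' @param graph A [brain_graph()].
#' @param region_ranges Matrix or list of per-region `c(lower, upper)`
#'   boxes (e.g. min/max of fitted values across subjects).
#' @param lobe_map Character vector: lobe of each region (see
#'   [dk68_lobe_map()]).
#' @param fixed_params An [adbc_params()] holding all non-varied parameters
#'   (typically cohort means of fitted values).
#' @param y0 Initial [adbc_state()] (typically the cohort mean state at the
#'   initial age).
#' @param stages Stage ages; default `c(60, 80, 100)`.
#' @param n_base Base sample size.
#' @param seed Integer seed.
#' @param t0 Initial age.
#' @return List per stage age: `S1` (per region), `S2` (region matrix),
#'   `lobe_S1`, `lobe_S2`, `variance`.
#' @export
sobol_level2 <- function(param_name, graph, region_ranges, lobe_map,
                         fixed_params, y0, stages = c(60, 80, 100),
                         n_base = 256, seed = 1, t0 = 50) {
  n <- graph$n
  stopifnot(param_name %in% adbc_parameter_names()$regional)
  if (is.list(region_ranges)) {
    region_ranges <- do.call(rbind, region_ranges)
  }
  stopifnot(nrow(region_ranges) == n, ncol(region_ranges) == 2)
  if (length(lobe_map) != n) {
    stop("lobe map must assign a lobe to each of the ", n, " regions")
  }
  biomarker <- if (param_name %in% c("lambda_Abeta", "K_Abeta")) "Abeta"
    else if (param_name %in% c("lambda_tau", "K_tau", "lambda_tauAbeta")) "tau"
    else "N"
  rows <- eq_rows(biomarker, n)
  yv <- state_to_vec(y0)
  L <- graph$laplacian
  P0 <- unclass(fixed_params)
  deg <- graph$degree
  dsum <- sum(deg)
  stages <- sort(stages)

  model_multi <- function(M) {
    m <- apply(M, 1, function(x) {
      P <- P0
      P[[param_name]] <- x
      out <- integrate_quiet(stages, t0, yv, L, P, 1e-6, 1e-8)
      if (is.null(out)) return(rep(NA_real_, length(stages)))
      apply(out[rows, , drop = FALSE], 2,
            function(f) if (dsum > 0) sum(deg * f) / dsum else mean(f))
    })
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    t(m)
  }

  lo <- region_ranges[, 1]
  hi <- region_ranges[, 2]
  N <- n_base
  scale_mat <- function(U) sweep(sweep(U, 2, hi - lo, "*"), 2, lo, "+")
  U <- halton_scrambled(N, 2 * n, seed)
  A <- scale_mat(U[, seq_len(n), drop = FALSE])
  B <- scale_mat(U[, n + seq_len(n), drop = FALSE])
  fA <- model_multi(A)
  fB <- model_multi(B)
  fAB <- fBA <- vector("list", n)
  for (i in seq_len(n)) {
    ABi <- A; ABi[, i] <- B[, i]
    BAi <- B; BAi[, i] <- A[, i]
    fAB[[i]] <- model_multi(ABi)
    fBA[[i]] <- model_multi(BAi)
  }

  lobes <- sort(unique(lobe_map))
  res <- list()
  for (s in seq_along(stages)) {
    V <- var(c(fA[, s], fB[, s]))
    S1 <- rep(0, n)
    S2 <- matrix(0, n, n)
    if (is.finite(V) && V > 1e-14) {
      for (i in seq_len(n)) {
        S1[i] <- cov(fB[, s], fAB[[i]][, s]) / V
      }
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          Vij <- cov(fBA[[i]][, s], fAB[[j]][, s]) / V
          S2[i, j] <- S2[j, i] <- Vij - S1[i] - S1[j]
        }
      }
    }
    deg_range <- hi - lo <= 0
    S1[deg_range] <- 0
    S2[deg_range, ] <- 0
    S2[, deg_range] <- 0
    lobe_S1 <- vapply(lobes, function(l) sum(S1[lobe_map == l]), numeric(1))
    lobe_S2 <- matrix(0, length(lobes), length(lobes),
                      dimnames = list(lobes, lobes))
    for (a in seq_along(lobes)) {
      for (b in seq_along(lobes)) {
        ia <- which(lobe_map == lobes[a])
        ib <- which(lobe_map == lobes[b])
        sub <- S2[ia, ib, drop = FALSE]
        if (a == b) {
          lobe_S2[a, b] <- sum(sub[upper.tri(sub)])
        } else if (a < b) {
          lobe_S2[a, b] <- lobe_S2[b, a] <- sum(sub)
        }
      }
    }
    res[[paste0("age", stages[s])]] <-
      list(age = stages[s], S1 = S1, S2 = S2,
           lobe_S1 = setNames(lobe_S1, lobes), lobe_S2 = lobe_S2,
           variance = V)
  }
  res
}

#' Rank regions by sensitivity
#'
#' Orders regions by first-order index (ties broken by total index, then by
#' region index) and reports the top k with their lobes and per-lobe counts.
#'
#' @param S1 Numeric vector of per-region first-order indices.
#' @param ST Optional per-region total indices used for tie-breaking.
#' @param lobe_map Optional character vector of lobe labels per region.
#' @param k Number of regions to report (clipped to the number available,
#'   with a warning).
#' @return List with `regions` (data frame: region, S1, ST, lobe) and
#'   `lobe_counts`.
#' @export
rank_regions <- function(S1, ST = NULL, lobe_map = NULL, k = 10) {
  n <- length(S1)
  if (k > n) {
    warning("k exceeds number of regions; clipping to ", n)
    k <- n
  }
  if (is.null(ST)) ST <- rep(0, n)
  ord <- order(-S1, -ST, seq_len(n))
  top <- ord[seq_len(k)]
  regions <- data.frame(region = top, S1 = S1[top], ST = ST[top],
                        lobe = if (!is.null(lobe_map)) lobe_map[top]
                               else NA_character_,
                        stringsAsFactors = FALSE)
  counts <- if (!is.null(lobe_map)) table(regions$lobe) else NULL
  list(regions = regions, lobe_counts = counts)
}

#' Standard lobe assignment for the 68-region cortical parcellation
#'
#' Maps each Desikan-Killiany region (34 per hemisphere, left 1-34 then
#' right 35-68, alphabetical within hemisphere) to one of six anatomical
#' lobes: frontal, temporal, parietal, occipital, limbic (cingulate) or
#' insular. Read from the YAML shipped with the package; user-overridable
#' via the `path` argument.
#'
#' @param path Optional path to a YAML file mapping region index to lobe.
#' @return Character vector of length 68 (or the file's length) of lobe
#'   labels, named by region label.
#' @export
dk68_lobe_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dk68_lobes.yaml", package = "adbcascade")
  }
  y <- yaml::read_yaml(path)
  setNames(vapply(y$regions, `[[`, character(1), "lobe"),
           vapply(y$regions, `[[`, character(1), "label"))
}
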