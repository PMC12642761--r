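#' Parameters of the generalized biomarker cascade model
#'
#' The model has exactly 14 named parameters: 6 global scalars — the three
#' diffusivities `D_Abeta`, `D_tau`, `D_N` (1/yr per unit Laplacian), the
#' cognition coupling `lambda_CN` (1/yr), the cognition logistic rate
#' `lambda_C` (1/yr) and its carrying capacity `K_C` — and 8 region-specific
#' vectors (length `n_regions`): logistic rates `lambda_Abeta`, `lambda_tau`,
#' `lambda_N`, linear cross-couplings `lambda_tauAbeta` (amyloid driving tau)
#' and `lambda_Ntau` (tau driving neurodegeneration), and carrying capacities
#' `K_Abeta`, `K_tau`, `K_N`. Scalars given for regional parameters are
#' broadcast to all regions.
#'
#' @param n_regions Number of graph regions (default 68, the
#'   Desikan-Killiany cortical parcellation).
#' @param D_Abeta,D_tau,D_N Global diffusivities, `>= 0`.
#' @param lambda_CN,lambda_C,K_C Global cognition parameters; `K_C > 0`.
#' @param lambda_Abeta,lambda_tau,lambda_N Regional logistic rates.
#' @param lambda_tauAbeta,lambda_Ntau Regional linear cross-couplings.
#' @param K_Abeta,K_tau,K_N Regional carrying capacities, `> 0`.
#' @return Object of class `adbc_params`.
#' @export
adbc_params <- function(n_regions = 68,
                        D_Abeta = 0, D_tau = 0, D_N = 0,
                        lambda_CN = 0, lambda_C = 0, K_C = 1,
                        lambda_Abeta = 0, lambda_tau = 0, lambda_N = 0,
                        lambda_tauAbeta = 0, lambda_Ntau = 0,
                        K_Abeta = 1, K_tau = 1, K_N = 1) {
  bc <- function(x, nm) {
    if (length(x) == 1) x <- rep(as.numeric(x), n_regions)
    if (length(x) != n_regions) {
      stop(nm, " must be scalar or length n_regions (", n_regions, ")")
    }
    if (any(!is.finite(x))) stop(nm, " must be finite")
    as.numeric(x)
  }
  sc <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x)) stop(nm, " must be a finite scalar")
    as.numeric(x)
  }
  p <- list(
    D_Abeta = sc(D_Abeta, "D_Abeta"), D_tau = sc(D_tau, "D_tau"),
    D_N = sc(D_N, "D_N"), lambda_CN = sc(lambda_CN, "lambda_CN"),
    lambda_C = sc(lambda_C, "lambda_C"), K_C = sc(K_C, "K_C"),
    lambda_Abeta = bc(lambda_Abeta, "lambda_Abeta"),
    lambda_tau = bc(lambda_tau, "lambda_tau"),
    lambda_N = bc(lambda_N, "lambda_N"),
    lambda_tauAbeta = bc(lambda_tauAbeta, "lambda_tauAbeta"),
    lambda_Ntau = bc(lambda_Ntau, "lambda_Ntau"),
    K_Abeta = bc(K_Abeta, "K_Abeta"), K_tau = bc(K_tau, "K_tau"),
    K_N = bc(K_N, "K_N"))
  if (p$D_Abeta < 0 || p$D_tau < 0 || p$D_N < 0) {
    stop("diffusivities must be nonnegative")
  }
  if (p$K_C <= 0 || any(p$K_Abeta <= 0) || any(p$K_tau <= 0) ||
      any(p$K_N <= 0)) {
    stop("carrying capacities must be positive")
  }
  structure(c(p, list(n_regions = n_regions)), class = "adbc_params")
}

#' Names of the model's global and regional parameters
#'
#' @return List with character vectors `global` (6 names) and `regional`
#'   (8 names).
#' @export
adbc_parameter_names <- function() {
  list(global = c("D_Abeta", "D_tau", "D_N", "lambda_CN", "lambda_C", "K_C"),
       regional = c("lambda_Abeta", "lambda_tau", "lambda_N",
                    "lambda_tauAbeta", "lambda_Ntau",
                    "K_Abeta", "K_tau", "K_N"))
}

#' Model state at one time point
#'
#' @param Abeta,tau,N Regional vectors (amyloid, tau, neurodegeneration).
#' @param C Scalar whole-brain cognitive impairment.
#' @return Object of class `adbc_state`.
#' @export
adbc_state <- function(Abeta, tau, N, C) {
  n <- length(Abeta)
  stopifnot(length(tau) == n, length(N) == n, length(C) == 1,
            all(is.finite(c(Abeta, tau, N, C))))
  structure(list(Abeta = as.numeric(Abeta), tau = as.numeric(tau),
                 N = as.numeric(N), C = as.numeric(C)),
            class = "adbc_state")
}

# flatten/unflatten between adbc_state and the integrator's vector layout
state_to_vec <- function(state) c(state$Abeta, state$tau, state$N, state$C)

vec_to_state <- function(y, n) {
  adbc_state(y[1:n], y[(n + 1):(2 * n)], y[(2 * n + 1):(3 * n)], y[3 * n + 1])
}

#' Time derivative of the cascade model
#'
#' Reference (R-level) implementation of the coupled dynamics on a brain
#' graph, with elementwise products over regions:
#' \deqn{dA\beta/dt = -D_{A\beta} L A\beta + \lambda_{A\beta} A\beta (K_{A\beta} - A\beta)}
#' \deqn{d\tau/dt = -D_\tau L \tau + \lambda_{\tau A\beta} A\beta + \lambda_\tau \tau (K_\tau - \tau)}
#' \deqn{dN/dt = -D_N L N + \lambda_{N\tau} \tau + \lambda_N N (K_N - N)}
#' \deqn{dC/dt = \lambda_{CN} \int_G N \, dv + \lambda_C C (K_C - C)}
#' where the graph integral is the degree-weighted mean
#' (see [graph_integral()]). Upstream biomarkers force downstream ones
#' linearly; each biomarker also grows logistically toward its carrying
#' capacity; the Laplacian term diffuses pathology along functional
#' connections.
#'
#' @param state An [adbc_state()].
#' @param params An [adbc_params()].
#' @param graph A [brain_graph()].
#' @return An `adbc_state` holding the derivative.
#' @export
adbc_rhs <- function(state, params, graph) {
  L <- graph$laplacian
  n <- graph$n
  stopifnot(length(state$Abeta) == n, params$n_regions == n)
  ab <- state$Abeta; ta <- state$tau; nn <- state$N; C <- state$C
  dab <- -params$D_Abeta * as.numeric(L %*% ab) +
    params$lambda_Abeta * ab * (params$K_Abeta - ab)
  dta <- -params$D_tau * as.numeric(L %*% ta) +
    params$lambda_tauAbeta * ab + params$lambda_tau * ta * (params$K_tau - ta)
  dnn <- -params$D_N * as.numeric(L %*% nn) +
    params$lambda_Ntau * ta + params$lambda_N * nn * (params$K_N - nn)
  nint <- if (sum(graph$degree) > 0) graph_integral(nn, graph) else mean(nn)
  dC <- params$lambda_CN * nint + params$lambda_C * C * (params$K_C - C)
  structure(list(Abeta = dab, tau = dta, N = dnn, C = dC),
            class = "adbc_state")
}

#' Simulate the biomarker cascade on a brain graph
#'
#' Integrates the model with an adaptive embedded Runge-Kutta 5(4)
#' (Dormand-Prince) scheme from `t0` (chronological age, years) and returns
#' the state at the requested evaluation ages.
#'
#' @param params An [adbc_params()].
#' @param y0 Initial state at `t0`: an [adbc_state()].
#' @param graph A [brain_graph()].
#' @param t0 Initial age; default 50 (a common disease clock origin).
#' @param t_end Final age; default 100 (the end-stage penalty time used in
#'   fitting).
#' @param t_eval Ages at which to report the state; default yearly grid.
#' @param rtol,atol Relative/absolute integration tolerances.
#' @param max_steps Step-count guard against runaway integrations.
#' @return Object of class `adbc_trajectory`: list with `ages`, matrices
#'   `Abeta`, `tau`, `N` (regions x ages), vector `C`, and `meta` (solver
#'   settings).
#' @export
adbc_simulate <- function(params, y0, graph, t0 = 50, t_end = 100,
                          t_eval = NULL, rtol = 1e-6, atol = 1e-8,
                          max_steps = 100000L) {
  if (t0 >= t_end) stop("t0 must be earlier than t_end")
  if (is.null(t_eval)) t_eval <- seq(t0, t_end, by = 1)
  t_eval <- sort(unique(as.numeric(t_eval)))
  if (any(t_eval < t0 - 1e-9) || any(t_eval > t_end + 1e-9)) {
    stop("t_eval must lie within [t0, t_end]")
  }
  n <- graph$n
  stopifnot(params$n_regions == n, length(y0$Abeta) == n)
  yv <- state_to_vec(y0)
  out <- tryCatch(
    .adbc_integrate_cpp(t_eval, t0, yv, graph$laplacian, unclass(params),
                        rtol, atol, as.integer(max_steps)),
    error = function(e) {
      stop("cascade integration failed: ", conditionMessage(e),
           " [n=", n, ", t0=", t0, ", t_end=", t_end, "]", call. = FALSE)
    })
  structure(list(
    ages = t_eval,
    Abeta = out[1:n, , drop = FALSE],
    tau = out[(n + 1):(2 * n), , drop = FALSE],
    N = out[(2 * n + 1):(3 * n), , drop = FALSE],
    C = out[3 * n + 1, ],
    meta = list(t0 = t0, t_end = t_end, rtol = rtol, atol = atol)),
    class = "adbc_trajectory")
}

#' Interpolate a trajectory's biomarker at arbitrary ages
#'
#' Linear interpolation on the trajectory's evaluation grid. Used when
#' scoring observations whose visit ages are off-grid.
#'
#' @param trajectory An `adbc_trajectory`.
#' @param biomarker One of `"Abeta"`, `"tau"`, `"N"`, `"C"`.
#' @param ages Ages inside the trajectory span.
#' @return For regional biomarkers a regions-by-ages matrix; for `"C"` a
#'   vector.
#' @export
trajectory_at <- function(trajectory, biomarker, ages) {
  stopifnot(biomarker %in% c("Abeta", "tau", "N", "C"))
  ta <- trajectory$ages
  if (any(ages < min(ta) - 1e-9) || any(ages > max(ta) + 1e-9)) {
    stop("requested age outside trajectory span")
  }
  if (biomarker == "C") {
    return(approx(ta, trajectory$C, xout = ages, rule = 2)$y)
  }
  m <- trajectory[[biomarker]]
  out <- matrix(0, nrow(m), length(ages))
  for (i in seq_len(nrow(m))) {
    out[i, ] <- approx(ta, m[i, ], xout = ages, rule = 2)$y
  }
  out
}

#' Prediction accuracy of a trajectory against observed records
#'
#' For each biomarker b with observations at visit ages t_i:
#' `accuracy_b = 100 * (1 - sum_i ||y_b(t_i) - obs_b(t_i)||_2 /
#' sum_i ||obs_b(t_i)||_2)`, clipped below at 0. The overall accuracy pools
#' all visits of all biomarkers present. Biomarkers without records are
#' omitted.
#'
#' @param trajectory An `adbc_trajectory` spanning all record ages.
#' @param records Normalized records data frame (columns `age`, `biomarker`,
#'   `region`, `value`) for one subject.
#' @return Named numeric vector of percentages, one per biomarker present,
#'   plus `"overall"`.
#' @export
trajectory_accuracy <- function(trajectory, records) {
  out <- numeric(0)
  num_all <- 0
  den_all <- 0
  for (b in c("Abeta", "tau", "N", "C")) {
    rb <- records[records$biomarker == b, , drop = FALSE]
    if (nrow(rb) == 0) next
    num <- 0
    den <- 0
    for (a in unique(rb$age)) {
      ra <- rb[rb$age == a, , drop = FALSE]
      if (b == "C") {
        pred <- trajectory_at(trajectory, b, a)
        obs <- ra$value[1]
      } else {
        pred_all <- trajectory_at(trajectory, b, a)
        pred <- pred_all[ra$region, 1]
        obs <- ra$value
      }
      num <- num + sqrt(sum((pred - obs)^2))
      den <- den + sqrt(sum(obs^2))
    }
    num_all <- num_all + num
    den_all <- den_all + den
    out[b] <- if (den > 0) max(0, 100 * (1 - num / den)) else NA_real_
  }
  if (length(out) > 0) {
    out["overall"] <- if (den_all > 0) max(0, 100 * (1 - num_all / den_all))
                      else NA_real_
  }
  out
}

#' Export a trajectory as a tidy table
#'
#' @param trajectory An `adbc_trajectory`.
#' @return Data frame with columns `age`, `biomarker`, `region`
#'   (NA for C), `value`.
#' @export
trajectory_to_table <- function(trajectory) {
  n <- nrow(trajectory$Abeta)
  ages <- trajectory$ages
  pieces <- lapply(c("Abeta", "tau", "N"), function(b) {
    m <- trajectory[[b]]
    data.frame(age = rep(ages, each = n), biomarker = b,
               region = rep(seq_len(n), length(ages)),
               value = as.vector(m), stringsAsFactors = FALSE)
  })
  cpiece <- data.frame(age = ages, biomarker = "C", region = NA_integer_,
                       value = trajectory$C, stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, pieces), cpiece)
  out[order(out$age, out$biomarker, out$region), , drop = FALSE]
}
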