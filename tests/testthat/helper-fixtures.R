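# shared fixtures, all generated in code

# small connected weighted graph with fixed seed
toy_graph <- function(n = 4, seed = 1, density = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  w <- runif(sum(up), 0.75, 1)
  keep <- runif(sum(up)) < density
  A[up] <- ifelse(keep, w, 0)
  A <- A + t(A)
  brain_graph(A)
}

# parameters in a mild progression regime
toy_params <- function(n = 4, ...) {
  defaults <- list(n_regions = n, D_Abeta = 0.05, D_tau = 0.05, D_N = 0.05,
                   lambda_CN = 0.03, lambda_C = 0.12, K_C = 1.1,
                   lambda_Abeta = 0.15, lambda_tau = 0.12, lambda_N = 0.12,
                   lambda_tauAbeta = 0.03, lambda_Ntau = 0.03,
                   K_Abeta = 1.1, K_tau = 1.1, K_N = 1.1)
  do.call(adbc_params, modifyList(defaults, list(...)))
}

toy_state <- function(n = 4, ab = 0.1, ta = 0.05, nn = 0.05, C = 0.02) {
  adbc_state(rep(ab, length.out = n), rep(ta, length.out = n),
             rep(nn, length.out = n), C)
}

default_level1_ranges_fixture <- function() {
  adbcascade:::default_level1_ranges()
}

# records table from a trajectory (exact, no noise) at given ages
records_from_trajectory <- function(traj, ages, biomarkers = c("Abeta", "tau", "N", "C"),
                                    subject_id = "T1") {
  n <- nrow(traj$Abeta)
  out <- list()
  for (b in biomarkers) {
    vals <- trajectory_at(traj, b, ages)
    if (b == "C") {
      out[[b]] <- data.frame(subject_id = subject_id, age = ages,
                             biomarker = b, region = NA_integer_,
                             value = as.numeric(vals))
    } else {
      out[[b]] <- data.frame(subject_id = subject_id,
                             age = rep(ages, each = n), biomarker = b,
                             region = rep(seq_len(n), length(ages)),
                             value = as.vector(vals))
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
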