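#' Specification of a synthetic longitudinal cohort
#'
#' Describes a cohort of virtual subjects with known ground-truth model
#' parameters, patient-specific connectivity and sparse noisy longitudinal
#' visits, emulating the structure of multimodal observational AD data:
#' irregular visit ages, at least three visits per retained modality,
#' optional missing modalities per subject, and regional trajectories with
#' sigmoid-like progression.
#'
#' Ground-truth parameters are drawn uniformly from sub-boxes of the
#' optimization bounds chosen so that trajectories actually transition
#' within the observation window (ages 55-95): logistic rates in
#' `[0.08, 0.25]`/yr, carrying capacities in `[1, 1.2]` (normalized
#' biomarkers saturate near 1 by construction of the cohort-max
#' normalization), cross-couplings in `[0.01, 0.05]`/yr, diffusivities in
#' `[0.02, 0.1]`/yr and initial values in `[0.03, 0.12]`.
#'
#' @param n_subjects Number of subjects.
#' @param n_regions Graph size; default 68 (8 is convenient for studies).
#' @param visits_min,visits_max Visits per retained modality (min >= 3).
#' @param age_window Visit age window, years; default `c(55, 95)`.
#' @param sigma Observation noise standard deviation on the normalized
#'   scale; default 0.02.
#' @param missing_frac Named fractions of subjects lacking each modality
#'   (`Abeta`, `tau`, `N`, `C`); default all 0 (complete multimodal data;
#'   raise to emulate availability patterns).
#' @param heterogeneity Relative spread of region-specific parameters
#'   around their subject-level scalar (default 0.2).
#' @param fc_density Edge density of the population graph; default 0.4.
#' @param pert_nonzero Number of nonzero entries in each of the true
#'   perturbation vectors u, v; default 3.
#' @param pert_scale Magnitude scale of the perturbation entries.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10, n_regions = 68,
                        visits_min = 4, visits_max = 7,
                        age_window = c(55, 95), sigma = 0.02,
                        missing_frac = c(Abeta = 0, tau = 0, N = 0, C = 0),
                        heterogeneity = 0.2, fc_density = 0.4,
                        pert_nonzero = 3, pert_scale = 0.1,
                        seed = 1) {
  stopifnot(visits_min >= 3, visits_max >= visits_min, sigma >= 0,
            fc_density > 0, fc_density <= 1, heterogeneity >= 0)
  mf <- c(Abeta = 0, tau = 0, N = 0, C = 0)
  mf[names(missing_frac)] <- missing_frac
  structure(list(n_subjects = n_subjects, n_regions = n_regions,
                 visits_min = visits_min, visits_max = visits_max,
                 age_window = age_window, sigma = sigma,
                 missing_frac = mf, heterogeneity = heterogeneity,
                 fc_density = fc_density, pert_nonzero = pert_nonzero,
                 pert_scale = pert_scale, seed = seed),
            class = "cohort_spec")
}

# true-parameter draw boxes (inside the optimization bounds; see
# ?cohort_spec)
synth_boxes <- function() {
  list(D = c(0.02, 0.1), lambda = c(0.08, 0.25), K = c(1, 1.2),
       cross = c(0.01, 0.05), y0 = c(0.03, 0.12), C0 = c(0, 0.05))
}

# connectivity check via breadth-first search on the adjacency
graph_connected <- function(A) {
  n <- nrow(A)
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue) > 0) {
    i <- queue[1]
    queue <- queue[-1]
    nb <- which(A[i, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Generate a synthetic population brain graph
#'
#' Symmetric hollow adjacency with Bernoulli(density) edges weighted
#' Uniform(0.75, 1) — consistent with a correlation-thresholded (r > 0.75)
#' functional-connectivity graph — redrawn until connected.
#'
#' @param n_regions Number of regions.
#' @param density Edge probability in (0, 1].
#' @param max_tries Redraw limit.
#' @return A `population_graph` ([brain_graph()]).
#' @export
synth_population_graph <- function(n_regions = 68, density = 0.4,
                                   max_tries = 100) {
  stopifnot(density > 0, density <= 1)
  for (try in seq_len(max_tries)) {
    A <- matrix(0, n_regions, n_regions)
    up <- upper.tri(A)
    edges <- runif(sum(up)) < density
    w <- runif(sum(up), 0.75, 1)
    A[up] <- ifelse(edges, w, 0)
    A <- A + t(A)
    if (graph_connected(A)) {
      g <- brain_graph(A)
      class(g) <- c("population_graph", "brain_graph")
      return(g)
    }
  }
  stop("failed to draw a connected graph in ", max_tries, " tries")
}

# regional vector: scalar * (1 + heterogeneity * centered uniform noise),
# clipped to the box
regionalize <- function(scalar, n, het, box) {
  v <- scalar * (1 + het * runif(n, -1, 1))
  pmin(pmax(v, box[1]), box[2])
}

#' Generate one synthetic subject
#'
#' Draws ground-truth parameters (see [cohort_spec()] for the boxes), a
#' sparse rank-2 connectivity perturbation rescaled until the perturbed
#' weights satisfy the `[0, 1]` box, simulates the noiseless trajectory on
#' the patient-specific graph, subsamples visits per modality, and adds
#' Gaussian observation noise clipped at 0.
#'
#' @param spec A [cohort_spec()].
#' @param population A population [brain_graph()].
#' @param subject_id Subject label.
#' @return List of class `synthetic_subject`: `params` (true
#'   [adbc_params()]), `y0`, `pert`, `graph`, `trajectory` (noiseless),
#'   `records` (observed), `visit_ages`, `modalities`.
#' @export
synth_subject <- function(spec, population, subject_id = "S1") {
  n <- spec$n_regions
  bx <- synth_boxes()
  het <- spec$heterogeneity
  u <- function(b) runif(1, b[1], b[2])

  lam_ab <- u(bx$lambda); lam_ta <- u(bx$lambda); lam_n <- u(bx$lambda)
  K_ab <- u(bx$K); K_ta <- u(bx$K); K_n <- u(bx$K)
  cr_ta <- u(bx$cross); cr_n <- u(bx$cross)
  params <- adbc_params(
    n_regions = n,
    D_Abeta = u(bx$D), D_tau = u(bx$D), D_N = u(bx$D),
    lambda_CN = u(bx$cross), lambda_C = u(bx$lambda), K_C = u(bx$K),
    lambda_Abeta = regionalize(lam_ab, n, het, c(0, 2)),
    lambda_tau = regionalize(lam_ta, n, het, c(0, 2)),
    lambda_N = regionalize(lam_n, n, het, c(0, 2)),
    lambda_tauAbeta = regionalize(cr_ta, n, het, c(0, 2)),
    lambda_Ntau = regionalize(cr_n, n, het, c(0, 2)),
    K_Abeta = regionalize(K_ab, n, het, c(1, 2)),
    K_tau = regionalize(K_ta, n, het, c(1, 2)),
    K_N = regionalize(K_n, n, het, c(1, 2)))

  y0 <- adbc_state(
    Abeta = regionalize(u(bx$y0), n, het, c(0, 1)),
    tau = regionalize(u(bx$y0) * 0.6, n, het, c(0, 1)),
    N = regionalize(u(bx$y0) * 0.6, n, het, c(0, 1)),
    C = u(bx$C0))

  # sparse perturbation, rescaled until the perturbed weights are feasible
  pert <- low_rank_perturbation(rep(0, n), rep(0, n))
  if (spec$pert_nonzero > 0) {
    iu <- sample.int(n, min(spec$pert_nonzero, n))
    iv <- sample.int(n, min(spec$pert_nonzero, n))
    uu <- rep(0, n); vv <- rep(0, n)
    uu[iu] <- rnorm(length(iu), 0, spec$pert_scale)
    vv[iv] <- rnorm(length(iv), 0, spec$pert_scale)
    ok <- FALSE
    for (try in seq_len(100)) {
      cand <- low_rank_perturbation(uu, vv)
      if (nrow(check_weight_constraints(population, cand)) == 0) {
        pert <- cand
        ok <- TRUE
        break
      }
      uu <- uu * 0.7
      vv <- vv * 0.7
    }
    if (!ok) stop("could not rescale perturbation into the weight box")
  }
  graph <- patient_graph(population, pert)

  traj <- adbc_simulate(params, y0, graph, t0 = 50, t_end = 100,
                        t_eval = seq(50, 100, by = 0.5))

  modalities <- c("Abeta", "tau", "N", "C")
  present <- vapply(modalities, function(b) {
    runif(1) >= spec$missing_frac[[b]]
  }, logical(1))
  # inclusion demands >= 3 visits in at least one regional modality
  if (!any(present[c("Abeta", "tau", "N")])) present["Abeta"] <- TRUE

  records <- list()
  visit_ages <- list()
  for (b in modalities[present]) {
    nv <- sample(spec$visits_min:spec$visits_max, 1)
    ages <- sort(runif(nv, spec$age_window[1], spec$age_window[2]))
    visit_ages[[b]] <- ages
    truth <- trajectory_at(traj, b, ages)
    if (b == "C") {
      vals <- pmax(0, truth + rnorm(length(ages), 0, spec$sigma))
      records[[b]] <- data.frame(subject_id = subject_id, age = ages,
                                 biomarker = b, region = NA_integer_,
                                 value = vals, stringsAsFactors = FALSE)
    } else {
      noise <- matrix(rnorm(n * nv, 0, spec$sigma), n, nv)
      vals <- pmax(0, truth + noise)
      records[[b]] <- data.frame(
        subject_id = subject_id, age = rep(ages, each = n), biomarker = b,
        region = rep(seq_len(n), nv), value = as.vector(vals),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(params = params, y0 = y0, pert = pert, graph = graph,
                 trajectory = traj,
                 records = do.call(rbind, c(records, list(make.row.names = FALSE))),
                 visit_ages = visit_ages,
                 modalities = modalities[present]),
            class = "synthetic_subject")
}

#' Generate a synthetic cohort
#'
#' Draws a shared population graph and `n_subjects` subjects (see
#' [synth_subject()]); bit-reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `synthetic_cohort`: `spec`, `population`
#'   (population graph), `subjects` (list of `synthetic_subject`),
#'   `records` (pooled observation table).
#' @export
synth_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  population <- synth_population_graph(spec$n_regions, spec$fc_density)
  subjects <- lapply(seq_len(spec$n_subjects), function(i) {
    synth_subject(spec, population, subject_id = sprintf("S%03d", i))
  })
  records <- do.call(rbind, c(lapply(subjects, `[[`, "records"),
                              list(make.row.names = FALSE)))
  structure(list(spec = spec, population = population, subjects = subjects,
                 records = records),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$subjects), "subjects,",
      x$spec$n_regions, "regions,", nrow(x$records), "observations\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the pooled longitudinal CSV, per-subject adjacency CSVs, and a
#' ground-truth JSON bundle (true parameters, initial states, perturbation
#' vectors) enabling recovery scoring.
#'
#' @param cohort A [synth_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_biomarker_table(cohort$records, file.path(dir, "records.csv"))
  write_fc_matrix(cohort$population$adjacency,
                  file.path(dir, "population_adjacency.csv"))
  truth <- lapply(cohort$subjects, function(s) {
    p <- unclass(s$params)
    list(params = p[setdiff(names(p), "n_regions")],
         y0 = unclass(s$y0), u = s$pert$u, v = s$pert$v)
  })
  names(truth) <- vapply(cohort$subjects,
                         function(s) s$records$subject_id[1], character(1))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE)
  for (s in cohort$subjects) {
    id <- s$records$subject_id[1]
    write_fc_matrix(s$graph$adjacency,
                    file.path(dir, paste0("adjacency_", id, ".csv")))
  }
  invisible(dir)
}
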