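#' Construct a brain graph from a weighted adjacency matrix
#'
#' A brain graph is an undirected weighted graph on n regions (68 for the
#' Desikan-Killiany atlas) stored as a symmetric, hollow-diagonal adjacency
#' matrix together with its degree vector and graph Laplacian `L = D - A`.
#'
#' @param adjacency Symmetric numeric matrix with zero diagonal and
#'   nonnegative weights.
#' @return Object of class `brain_graph`: list with `adjacency`, `degree`,
#'   `laplacian`, `n`.
#' @export
brain_graph <- function(adjacency) {
  A <- as.matrix(adjacency)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (max(abs(A - t(A))) > 1e-8) stop("adjacency must be symmetric")
  if (any(abs(diag(A)) > 1e-12)) stop("adjacency must have zero diagonal")
  if (any(A < 0)) stop("negative edge weight in adjacency")
  A <- (A + t(A)) / 2
  diag(A) <- 0
  lap <- build_laplacian(A)
  structure(list(adjacency = A, degree = lap$degree,
                 laplacian = lap$laplacian, n = nrow(A)),
            class = "brain_graph")
}

#' Degree vector and graph Laplacian of an adjacency matrix
#'
#' `d_i = sum_k a_ik`, `L = diag(d) - A`. Row sums of `L` are exactly zero
#' and `L` is symmetric positive semi-definite for nonnegative weights.
#'
#' @param A Symmetric nonnegative adjacency matrix with zero diagonal.
#' @return List with `degree` (numeric vector) and `laplacian` (matrix).
#' @export
build_laplacian <- function(A) {
  A <- as.matrix(A)
  if (any(A < 0)) stop("negative edge weight")
  d <- rowSums(A)
  L <- diag(d, nrow = nrow(A)) - A
  list(degree = d, laplacian = L)
}

#' Threshold a functional-connectivity matrix into a brain graph
#'
#' Keeps edge (i, j), i != j, iff the correlation exceeds `r_min` and (when a
#' p-value matrix is supplied) the p-value is below `p_max`; both
#' inequalities strict. Kept edges are weighted by the correlation; the
#' diagonal (self-connections) is removed. Defaults follow the statistical
#' truncation rule r > 0.75, p < 1e-5.
#'
#' @param fc An `fc_matrix` (see [read_fc_matrix()]) or a plain symmetric
#'   correlation matrix.
#' @param r_min Correlation threshold (strict); default 0.75.
#' @param p_max p-value threshold (strict); default 1e-5. Ignored when no
#'   p-value matrix is present.
#' @return A [brain_graph()].
#' @export
threshold_fc <- function(fc, r_min = 0.75, p_max = 1e-5) {
  if (inherits(fc, "fc_matrix")) {
    r <- fc$r
    p <- fc$p
  } else {
    r <- as.matrix(fc)
    p <- NULL
  }
  if (max(abs(r - t(r))) > 1e-8) stop("FC matrix not symmetric within 1e-8")
  keep <- r > r_min
  if (!is.null(p)) keep <- keep & (p < p_max)
  A <- ifelse(keep, r, 0)
  diag(A) <- 0
  A <- (A + t(A)) / 2
  brain_graph(A)
}

#' Average per-subject graphs into a population graph
#'
#' Each member adjacency is symmetrized as `(A + t(A))/2` (guarding against
#' measurement noise) before averaging: `Ap = mean_k A(k)`. The population
#' Laplacian equals both the mean of the member Laplacians and the Laplacian
#' of `Ap` (Laplacian construction is linear in the adjacency).
#'
#' @param graphs List of [brain_graph()] objects (or adjacency matrices) of
#'   identical dimension.
#' @return Object of class `c("population_graph", "brain_graph")`.
#' @export
population_graph <- function(graphs) {
  stopifnot(length(graphs) >= 1)
  mats <- lapply(graphs, function(g) {
    A <- if (inherits(g, "brain_graph")) g$adjacency else as.matrix(g)
    (A + t(A)) / 2
  })
  n <- nrow(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == n), logical(1)))) {
    stop("inconsistent graph dimensions")
  }
  Ap <- Reduce(`+`, mats) / length(mats)
  g <- brain_graph(Ap)
  class(g) <- c("population_graph", "brain_graph")
  g
}

#' Low-rank patient-specific perturbation of a population graph
#'
#' Bundles the vector pair (u, v) whose symmetrized outer product encodes a
#' patient's deviation from the population adjacency. The unit-norm
#' constraints `||u|| = ||v|| = 1` are soft-penalized during fitting, not
#' enforced here.
#'
#' @param u,v Numeric vectors of equal length (one entry per region).
#' @return Object of class `low_rank_perturbation`.
#' @export
low_rank_perturbation <- function(u, v) {
  stopifnot(length(u) == length(v), all(is.finite(u)), all(is.finite(v)))
  structure(list(u = as.numeric(u), v = as.numeric(v)),
            class = "low_rank_perturbation")
}

#' Patient-specific adjacency matrix
#'
#' `A = Ap + (u v' + v u')/2 - diag(u * v)`. The diagonal correction exactly
#' cancels the rank-2 term's diagonal, so `diag(A) = diag(Ap) = 0`. With
#' `u = v` this reduces to the rank-1 form `Ap + u u' - diag(u^2)`.
#'
#' @param population A population [brain_graph()] (or adjacency matrix).
#' @param pert A [low_rank_perturbation()].
#' @return The perturbed adjacency matrix (not validated against the
#'   `[0, 1]` weight box; see [check_weight_constraints()]).
#' @export
patient_adjacency <- function(population, pert) {
  Ap <- if (inherits(population, "brain_graph")) population$adjacency
        else as.matrix(population)
  u <- pert$u
  v <- pert$v
  stopifnot(length(u) == nrow(Ap))
  Ap + (tcrossprod(u, v) + tcrossprod(v, u)) / 2 - diag(u * v, nrow = length(u))
}

#' Patient-specific graph Laplacian
#'
#' Closed form avoiding reconstruction of the full adjacency:
#' `L = Lp + diag(u (v'1) + v (u'1))/2 - (u v' + v u')/2`. Algebraically
#' identical to `build_laplacian(patient_adjacency(Ap, pert))` whenever
#' `Lp` is the Laplacian of `Ap`; row sums are zero for any perturbation.
#'
#' @param population A population [brain_graph()] whose `laplacian` is `Lp`.
#' @param pert A [low_rank_perturbation()].
#' @return The perturbed Laplacian matrix.
#' @export
patient_laplacian <- function(population, pert) {
  Lp <- if (inherits(population, "brain_graph")) population$laplacian
        else stop("population must be a brain_graph")
  u <- pert$u
  v <- pert$v
  n <- length(u)
  su <- sum(u)
  sv <- sum(v)
  Lp + diag(u * sv + v * su, nrow = n) / 2 -
    (tcrossprod(u, v) + tcrossprod(v, u)) / 2
}

#' Build a patient-specific brain graph from a perturbation
#'
#' Convenience wrapper returning a full [brain_graph()] for the perturbed
#' adjacency (which must be feasible, i.e. weights in `[0, 1]`).
#'
#' @inheritParams patient_adjacency
#' @return A [brain_graph()].
#' @export
patient_graph <- function(population, pert, tol = 1e-6) {
  viol <- check_weight_constraints(population, pert, tol = tol)
  if (nrow(viol) > 0) {
    stop("perturbation infeasible: ", nrow(viol),
         " edge weight(s) outside [0, 1]")
  }
  A <- patient_adjacency(population, pert)
  A <- pmin(pmax(A, 0), 1)  # absorb float-level box overshoot
  diag(A) <- 0
  brain_graph(A)
}

#' Audit the edge-weight box constraints of a perturbation
#'
#' Lists every region pair (k, h) whose perturbed weight
#' `a_kh + (u_k v_h + v_k u_h)/2 - delta_kh u_k v_k` falls outside `[0, 1]`.
#' An empty result means the perturbation is feasible. Perturbations may
#' light up new edges (weight moving off 0 into (0, 1]) without violation.
#'
#' @inheritParams patient_adjacency
#' @param tol Feasibility tolerance; default 1e-9.
#' @return Data frame with columns `k`, `h`, `value` (upper triangle only).
#' @export
check_weight_constraints <- function(population, pert, tol = 1e-9) {
  A <- patient_adjacency(population, pert)
  bad <- which(upper.tri(A) & (A < -tol | A > 1 + tol), arr.ind = TRUE)
  data.frame(k = bad[, 1], h = bad[, 2],
             value = A[bad], row.names = NULL)
}

#' Degree-weighted graph integral of a regional field
#'
#' The discrete integral `sum_v d_v f(v) / sum_v d_v`: the degree-weighted
#' mean of the field. On a uniform-degree graph it reduces to the plain
#' mean.
#'
#' @param field Numeric vector, one value per region.
#' @param graph A [brain_graph()].
#' @return Scalar.
#' @export
graph_integral <- function(field, graph) {
  d <- graph$degree
  stopifnot(length(field) == length(d))
  total <- sum(d)
  if (total <= 0) stop("graph integral undefined: all nodes isolated (sum of degrees is 0)")
  sum(d * field) / total
}
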