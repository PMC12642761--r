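#' Read a longitudinal regional biomarker table
#'
#' Reads a delimited text file with columns `subject_id`, `age`, `biomarker`,
#' `region`, `value` (in any column order) into a data frame of raw
#' observations. Row order is preserved. `region` may be empty/NA for
#' whole-brain measures (MMSE before normalization, C after).
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @return A data frame with columns `subject_id` (character), `age`
#'   (numeric, years), `biomarker` (character), `region` (integer or NA),
#'   `value` (numeric).
#' @export
read_biomarker_table <- function(path, sep = ",") {
  if (!file.exists(path)) {
    stop("input file not found: ", path)
  }
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = TRUE)
  required <- c("subject_id", "age", "biomarker", "region", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("format error: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, required]
  n <- nrow(df)
  if (n == 0) {
    return(data.frame(subject_id = character(0), age = numeric(0),
                      biomarker = character(0), region = integer(0),
                      value = numeric(0), stringsAsFactors = FALSE))
  }
  age <- suppressWarnings(as.numeric(df$age))
  value <- suppressWarnings(as.numeric(df$value))
  # header is line 1, so data row i sits on file line i + 1
  bad_age <- which(is.na(age) & !is.na(df$age) & nzchar(df$age))
  if (length(bad_age) > 0) {
    stop("row error: non-numeric age at line ", bad_age[1] + 1L,
         " ('", df$age[bad_age[1]], "')")
  }
  bad_val <- which(is.na(value) & !is.na(df$value) & nzchar(df$value))
  if (length(bad_val) > 0) {
    stop("row error: non-numeric value at line ", bad_val[1] + 1L,
         " ('", df$value[bad_val[1]], "')")
  }
  region <- suppressWarnings(as.integer(df$region))
  data.frame(subject_id = df$subject_id, age = age,
             biomarker = df$biomarker, region = region, value = value,
             stringsAsFactors = FALSE)
}

#' Write a longitudinal biomarker table
#'
#' Inverse of [read_biomarker_table()]: writes the five standard columns as
#' delimited text at full precision, so a write/read round trip reproduces
#' values exactly.
#'
#' @param records Data frame with columns `subject_id`, `age`, `biomarker`,
#'   `region`, `value`.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_biomarker_table <- function(records, path, sep = ",") {
  required <- c("subject_id", "age", "biomarker", "region", "value")
  stopifnot(all(required %in% names(records)))
  out <- records[, required]
  out$age <- format(out$age, digits = 17, trim = TRUE, scientific = FALSE)
  out$value <- vapply(out$value, function(v) format(v, digits = 17, trim = TRUE),
                      character(1))
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a reference-value table for biomarker normalization
#'
#' Computes one positive reference value per (biomarker, region) pair present
#' in the observations. Whole-brain biomarkers (NA region) get a single
#' reference keyed on region NA.
#'
#' @param observations Data frame of raw observations
#'   (see [read_biomarker_table()]).
#' @param rule `"cohort_max"` (default): per-(biomarker, region) maximum over
#'   the cohort, so normalized trajectories approach 1 at end stage;
#'   `"cohort_quantile"`: the `q` quantile instead of the maximum;
#'   `"fixed_table"`: pass `table` through unchanged.
#' @param q Quantile used by `"cohort_quantile"` (type-7, the [stats::quantile()]
#'   default).
#' @param table Data frame with columns `biomarker`, `region`, `reference`
#'   for `rule = "fixed_table"`.
#' @return Data frame with columns `biomarker`, `region`, `reference`.
#' @export
build_reference_table <- function(observations,
                                  rule = c("cohort_max", "cohort_quantile",
                                           "fixed_table"),
                                  q = 0.95, table = NULL) {
  rule <- match.arg(rule)
  if (rule == "fixed_table") {
    stopifnot(is.data.frame(table),
              all(c("biomarker", "region", "reference") %in% names(table)))
    if (any(!is.finite(table$reference) | table$reference <= 0)) {
      stop("reference values must be positive (division unsafe)")
    }
    return(table[, c("biomarker", "region", "reference")])
  }
  stat <- if (rule == "cohort_max") {
    function(v) max(v)
  } else {
    function(v) as.numeric(quantile(v, q, names = FALSE))
  }
  key <- interaction(observations$biomarker,
                     ifelse(is.na(observations$region), -1L, observations$region),
                     drop = TRUE)
  pieces <- split(observations, key)
  refs <- do.call(rbind, lapply(pieces, function(g) {
    data.frame(biomarker = g$biomarker[1], region = g$region[1],
               reference = stat(g$value), stringsAsFactors = FALSE)
  }))
  rownames(refs) <- NULL
  if (any(!is.finite(refs$reference) | refs$reference <= 0)) {
    bad <- refs[!is.finite(refs$reference) | refs$reference <= 0, ]
    stop("non-positive reference value for ", bad$biomarker[1], " region ",
         bad$region[1], " (division unsafe)")
  }
  refs
}

#' Normalize raw biomarker observations and orient them with severity
#'
#' Divides each raw value by its (biomarker, region) reference and applies
#' the severity-direction transforms: amyloid (`Abeta`) and tau increase with
#' disease and are kept as `value / reference`; cortical thickness (`Nct`)
#' decreases with disease and becomes neurodegeneration `N = 1 - Nct/ref`
#' (or `(1 - Nct)/ref'` with `nct_order = "invert_then_normalize"`); the MMSE
#' score `S` (0-30, 30 = intact) becomes cognitive impairment
#' `C = 1 - S/mmse_max`. Output biomarker labels are remapped
#' `Nct -> N`, `MMSE -> C`.
#'
#' @param observations Raw observations (see [read_biomarker_table()]).
#' @param references Reference table from [build_reference_table()]. MMSE
#'   needs no reference entry (it is normalized by `mmse_max`).
#' @param mmse_max Maximum MMSE score; default 30.
#' @param nct_order Order of normalization and inversion for cortical
#'   thickness: `"normalize_then_invert"` (default, `N = 1 - Nct/ref`) or
#'   `"invert_then_normalize"` (`N = (1 - Nct) / ref`, with the reference
#'   computed on the inverted scale by the caller).
#' @return Data frame of normalized, severity-increasing records with
#'   biomarker labels in `{Abeta, tau, N, C}`.
#' @export
normalize_biomarkers <- function(observations, references, mmse_max = 30,
                                 nct_order = c("normalize_then_invert",
                                               "invert_then_normalize")) {
  nct_order <- match.arg(nct_order)
  obs <- observations
  refkey <- paste(references$biomarker,
                  ifelse(is.na(references$region), -1L, references$region))
  ref_lookup <- setNames(references$reference, refkey)
  out_value <- numeric(nrow(obs))
  out_marker <- character(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    b <- obs$biomarker[i]
    v <- obs$value[i]
    if (b == "MMSE") {
      if (is.na(v) || v < 0 || v > mmse_max) {
        stop("MMSE value out of [0, ", mmse_max, "] at row ", i)
      }
      out_value[i] <- 1 - v / mmse_max
      out_marker[i] <- "C"
      next
    }
    key <- paste(b, ifelse(is.na(obs$region[i]), -1L, obs$region[i]))
    if (!key %in% names(ref_lookup)) {
      stop("missing reference for biomarker '", b, "' region ",
           obs$region[i])
    }
    r <- ref_lookup[[key]]
    if (b == "Nct") {
      out_value[i] <- if (nct_order == "normalize_then_invert") 1 - v / r
                      else (1 - v) / r
      out_marker[i] <- "N"
    } else if (b %in% c("Abeta", "tau")) {
      out_value[i] <- v / r
      out_marker[i] <- b
    } else {
      # already-normalized labels pass through (idempotence under fixed_table)
      out_value[i] <- v / r
      out_marker[i] <- b
    }
  }
  data.frame(subject_id = obs$subject_id, age = obs$age,
             biomarker = out_marker, region = obs$region, value = out_value,
             stringsAsFactors = FALSE)
}

#' Read a functional-connectivity matrix
#'
#' Reads an n-by-n matrix of Pearson correlations (and optionally a parallel
#' matrix of p-values) from headerless CSV. Checks symmetry (tolerance 1e-8)
#' and, for the correlation matrix, a unit diagonal.
#'
#' @param path_r Path to the correlation CSV.
#' @param path_p Optional path to a parallel p-value CSV.
#' @return A list of class `fc_matrix` with elements `r` and `p` (NULL if
#'   absent).
#' @export
read_fc_matrix <- function(path_r, path_p = NULL) {
  r <- as.matrix(read.csv(path_r, header = FALSE))
  dimnames(r) <- NULL
  storage.mode(r) <- "double"
  if (nrow(r) != ncol(r)) stop("FC matrix must be square")
  if (max(abs(r - t(r))) > 1e-8) stop("FC matrix not symmetric within 1e-8")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("FC matrix diagonal must be 1")
  p <- NULL
  if (!is.null(path_p)) {
    p <- as.matrix(read.csv(path_p, header = FALSE))
    dimnames(p) <- NULL
    storage.mode(p) <- "double"
    if (!all(dim(p) == dim(r))) stop("p-value matrix dimensions differ from r")
  }
  structure(list(r = r, p = p), class = "fc_matrix")
}

#' Write a functional-connectivity matrix as headerless CSV
#'
#' @param m Numeric square matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fc_matrix <- function(m, path) {
  write.table(format(m, digits = 17, trim = TRUE), path, sep = ",",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
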