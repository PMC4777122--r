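#' Phenotype table for Finlay-Wilkinson regression
#'
#' Bundles a long-format multi-environment trial: one row per plot record
#' with a variety label, an environment label and a numeric trait value.
#' The trait may be missing (`NA`); labels may not. Replicate records of
#' the same variety-environment cell are allowed. Variety and environment
#' orderings are fixed by first appearance in the data, so all downstream
#' output (effect vectors, covariance alignment) has a reproducible order
#' independent of locale or sorting.
#'
#' @param VAR character (or coercible) vector of variety labels.
#' @param ENV character (or coercible) vector of environment labels.
#' @param y numeric trait values, `NA` allowed.
#' @return An object of class `fw_table`: a list with `records`
#'   (data.frame with columns `VAR`, `ENV`, `y`), `varieties`,
#'   `environments` (ordered unique labels) and `n_obs` (number of
#'   non-missing trait values).
#' @examples
#' tab <- fw_table(VAR = c("L1", "L1", "L2", "L2"),
#'                 ENV = c("E1", "E2", "E1", "E2"),
#'                 y = c(1, 2, 3, 4))
#' tab$n_obs
#' @export
fw_table <- function(VAR, ENV, y) {
  if (length(VAR) == 0L) stop("phenotype table is empty")
  VAR <- as.character(VAR)
  ENV <- as.character(ENV)
  y <- as.numeric(y)
  if (length(VAR) != length(y) || length(ENV) != length(y))
    stop("VAR, ENV and y must have equal length")
  if (anyNA(VAR) || anyNA(ENV))
    stop("variety and environment labels may not be missing")
  out <- list(records = data.frame(VAR = VAR, ENV = ENV, y = y,
                                   stringsAsFactors = FALSE),
              varieties = unique(VAR),
              environments = unique(ENV),
              n_obs = sum(!is.na(y)))
  class(out) <- "fw_table"
  out
}

#' @export
print.fw_table <- function(x, ...) {
  cat(sprintf("fw_table: %d records (%d observed), %d varieties, %d environments\n",
              nrow(x$records), x$n_obs, length(x$varieties),
              length(x$environments)))
  invisible(x)
}

#' Labeled covariance structure for varieties or environments
#'
#' Wraps a symmetric positive-semidefinite matrix describing covariances
#' between variety effects (a pedigree- or marker-derived relationship
#' matrix `A`) or between environment effects (`H`). Symmetry is required
#' to a relative tolerance of 1e-8 and eigenvalues may not fall below
#' `-1e-8` times the largest eigenvalue; matrices failing either check are
#' rejected rather than repaired (a small jitter is applied only at
#' inversion time inside the Gibbs sampler).
#'
#' @param K square numeric matrix.
#' @param labels row/column labels; defaults to `rownames(K)`.
#' @param kind `"lines"` or `"environments"`.
#' @return An object of class `fw_cov`: list with `K` (labeled matrix),
#'   `labels`, `kind`.
#' @export
cov_spec <- function(K, labels = rownames(K),
                     kind = c("lines", "environments")) {
  kind <- match.arg(kind)
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("covariance matrix must be square")
  if (is.null(labels)) stop("covariance matrix needs labels (rownames or `labels`)")
  labels <- as.character(labels)
  if (length(labels) != nrow(K)) stop("label length does not match matrix dimension")
  if (anyDuplicated(labels)) stop("covariance labels must be unique")
  sc <- max(abs(K), 1e-300)
  if (max(abs(K - t(K))) > 1e-8 * sc)
    stop("covariance matrix is not symmetric within tolerance 1e-8")
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop(sprintf("covariance matrix is not positive semidefinite (min eigenvalue %.3g)",
                 min(ev)))
  dimnames(K) <- list(labels, labels)
  structure(list(K = K, labels = labels, kind = kind), class = "fw_cov")
}

#' Align a phenotype table with optional covariance matrices
#'
#' Produces the integer-indexed model frame used by both estimators:
#' variety/environment index per record, the observed mask, and the `A`
#' and `H` matrices reordered to the table's variety and environment order
#' (subset to the labels present; surplus covariance labels are dropped).
#' A missing covariance means independence and is represented as `NULL`
#' (interpreted as the identity).
#'
#' @param table an [fw_table].
#' @param A optional [cov_spec] of kind `"lines"` covering every variety.
#' @param H optional [cov_spec] of kind `"environments"` covering every
#'   environment.
#' @return list with `vi`, `ei` (1-based indices), `y`, `obs` (logical),
#'   `varieties`, `environments`, `nV`, `nE`, `n_obs`, `A`, `H` (reordered
#'   matrices or `NULL`).
#' @export
fw_align <- function(table, A = NULL, H = NULL) {
  stopifnot(inherits(table, "fw_table"))
  vlab <- table$varieties
  elab <- table$environments
  reorder_cov <- function(cv, want, what) {
    if (is.null(cv)) return(NULL)
    if (is.matrix(cv)) cv <- cov_spec(cv, kind = if (what == "variety") "lines" else "environments")
    stopifnot(inherits(cv, "fw_cov"))
    missing_lab <- setdiff(want, cv$labels)
    if (length(missing_lab))
      stop(sprintf("%s label(s) absent from covariance matrix: %s",
                   what, paste(missing_lab, collapse = ", ")))
    cv$K[want, want, drop = FALSE]
  }
  list(vi = match(table$records$VAR, vlab),
       ei = match(table$records$ENV, elab),
       y = table$records$y,
       obs = !is.na(table$records$y),
       varieties = vlab, environments = elab,
       nV = length(vlab), nE = length(elab),
       n_obs = table$n_obs,
       A = reorder_cov(A, vlab, "variety"),
       H = reorder_cov(H, elab, "environment"))
}

#' Evaluate the reaction-norm predictor
#'
#' Returns \eqn{\mu + g_i + h_j + b_i h_j} for the requested
#' variety/environment pairs. This is an identity in the parameters, used
#' both for fitted values and for predictions of unobserved cells.
#'
#' @param params list with `mu` (scalar) and named vectors `g`, `b` (over
#'   varieties) and `h` (over environments).
#' @param variety,env label vectors (recycled to a common length).
#' @return numeric vector of predictor values.
#' @export
fw_predictor <- function(params, variety, env) {
  variety <- as.character(variety)
  env <- as.character(env)
  if (!all(variety %in% names(params$g)))
    stop("unknown variety label: ",
         paste(setdiff(variety, names(params$g)), collapse = ", "))
  if (!all(env %in% names(params$h)))
    stop("unknown environment label: ",
         paste(setdiff(env, names(params$h)), collapse = ", "))
  g <- params$g[variety]
  b <- params$b[variety]
  h <- params$h[env]
  unname(params$mu + g + h + b * h)
}

# ---- file formats -----------------------------------------------------------

# Sniff the field separator: tab if the header contains one, else comma.
.sep_of <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (grepl("\t", hdr)) "\t" else ","
}

#' Read a phenotype file
#'
#' Expects a CSV or TSV (auto-detected from the header line) with a header
#' containing columns `VAR`, `ENV` and `y`; extra columns are ignored. The
#' literal `NA` and the empty field both parse as missing trait values.
#'
#' @param path file path.
#' @return an [fw_table].
#' @export
read_phenotype <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = .sep_of(path),
                         colClasses = "character", na.strings = NULL,
                         check.names = TRUE, stringsAsFactors = FALSE)
  need <- c("VAR", "ENV", "y")
  if (!all(need %in% names(d)))
    stop(sprintf("phenotype file must have columns VAR, ENV, y (found: %s)",
                 paste(names(d), collapse = ", ")))
  yy <- d$y
  yy[yy == "NA" | yy == ""] <- NA_character_
  fw_table(VAR = d$VAR, ENV = d$ENV, y = as.numeric(yy))
}

#' Write a phenotype table
#'
#' Inverse of [read_phenotype()]; missing trait values are written as the
#' literal `NA`. Round-tripping preserves records, ordering and
#' missingness exactly.
#'
#' @param table an [fw_table].
#' @param path output path; `.tsv` extension selects tab separation.
#' @export
write_phenotype <- function(table, path) {
  stopifnot(inherits(table, "fw_table"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  rec <- table$records
  # 17 significant digits so doubles survive the text round trip exactly
  rec$y <- ifelse(is.na(rec$y), NA_character_, sprintf("%.17g", rec$y))
  utils::write.table(rec, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a labeled covariance matrix
#'
#' First row and first column hold the labels; the body is the square
#' matrix (CSV or TSV, auto-detected).
#'
#' @param path file path.
#' @param kind `"lines"` or `"environments"`.
#' @return a [cov_spec].
#' @export
read_covariance <- function(path, kind = c("lines", "environments")) {
  kind <- match.arg(kind)
  d <- utils::read.table(path, header = TRUE, sep = .sep_of(path),
                         row.names = 1, check.names = FALSE)
  cov_spec(as.matrix(d), labels = rownames(d), kind = kind)
}

#' Write a labeled covariance matrix
#' @param cov a [cov_spec] (or labeled matrix).
#' @param path output path; `.tsv` extension selects tab separation.
#' @export
write_covariance <- function(cov, path) {
  K <- if (inherits(cov, "fw_cov")) cov$K else as.matrix(cov)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(cbind(label = rownames(K), as.data.frame(K)), path,
                     sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
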