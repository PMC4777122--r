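# Synthetic-data generator: phenotype tables with the exact reaction-norm
# structure y = mu + g_i + (1 + b_i) h_j + e, optionally with
# kinship-structured line effects and H-structured environment effects,
# plus the design-masking utility used for cross-validation.

#' Simulate a marker-derived genomic relationship matrix
#'
#' Draws biallelic dosages (0/1/2) for `n_markers` independent loci with
#' per-locus allele frequency uniform on `maf_range`, then forms the
#' VanRaden-style relationship matrix \eqn{G = WW'/m} from the
#' column-centered, column-scaled dosage matrix \eqn{W} (monomorphic
#' markers are dropped from \eqn{m}). The diagonal averages about 1; with
#' many markers and unrelated lines the off-diagonals shrink toward 0. No
#' linkage disequilibrium or population structure is modeled — the aim is
#' a valid, reproducible PSD kinship, not a realistic genome.
#'
#' @param n_lines number of lines.
#' @param n_markers number of loci (`>= n_lines` recommended so the
#'   matrix is well conditioned).
#' @param maf_range length-2 range of minor-allele frequencies in (0, 0.5].
#' @param seed integer seed.
#' @return a [cov_spec] of kind `"lines"` with labels `L1..Ln`; the dosage
#'   matrix is attached as attribute `"markers"`.
#' @export
simulate_kinship <- function(n_lines, n_markers, maf_range = c(0.05, 0.5),
                             seed = NULL) {
  if (length(maf_range) != 2 || diff(maf_range) < 0 ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must be an increasing range within (0, 0.5]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- runif(n_markers, maf_range[1], maf_range[2])
  X <- vapply(p, function(pj) rbinom(n_lines, 2, pj), numeric(n_lines))
  X <- matrix(X, nrow = n_lines)
  sds <- apply(X, 2, sd)
  keep <- sds > 0
  if (!any(keep)) stop("all simulated markers are monomorphic; widen maf_range")
  W <- scale(X[, keep, drop = FALSE])
  G <- tcrossprod(W) / sum(keep)
  labels <- paste0("L", seq_len(n_lines))
  dimnames(G) <- list(labels, labels)
  out <- cov_spec(G, kind = "lines")
  attr(out, "markers") <- X
  out
}

#' Simulate a Finlay-Wilkinson phenotype table
#'
#' Generates \eqn{y_{ijk} = \mu + g_i + (1 + b_i) h_j +
#' \varepsilon_{ijk}} with \eqn{g \sim N(0, A\sigma^2_g)}, \eqn{b \sim
#' N(0, A\sigma^2_b)}, \eqn{h \sim N(0, H\sigma^2_h)} (or fixed
#' `env_effects`) and iid normal residuals, on a full-factorial design
#' with `replicates` records per cell. Default variance magnitudes
#' (residual 0.3, intercept 0.09, slope 0.10, environment 0.9, grand mean
#' 4) mirror a typical wheat grain-yield multi-environment trial, where
#' environment differences dominate the genetic signal.
#'
#' @param n_lines number of varieties.
#' @param n_envs number of environments (ignored when `env_effects` is
#'   given).
#' @param mu grand mean (trait units).
#' @param var_e,var_g,var_b,var_h variance components (trait units
#'   squared; `var_e = 0` gives noise-free data).
#' @param A optional [cov_spec] (or matrix) for the line effects; identity
#'   if omitted. Its labels become the variety labels.
#' @param H optional [cov_spec] (or matrix) for the environment effects.
#' @param env_effects optional fixed environment-effect vector (overrides
#'   `n_envs`/`var_h`/`H`).
#' @param replicates records per variety-environment cell.
#' @param seed integer seed; the same seed reproduces the identical table.
#' @return list with `table` (an [fw_table]) and `truth` (the parameters
#'   actually used: `mu`, `g`, `b`, `h`, the variances, design descriptor
#'   and seed).
#' @export
simulate_fw_table <- function(n_lines, n_envs = 4, mu = 4,
                              var_e = 0.3, var_g = 0.09, var_b = 0.10,
                              var_h = 0.9,
                              A = NULL, H = NULL, env_effects = NULL,
                              replicates = 1, seed = NULL) {
  if (var_e < 0 || var_g <= 0 || var_b <= 0)
    stop("variances must be positive (var_e may be zero)")
  if (!is.null(seed)) set.seed(as.integer(seed))

  get_K <- function(cv, n, kind) {
    if (is.null(cv)) return(NULL)
    if (is.matrix(cv) && is.null(rownames(cv))) {
      dimnames(cv) <- list(paste0(if (kind == "lines") "L" else "E", seq_len(nrow(cv))),
                           paste0(if (kind == "lines") "L" else "E", seq_len(nrow(cv))))
    }
    if (!inherits(cv, "fw_cov")) cv <- cov_spec(cv, kind = kind)
    if (nrow(cv$K) != n) stop("covariance dimension does not match the design")
    cv
  }

  Acov <- get_K(A, n_lines, "lines")
  vlab <- if (is.null(Acov)) paste0("L", seq_len(n_lines)) else Acov$labels
  rmvn <- function(n, K, s2) {
    if (is.null(K)) rnorm(n, 0, sqrt(s2))
    else drop(MASS::mvrnorm(1, mu = rep(0, n), Sigma = K * s2))
  }
  g <- rmvn(n_lines, if (is.null(Acov)) NULL else Acov$K, var_g)
  b <- rmvn(n_lines, if (is.null(Acov)) NULL else Acov$K, var_b)

  if (!is.null(env_effects)) {
    h <- as.numeric(env_effects)
    n_envs <- length(h)
    elab <- if (!is.null(names(env_effects))) names(env_effects) else paste0("E", seq_len(n_envs))
  } else {
    if (var_h <= 0) stop("var_h must be positive when env_effects is not given")
    Hcov <- get_K(H, n_envs, "environments")
    elab <- if (is.null(Hcov)) paste0("E", seq_len(n_envs)) else Hcov$labels
    h <- rmvn(n_envs, if (is.null(Hcov)) NULL else Hcov$K, var_h)
  }

  vi <- rep(rep(seq_len(n_lines), each = n_envs), times = replicates)
  ei <- rep(rep(seq_len(n_envs), times = n_lines), times = replicates)
  eps <- if (var_e > 0) rnorm(length(vi), 0, sqrt(var_e)) else 0
  y <- mu + g[vi] + (1 + b[vi]) * h[ei] + eps

  table <- fw_table(VAR = vlab[vi], ENV = elab[ei], y = y)
  truth <- list(mu = mu, g = setNames(g, vlab), b = setNames(b, vlab),
                h = setNames(h, elab),
                var_e = var_e, var_g = var_g, var_b = var_b,
                var_h = if (is.null(env_effects)) var_h else NA_real_,
                design = list(n_lines = n_lines, n_envs = n_envs,
                              replicates = replicates),
                seed = seed)
  list(table = table, truth = truth)
}

#' Mask one observed record per line
#'
#' For each variety, chooses one of its observed records uniformly at
#' random and sets its phenotype to `NA`, producing the train/validation
#' split used to assess prediction accuracy. Every line must be observed
#' in at least two environments.
#'
#' @param table an [fw_table].
#' @param seed integer seed.
#' @return list with `table` (masked copy) and `mask` (row indices of the
#'   masked records).
#' @export
mask_one_env_per_line <- function(table, seed = NULL) {
  stopifnot(inherits(table, "fw_table"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  rec <- table$records
  mask <- integer(0)
  for (v in table$varieties) {
    idx <- which(rec$VAR == v & !is.na(rec$y))
    if (length(unique(rec$ENV[idx])) < 2)
      stop(sprintf("variety %s is observed in fewer than 2 environments", v))
    mask <- c(mask, if (length(idx) == 1) idx else sample(idx, 1))
  }
  rec$y[mask] <- NA_real_
  list(table = fw_table(rec$VAR, rec$ENV, rec$y), mask = mask)
}
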