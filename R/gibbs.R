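# Single-step Bayesian Finlay-Wilkinson regression via Gibbs sampling.
# The cycle-level sampler lives in src/gibbs.cpp; this file handles
# validation, covariance inversion, initialization, multi-chain control
# and assembly of the fit object.

# Invert a PSD covariance matrix; on Cholesky failure add a jitter of
# 1e-8 * mean(diag) once and retry (marker-derived kinships are often
# numerically singular).
.inv_psd <- function(K, label) {
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) {
    jit <- 1e-8 * mean(diag(K))
    message(sprintf("matrix %s is numerically singular; adding jitter %.3g to its diagonal",
                    label, jit))
    ch <- tryCatch(chol(K + diag(jit, nrow(K))),
                   error = function(e) stop(sprintf("cannot invert %s even after jitter", label)))
  }
  chol2inv(ch)
}

.is_diagonal <- function(K) all(K[row(K) != col(K)] == 0)

# Low-level single-chain runner (also used by tests to clamp blocks).
fw_gibbs_chain <- function(frame, hyper, nIter, burnIn, thin,
                           mon_var, mon_env,
                           init = NULL,
                           update = rep(TRUE, 8)) {
  nV <- frame$nV; nE <- frame$nE
  a_diag <- is.null(frame$A) || .is_diagonal(frame$A)
  h_diag <- is.null(frame$H) || .is_diagonal(frame$H)
  if (a_diag) {
    adiag <- if (is.null(frame$A)) rep(1, nV) else 1 / diag(frame$A)
    Ainv <- matrix(0, 1, 1)
  } else {
    adiag <- numeric(nV)
    Ainv <- .inv_psd(frame$A, "A")
  }
  if (h_diag) {
    hdiag <- if (is.null(frame$H)) rep(1, nE) else 1 / diag(frame$H)
    Hinv <- matrix(0, 1, 1)
  } else {
    hdiag <- numeric(nE)
    Hinv <- .inv_psd(frame$H, "H")
  }

  if (is.null(init)) init <- fw_gibbs_init(frame, hyper)

  res <- fw_gibbs_chain_cpp(
    y = ifelse(is.na(frame$y), 0, frame$y),
    vi = frame$vi - 1L, ei = frame$ei - 1L,
    obs = which(frame$obs) - 1L,
    Ainv = Ainv, a_diag = a_diag, adiag = adiag,
    Hinv = Hinv, h_diag = h_diag, hdiag = hdiag,
    hyper = unlist(hyper, use.names = FALSE),
    n_iter = nIter, burn_in = burnIn, thin = thin,
    mu0 = init$mu, g0 = init$g, b0 = init$b, h0 = init$h,
    var0 = init$vars,
    mon_var = mon_var - 1L, mon_env = mon_env - 1L,
    update = update)
  colnames(res$samples) <- c(
    "var_e", "var_g", "var_b", "var_h", "mu",
    if (length(mon_var)) paste0("g[", frame$varieties[mon_var], "]"),
    if (length(mon_var)) paste0("b[", frame$varieties[mon_var], "]"),
    if (length(mon_env)) paste0("h[", frame$environments[mon_env], "]"))
  res
}

# Starting values: mu at the observed mean; g, b at zero; h at centered
# environment means (zero for environments with no observed records);
# variances at their prior expectations.
fw_gibbs_init <- function(frame, hyper) {
  yo <- frame$y[frame$obs]
  mu0 <- if (length(yo)) mean(yo) else 0
  h0 <- numeric(frame$nE)
  for (j in seq_len(frame$nE)) {
    sel <- frame$obs & frame$ei == j
    if (any(sel)) h0[j] <- mean(frame$y[sel]) - mu0
  }
  list(mu = mu0, g = numeric(frame$nV), b = numeric(frame$nV), h = h0,
       vars = c(.prior_mean_var(hyper$df_e, hyper$S2_e),
                .prior_mean_var(hyper$df_g, hyper$S2_g),
                .prior_mean_var(hyper$df_b, hyper$S2_b),
                .prior_mean_var(hyper$df_h, hyper$S2_h)))
}

#' Fit a Finlay-Wilkinson regression
#'
#' Fits the reaction-norm model
#' \eqn{y_{ijk} = \mu + g_i + h_j + b_i h_j + \varepsilon_{ijk}} by either
#' the two-step ordinary-least-squares procedure (`method = "OLS"`) or the
#' single-step Bayesian model fitted by Gibbs sampling (`method =
#' "Gibbs"`, the default). In the Bayesian model the variety intercepts
#' \eqn{g} and slope deviations \eqn{b} have multivariate normal priors
#' with covariance proportional to `A` (a kinship matrix; identity if
#' omitted), the environment effects \eqn{h} have covariance proportional
#' to `H`, and the four variance components carry scaled-inverse-chi-square
#' priors (see [default_hyperparameters()]). Records with missing `y` are
#' excluded from every likelihood contribution but still receive fitted
#' values through the predictor identity, which is what makes masked-entry
#' cross-validation and prediction of unobserved environments possible.
#'
#' @param y numeric phenotypes, `NA` allowed.
#' @param VAR,ENV variety and environment labels (no `NA`).
#' @param method `"Gibbs"` (default) or `"OLS"`.
#' @param A optional variety covariance: a [cov_spec] of kind `"lines"` or
#'   a labeled matrix.
#' @param H optional environment covariance (kind `"environments"`).
#' @param nIter,burnIn,thin Gibbs cycles, discarded cycles, and keep-every
#'   thinning interval. Defaults 5000/3000/5. Posterior summaries use the
#'   thinned post-burn-in draws.
#' @param nChains number of independent chains; estimates from different
#'   chains are returned in different columns.
#' @param seed integer seed; chain-specific seeds are derived from it
#'   deterministically. `NULL` leaves the RNG state alone.
#' @param saveAt optional path prefix; thinned samples are written as one
#'   CSV per chain plus a JSON sidecar (see [write_samples()]).
#' @param saveVAR,saveENV labels of varieties / environments whose `g`,
#'   `b` / `h` draws are stored; default the first two of each.
#' @param hyper optional `fw_hyper` object overriding the default priors.
#' @return An object of class `fw_fit`: a list with the response and
#'   labels, `whichNa`, posterior means `mu`, `g`, `b`, `h`, `yhat` and
#'   matching posterior standard deviations `SD.*` (one column per chain),
#'   variance components `var_e`, `var_g`, `var_b`, `var_h` with `SD.*`
#'   (Gibbs only), `var_e_weighted` (OLS only: within-line residual
#'   variance pooled by residual degrees of freedom), and `samples` (an
#'   `fw_samples` store, Gibbs only).
#' @examples
#' sim <- simulate_fw_table(n_lines = 30, n_envs = 4, seed = 1)
#' fit <- fw(y = sim$table$records$y, VAR = sim$table$records$VAR,
#'           ENV = sim$table$records$ENV, method = "OLS")
#' fit$var_e_weighted
#' @export
fw <- function(y, VAR, ENV, method = c("Gibbs", "OLS"),
               A = NULL, H = NULL,
               nIter = 5000, burnIn = 3000, thin = 5,
               nChains = 1, seed = NULL, saveAt = NULL,
               saveVAR = NULL, saveENV = NULL, hyper = NULL) {
  method <- match.arg(method)
  table <- fw_table(VAR = VAR, ENV = ENV, y = y)
  if (method == "OLS") return(fw_ols(table, A = A, H = H))

  if (table$n_obs < 2) stop("Gibbs method needs at least 2 non-missing phenotypes")
  if (!(burnIn < nIter)) stop("burnIn must be smaller than nIter")
  if (thin < 1) stop("thin must be >= 1")
  if (nChains < 1) stop("nChains must be >= 1")
  frame <- fw_align(table, A = A, H = H)
  if (is.null(hyper)) hyper <- default_hyperparameters(frame$y[frame$obs])
  stopifnot(inherits(hyper, "fw_hyper"))

  pick_monitor <- function(want, all_labels, what) {
    if (is.null(want)) return(seq_len(min(2L, length(all_labels))))
    idx <- match(as.character(want), all_labels)
    if (anyNA(idx)) stop("unknown ", what, " label in monitor list: ",
                         paste(want[is.na(idx)], collapse = ", "))
    idx
  }
  mon_var <- pick_monitor(saveVAR, frame$varieties, "variety")
  mon_env <- pick_monitor(saveENV, frame$environments, "environment")

  if (!is.null(seed)) set.seed(as.integer(seed))
  chain_seeds <- sample.int(.Machine$integer.max - 1L, nChains)

  chains <- vector("list", nChains)
  for (cc in seq_len(nChains)) {
    set.seed(chain_seeds[cc])
    chains[[cc]] <- fw_gibbs_chain(frame, hyper, nIter, burnIn, thin,
                                   mon_var, mon_env)
  }

  col <- function(field) do.call(cbind, lapply(chains, `[[`, field))
  named_row <- function(field, k) {
    v <- vapply(chains, function(ch) ch$var[k], numeric(1))
    setNames(v, paste0("chain", seq_len(nChains)))
  }
  named_row_sd <- function(k) {
    v <- vapply(chains, function(ch) ch$SD.var[k], numeric(1))
    setNames(v, paste0("chain", seq_len(nChains)))
  }
  samples <- structure(
    list(chains = lapply(chains, `[[`, "samples"),
         config = list(nIter = nIter, burnIn = burnIn, thin = thin,
                       seed = seed, chain_seeds = chain_seeds,
                       hyper = unclass(hyper))),
    class = "fw_samples")

  fit <- list(
    y = frame$y, VAR = table$records$VAR, ENV = table$records$ENV,
    whichNa = which(!frame$obs),
    mu = setNames(vapply(chains, `[[`, numeric(1), "mu"),
                  paste0("chain", seq_len(nChains))),
    SD.mu = setNames(vapply(chains, `[[`, numeric(1), "SD.mu"),
                     paste0("chain", seq_len(nChains))),
    g = structure(col("g"), dimnames = list(frame$varieties, NULL)),
    SD.g = structure(col("SD.g"), dimnames = list(frame$varieties, NULL)),
    b = structure(col("b"), dimnames = list(frame$varieties, NULL)),
    SD.b = structure(col("SD.b"), dimnames = list(frame$varieties, NULL)),
    h = structure(col("h"), dimnames = list(frame$environments, NULL)),
    SD.h = structure(col("SD.h"), dimnames = list(frame$environments, NULL)),
    yhat = col("yhat"), SD.yhat = col("SD.yhat"),
    var_e = named_row("var", 1), SD.var_e = named_row_sd(1),
    var_g = named_row("var", 2), SD.var_g = named_row_sd(2),
    var_b = named_row("var", 3), SD.var_b = named_row_sd(3),
    var_h = named_row("var", 4), SD.var_h = named_row_sd(4),
    hyper = hyper, samples = samples, method = "Gibbs",
    config = samples$config)
  class(fit) <- "fw_fit"

  if (!is.null(saveAt)) write_samples(samples, saveAt)
  fit
}

#' @export
print.fw_fit <- function(x, ...) {
  cat(sprintf("Finlay-Wilkinson fit (%s): %d records, %d varieties, %d environments\n",
              x$method, length(x$y), nrow(x$g), nrow(x$h)))
  if (x$method == "Gibbs") {
    cat(sprintf("  chains: %d, kept draws/chain: %d\n",
                length(x$samples$chains), nrow(x$samples$chains[[1]])))
    cat(sprintf("  var_e=%.4g var_g=%.4g var_b=%.4g var_h=%.4g (chain 1)\n",
                x$var_e[1], x$var_g[1], x$var_b[1], x$var_h[1]))
  } else {
    cat(sprintf("  pooled within-line residual variance: %.4g\n", x$var_e_weighted))
  }
  invisible(x)
}

#' Predict from a fitted Finlay-Wilkinson regression
#'
#' Evaluates the predictor identity \eqn{\hat\mu + \hat g_i + \hat h_j +
#' \hat b_i \hat h_j} at the requested variety/environment pairs using the
#' estimates of one chain.
#'
#' @param object an `fw_fit`.
#' @param VAR,ENV label vectors of equal length.
#' @param chain which chain's estimates to use (default 1).
#' @param ... unused.
#' @export
predict.fw_fit <- function(object, VAR, ENV, chain = 1, ...) {
  params <- list(mu = unname(object$mu[chain]),
                 g = setNames(object$g[, chain], rownames(object$g)),
                 b = setNames(object$b[, chain], rownames(object$b)),
                 h = setNames(object$h[, chain], rownames(object$h)))
  fw_predictor(params, VAR, ENV)
}

# ---- sample persistence -----------------------------------------------------

#' Write thinned Gibbs samples to disk
#'
#' One CSV per chain (`<prefix>samples_chain<k>.csv`, header row of
#' parameter names, one thinned draw per row) plus a JSON sidecar
#' (`<prefix>samples_config.json`) recording `nIter`, `burnIn`, `thin`,
#' the seed and the derived chain seeds.
#'
#' @param samples an `fw_samples` object (from `fit$samples`).
#' @param prefix path prefix for the output files.
#' @return the file paths, invisibly.
#' @export
write_samples <- function(samples, prefix) {
  stopifnot(inherits(samples, "fw_samples"))
  paths <- character(0)
  for (cc in seq_along(samples$chains)) {
    p <- paste0(prefix, "samples_chain", cc, ".csv")
    utils::write.csv(as.data.frame(samples$chains[[cc]]), p, row.names = FALSE,
                     quote = FALSE)
    paths <- c(paths, p)
  }
  pj <- paste0(prefix, "samples_config.json")
  jsonlite::write_json(samples$config, pj, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, pj))
}

#' Read thinned Gibbs samples written by [write_samples()]
#' @param prefix the path prefix used when writing.
#' @return an `fw_samples` object.
#' @export
read_samples <- function(prefix) {
  pj <- paste0(prefix, "samples_config.json")
  if (!file.exists(pj)) stop("no sample store found at prefix: ", prefix)
  config <- jsonlite::read_json(pj, simplifyVector = TRUE)
  chains <- list()
  cc <- 1
  repeat {
    p <- paste0(prefix, "samples_chain", cc, ".csv")
    if (!file.exists(p)) break
    m <- as.matrix(utils::read.csv(p, check.names = FALSE))
    chains[[cc]] <- m
    cc <- cc + 1
  }
  if (!length(chains)) stop("no chain files found at prefix: ", prefix)
  structure(list(chains = chains, config = config), class = "fw_samples")
}
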