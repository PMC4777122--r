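# Posterior summaries and MCMC diagnostics: HPD intervals, autocorrelation,
# time-series (Monte Carlo) standard errors, prediction scoring, the
# cross-validation loop, and plot-data extraction for reaction-norm plots.

#' Highest posterior density interval
#'
#' The shortest contiguous window over the sorted draws containing at
#' least `mass` of them (ties broken by the lowest-index window). For a
#' constant chain the interval has zero width.
#'
#' @param draws numeric vector of at least 10 draws.
#' @param mass probability mass in (0, 1); default 0.95.
#' @return named numeric `c(lower, upper)` with attribute `mass`.
#' @export
hpd <- function(draws, mass = 0.95) {
  if (!(mass > 0 && mass < 1)) stop("mass must be in (0, 1)")
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 10) stop("need at least 10 draws")
  x <- sort(draws)
  k <- ceiling(mass * n)
  if (k >= n) k <- n
  starts <- seq_len(n - k + 1)
  widths <- x[starts + k - 1] - x[starts]
  i <- which.min(widths)
  structure(c(lower = x[i], upper = x[i + k - 1]), mass = mass)
}

#' Empirical lag-k autocorrelation
#'
#' Mean-centered autocovariance at the requested lag divided by the lag-0
#' autocovariance, with the biased (1/n) normalization; lag 0 returns 1
#' exactly.
#'
#' @param draws numeric vector.
#' @param lag non-negative integer smaller than `length(draws)`.
#' @export
autocorr <- function(draws, lag = 5) {
  n <- length(draws)
  if (lag < 0 || lag >= n) stop("need 0 <= lag < length(draws)")
  if (lag == 0) return(1)
  xc <- draws - mean(draws)
  c0 <- sum(xc^2) / n
  ck <- sum(xc[seq_len(n - lag)] * xc[seq_len(n - lag) + lag]) / n
  ck / c0
}

#' Time-series standard error of the chain mean
#'
#' Monte Carlo standard error of the sample mean accounting for
#' autocorrelation, estimated by batch means with about \eqn{\sqrt{n}}
#' batches: the draws are cut into `floor(sqrt(n))` consecutive batches of
#' equal size (trailing remainder dropped) and the standard error of the
#' batch means is reported.
#'
#' @param draws numeric vector of at least 100 draws.
#' @export
timeseries_se <- function(draws) {
  n <- length(draws)
  if (n < 100) stop("need at least 100 draws")
  nb <- floor(sqrt(n))
  m <- n %/% nb
  bm <- colMeans(matrix(draws[seq_len(nb * m)], nrow = m))
  sd(bm) / sqrt(nb)
}

#' Correlation between observed and predicted phenotypes on an index set
#'
#' Pearson correlation over the requested record indices, used both for
#' training accuracy (unmasked records) and validation accuracy (masked
#' records). Pairs with a non-finite member are dropped; if fewer than 3
#' finite pairs remain or either side has zero variance the correlation is
#' undefined and `NA` is returned with a warning.
#'
#' @param y_true,yhat numeric vectors of equal length.
#' @param indices record indices to score (default: all).
#' @export
score_predictions <- function(y_true, yhat, indices = seq_along(y_true)) {
  yt <- y_true[indices]; yp <- yhat[indices]
  ok <- is.finite(yt) & is.finite(yp)
  yt <- yt[ok]; yp <- yp[ok]
  if (length(yt) < 3) {
    warning("fewer than 3 finite pairs; correlation undefined")
    return(NA_real_)
  }
  if (sd(yt) == 0 || sd(yp) == 0) {
    warning("zero variance in observations or predictions; correlation undefined")
    return(NA_real_)
  }
  cor(yt, yp)
}

#' Cross-validate prediction accuracy by masking one record per line
#'
#' For each replicate, masks one observed record per variety
#' ([mask_one_env_per_line()]), refits every requested method on the
#' masked table, and scores the Pearson correlation between the held-out
#' truth and the fitted values on both the training (unmasked) and
#' validation (masked) index sets. Methods: `"OLS"`, `"GibbsI"`
#' (independent lines and environments) and `"GibbsA"` (uses `A`).
#'
#' @param table a fully observed [fw_table].
#' @param methods subset of `c("OLS", "GibbsI", "GibbsA")`.
#' @param n_replicates number of random train/validation partitions.
#' @param seed integer seed; replicate masks and chain seeds derive from it.
#' @param A variety covariance, required for `"GibbsA"`.
#' @param H optional environment covariance (used by both Gibbs methods).
#' @param nIter,burnIn,thin Gibbs settings per fit.
#' @return data.frame with columns `replicate`, `method`, `train_cor`,
#'   `valid_cor`; the per-replicate mask indices are attached as attribute
#'   `"masks"`.
#' @export
crossvalidate <- function(table, methods = c("OLS", "GibbsI", "GibbsA"),
                          n_replicates = 10, seed = NULL,
                          A = NULL, H = NULL,
                          nIter = 4000, burnIn = 1500, thin = 5) {
  stopifnot(inherits(table, "fw_table"))
  methods <- match.arg(methods, several.ok = TRUE)
  if ("GibbsA" %in% methods && is.null(A))
    stop("method GibbsA requires a variety covariance matrix A")
  if (!is.null(seed)) set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)

  out <- vector("list", n_replicates * length(methods))
  masks <- vector("list", n_replicates)
  row <- 1
  for (r in seq_len(n_replicates)) {
    mk <- mask_one_env_per_line(table, seed = rep_seeds[r])
    masks[[r]] <- mk$mask
    train_idx <- setdiff(seq_along(table$records$y), mk$mask)
    stopifnot(length(intersect(train_idx, mk$mask)) == 0)
    rec <- mk$table$records
    for (m in methods) {
      fit <- switch(m,
        OLS = fw(y = rec$y, VAR = rec$VAR, ENV = rec$ENV, method = "OLS"),
        GibbsI = fw(y = rec$y, VAR = rec$VAR, ENV = rec$ENV, method = "Gibbs",
                    H = H, nIter = nIter, burnIn = burnIn, thin = thin,
                    seed = rep_seeds[r]),
        GibbsA = fw(y = rec$y, VAR = rec$VAR, ENV = rec$ENV, method = "Gibbs",
                    A = A, H = H, nIter = nIter, burnIn = burnIn, thin = thin,
                    seed = rep_seeds[r]))
      out[[row]] <- data.frame(
        replicate = r, method = m,
        train_cor = score_predictions(table$records$y, fit$yhat[, 1], train_idx),
        valid_cor = score_predictions(table$records$y, fit$yhat[, 1], mk$mask))
      row <- row + 1
    }
  }
  res <- do.call(rbind, out)
  attr(res, "masks") <- masks
  res
}

#' Reaction-norm plot data
#'
#' Extracts what is needed to draw variety-performance-versus-environment
#' plots: per variety the fitted intercept \eqn{\hat\mu + \hat g_i} and
#' slope \eqn{1 + \hat b_i} (so a variety with \eqn{b_i = 0} has slope
#' exactly 1, the usual dashed reference line), and per observed
#' variety-environment cell the mean phenotype together with the
#' estimated environment effect as the x coordinate.
#'
#' @param fit an `fw_fit`.
#' @param chain which chain's estimates to use.
#' @return list with `lines` (data.frame `VAR`, `intercept`, `slope`) and
#'   `cells` (data.frame `VAR`, `ENV`, `h`, `cell_mean`).
#' @export
fitted_lines <- function(fit, chain = 1) {
  stopifnot(inherits(fit, "fw_fit"))
  mu <- unname(if (fit$method == "Gibbs") fit$mu[chain] else fit$mu)
  lines <- data.frame(VAR = rownames(fit$g),
                      intercept = mu + fit$g[, chain],
                      slope = 1 + fit$b[, chain],
                      row.names = NULL)
  obs <- data.frame(VAR = fit$VAR, ENV = fit$ENV, y = fit$y)
  obs <- obs[!is.na(obs$y), , drop = FALSE]
  cells <- aggregate(y ~ VAR + ENV, data = obs, FUN = mean)
  names(cells)[names(cells) == "y"] <- "cell_mean"
  cells$h <- fit$h[cells$ENV, chain]
  cells <- cells[, c("VAR", "ENV", "h", "cell_mean")]
  list(lines = lines, cells = cells)
}

#' Summarize a Gibbs sample store
#'
#' Per monitored parameter and chain: posterior mean, SD, time-series
#' standard error of the mean, lag-`lag` autocorrelation, and the
#' `mass`-HPD interval.
#'
#' @param object an `fw_samples` store.
#' @param mass HPD mass (default 0.95).
#' @param lag autocorrelation lag (default 5).
#' @param ... unused.
#' @return data.frame with one row per chain and parameter.
#' @export
summary.fw_samples <- function(object, mass = 0.95, lag = 5, ...) {
  rows <- list()
  for (cc in seq_along(object$chains)) {
    m <- object$chains[[cc]]
    for (p in colnames(m)) {
      x <- m[, p]
      iv <- hpd(x, mass)
      rows[[length(rows) + 1]] <- data.frame(
        chain = cc, param = p, mean = mean(x), sd = sd(x),
        ts_se = if (length(x) >= 100) timeseries_se(x) else NA_real_,
        autocorr = if (length(x) > lag) autocorr(x, lag) else NA_real_,
        hpd_lower = iv[["lower"]], hpd_upper = iv[["upper"]])
    }
  }
  do.call(rbind, rows)
}
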