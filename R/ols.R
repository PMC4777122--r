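# Two-step ordinary least squares Finlay-Wilkinson regression.
#
# Step 1 fits the additive model y = mu + g_i + h_j + e by least squares
# under sum-to-zero constraints on g and h (bordered normal equations).
# Step 2 regresses, separately within each line, the observed phenotypes
# on the step-1 environment effects; the slope is 1 + b_i.

# Union-find connectivity of the variety-environment incidence graph over
# observed records. Returns component id per node (varieties then envs).
.incidence_components <- function(vi, ei, nV, nE) {
  parent <- seq_len(nV + nE)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(vi)) {
    a <- find(vi[k]); b <- find(nV + ei[k])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(nV + nE), find, integer(1))
}

#' Step 1: constrained main-effects least squares
#'
#' Fits \eqn{y = \mu + g_i + h_j + \varepsilon} by ordinary least squares
#' over the non-missing records, under the constraints
#' \eqn{\sum_i g_i = 0} and \eqn{\sum_j h_j = 0}, via the bordered
#' (Lagrange) normal equations solved densely. On a complete balanced
#' design this reduces to \eqn{\hat h_j =} environment mean minus grand
#' mean.
#'
#' @param frame model frame from [fw_align()].
#' @return list with `mu`, `g` (named, over varieties), `h` (named, over
#'   environments).
#' @export
fit_main_effects <- function(frame) {
  obs <- frame$obs
  if (!any(obs)) stop("no non-missing records")
  vi <- frame$vi[obs]; ei <- frame$ei[obs]; y <- frame$y[obs]
  nV <- frame$nV; nE <- frame$nE

  no_obs_env <- setdiff(seq_len(nE), unique(ei))
  if (length(no_obs_env))
    stop("environment(s) with no non-missing records: ",
         paste(frame$environments[no_obs_env], collapse = ", "))
  no_obs_var <- setdiff(seq_len(nV), unique(vi))
  if (length(no_obs_var))
    stop("variety(ies) with no non-missing records: ",
         paste(frame$varieties[no_obs_var], collapse = ", "))

  comp <- .incidence_components(vi, ei, nV, nE)
  if (length(unique(comp)) > 1L) {
    tab <- split(seq_len(nV + nE), comp)
    small <- tab[[which.min(lengths(tab))]]
    labs <- c(frame$varieties, frame$environments)[small]
    stop("variety/environment incidence is disconnected; one component is: ",
         paste(labs, collapse = ", "))
  }

  # normal equations for beta = (mu, g, h), assembled from counts
  n <- length(y)
  nv <- tabulate(vi, nV)                        # records per variety
  ne <- tabulate(ei, nE)                        # records per environment
  Nve <- matrix(0, nV, nE)                      # incidence counts
  for (k in seq_len(n)) Nve[vi[k], ei[k]] <- Nve[vi[k], ei[k]] + 1
  p <- 1L + nV + nE
  M <- matrix(0, p, p)
  M[1, 1] <- n
  M[1, 1 + seq_len(nV)] <- nv; M[1 + seq_len(nV), 1] <- nv
  M[1, 1 + nV + seq_len(nE)] <- ne; M[1 + nV + seq_len(nE), 1] <- ne
  M[1 + seq_len(nV), 1 + seq_len(nV)] <- diag(nv, nV)
  M[1 + nV + seq_len(nE), 1 + nV + seq_len(nE)] <- diag(ne, nE)
  M[1 + seq_len(nV), 1 + nV + seq_len(nE)] <- Nve
  M[1 + nV + seq_len(nE), 1 + seq_len(nV)] <- t(Nve)
  rhs <- c(sum(y),
           vapply(seq_len(nV), function(i) sum(y[vi == i]), numeric(1)),
           vapply(seq_len(nE), function(j) sum(y[ei == j]), numeric(1)))

  # border with the two sum-to-zero constraints
  C <- rbind(c(0, rep(1, nV), rep(0, nE)),
             c(0, rep(0, nV), rep(1, nE)))
  K <- rbind(cbind(M, t(C)), cbind(C, matrix(0, 2, 2)))
  sol <- tryCatch(solve(K, c(rhs, 0, 0)),
                  error = function(e) stop("constrained normal equations are singular: ",
                                           conditionMessage(e)))
  list(mu = sol[1],
       g = setNames(sol[1 + seq_len(nV)], frame$varieties),
       h = setNames(sol[1 + nV + seq_len(nE)], frame$environments))
}

#' Step 2: within-line regression on estimated environment effects
#'
#' For each line, ordinary least squares of its non-missing phenotypes on
#' the step-1 environment effects, with an intercept and no global mean
#' (the intercept therefore estimates \eqn{\mu + g_i}); the slope is
#' \eqn{1 + b_i}. Lines observed at fewer than two distinct environment
#' effects cannot support a slope: their `b` is set to 0, the intercept to
#' the line mean minus the mean environment effect at its records, and
#' they contribute nothing to the pooled residual variance (status
#' `"degenerate"`).
#'
#' @param frame model frame from [fw_align()].
#' @param h_hat named environment-effect vector from [fit_main_effects()].
#' @return list with `intercept` (named, estimates \eqn{\mu + g_i}), `b`
#'   (named slope deviations), `pooled_resid_var` (residual sums of
#'   squares pooled over lines, divided by the summed residual degrees of
#'   freedom \eqn{n_i - 2}), `status` (per-line `"ok"`/`"degenerate"`),
#'   `rss`, `df`.
#' @export
fit_within_line <- function(frame, h_hat) {
  nV <- frame$nV
  intercept <- numeric(nV); b <- numeric(nV)
  rss <- numeric(nV); df <- numeric(nV)
  status <- rep("ok", nV)
  for (i in seq_len(nV)) {
    sel <- frame$obs & frame$vi == i
    ys <- frame$y[sel]
    xs <- unname(h_hat[frame$ei[sel]])
    if (length(unique(xs)) < 2L) {
      status[i] <- "degenerate"
      b[i] <- 0
      intercept[i] <- mean(ys) - mean(xs)
      next
    }
    xb <- mean(xs); yb <- mean(ys)
    slope <- sum((xs - xb) * (ys - yb)) / sum((xs - xb)^2)
    a <- yb - slope * xb
    res <- ys - a - slope * xs
    intercept[i] <- a
    b[i] <- slope - 1
    rss[i] <- sum(res^2)
    df[i] <- length(ys) - 2
  }
  tot_df <- sum(df)
  list(intercept = setNames(intercept, frame$varieties),
       b = setNames(b, frame$varieties),
       pooled_resid_var = if (tot_df > 0) sum(rss) / tot_df else 0,
       status = setNames(status, frame$varieties),
       rss = setNames(rss, frame$varieties),
       df = setNames(df, frame$varieties))
}

# Compose the two steps into an fw_fit (one column per estimate).
fw_ols <- function(table, A = NULL, H = NULL) {
  frame <- fw_align(table, A = A, H = H)
  s1 <- fit_main_effects(frame)
  s2 <- fit_within_line(frame, s1$h)
  mu <- s1$mu
  g <- s2$intercept - mu
  b <- s2$b
  h <- s1$h
  yhat <- mu + g[frame$vi] + (1 + b[frame$vi]) * h[frame$ei]
  fit <- list(y = frame$y, VAR = table$records$VAR, ENV = table$records$ENV,
              whichNa = which(!frame$obs),
              mu = setNames(mu, "mu"),
              g = matrix(g, ncol = 1, dimnames = list(frame$varieties, NULL)),
              b = matrix(b, ncol = 1, dimnames = list(frame$varieties, NULL)),
              h = matrix(unname(h), ncol = 1, dimnames = list(frame$environments, NULL)),
              yhat = matrix(unname(yhat), ncol = 1),
              var_e_weighted = s2$pooled_resid_var,
              within_line_status = s2$status,
              method = "OLS")
  class(fit) <- "fw_fit"
  fit
}
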