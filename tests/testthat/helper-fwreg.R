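# Fixture builders and independent oracles used across the suite.

# Random full-factorial table with optional replicates and missing cells.
# Environment E1 of every line is always kept observed so the
# variety-environment incidence graph stays connected.
rand_table <- function(n_lines, n_envs, miss_frac = 0, replicates = 1,
                       seed = 1) {
  set.seed(seed)
  vi <- rep(rep(seq_len(n_lines), each = n_envs), replicates)
  ei <- rep(rep(seq_len(n_envs), times = n_lines), replicates)
  y <- rnorm(length(vi), 5, 2)
  if (miss_frac > 0) {
    cand <- which(ei != 1L)
    drop <- sample(cand, floor(miss_frac * length(cand)))
    y[drop] <- NA
  }
  fw_table(paste0("L", vi), paste0("E", ei), y)
}

# Independent constrained-least-squares oracle for the additive model
# y = mu + g_i + h_j with sum-to-zero g and h: fit by lm() with sum
# contrasts (a different route than the bordered normal equations).
ols_step1_oracle <- function(table) {
  rec <- table$records[!is.na(table$records$y), , drop = FALSE]
  V <- factor(rec$VAR, levels = table$varieties)
  E <- factor(rec$ENV, levels = table$environments)
  fit <- lm(rec$y ~ V + E, contrasts = list(V = "contr.sum", E = "contr.sum"))
  cf <- coef(fit)
  nV <- nlevels(V); nE <- nlevels(E)
  g <- cf[1 + seq_len(nV - 1)]
  h <- cf[nV + seq_len(nE - 1)]
  list(mu = unname(cf[1]),
       g = setNames(c(unname(g), -sum(g)), levels(V)),
       h = setNames(c(unname(h), -sum(h)), levels(E)))
}

# Per-line simple-regression oracle for step two (lm route).
ols_step2_oracle <- function(table, h_hat) {
  rec <- table$records[!is.na(table$records$y), , drop = FALSE]
  out <- lapply(table$varieties, function(v) {
    d <- rec[rec$VAR == v, , drop = FALSE]
    x <- unname(h_hat[d$ENV])
    if (length(unique(x)) < 2) return(NULL)
    f <- lm(d$y ~ x)
    list(VAR = v, intercept = unname(coef(f)[1]), b = unname(coef(f)[2]) - 1,
         rss = sum(resid(f)^2), df = nrow(d) - 2)
  })
  out[!vapply(out, is.null, logical(1))]
}

# Closed-form conditional of a Gaussian block with precision
# P = diag(D)/ve + Kinv/vu and location P^{-1} r/ve.
conditional_normal <- function(D, Kinv, r, ve, vu) {
  P <- diag(D, length(D)) / ve + Kinv / vu
  S <- solve(P)
  list(mean = drop(S %*% r) / ve, cov = S)
}

# Build an aligned frame plus explicit hyperparameters for low-level
# single-chain runs (used to clamp parameter blocks).
clamped_setup <- function(table, A = NULL, H = NULL, hyper = NULL) {
  frame <- fw_align(table, A = A, H = H)
  if (is.null(hyper)) hyper <- default_hyperparameters(frame$y[frame$obs])
  list(frame = frame, hyper = hyper)
}
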