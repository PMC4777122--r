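#' Default prior hyperparameters for the Bayesian model
#'
#' Each variance component carries a scaled-inverse-chi-square prior
#' \eqn{\chi^{-2}(\nu, S^2)} with prior mean \eqn{\nu S^2/(\nu-2)} for
#' \eqn{\nu > 2}. By default all four degrees of freedom are 5 and the
#' scales are chosen so that the prior expectations partition the sample
#' variance of the observed phenotypes:
#' \eqn{E[\sigma^2_\varepsilon] = 0.5\,\mathrm{Var}(y)},
#' \eqn{E[\sigma^2_g] = E[\sigma^2_b] = 0.25\,\mathrm{Var}(y)},
#' \eqn{E[\sigma^2_h] = 0.5\,\mathrm{Var}(y)} (deliberately generous for
#' the environment effects, whose posterior is typically wide when only a
#' handful of environments are observed). Hence
#' \eqn{S^2 = E \cdot (\nu - 2)/\nu}. Any user-supplied value overrides
#' the corresponding default; degrees of freedom of 2 or below are
#' accepted (the prior then has no finite mean) with a warning.
#'
#' @param y_obs numeric vector of non-missing phenotypes (at least 2, with
#'   positive variance).
#' @param df_e,S2_e,df_g,S2_g,df_b,S2_b,df_h,S2_h optional overrides.
#' @return object of class `fw_hyper`: named list of the eight values.
#' @export
default_hyperparameters <- function(y_obs,
                                    df_e = NULL, S2_e = NULL,
                                    df_g = NULL, S2_g = NULL,
                                    df_b = NULL, S2_b = NULL,
                                    df_h = NULL, S2_h = NULL) {
  y_obs <- y_obs[!is.na(y_obs)]
  if (length(y_obs) < 2) stop("need at least 2 non-missing phenotypes")
  vy <- stats::var(y_obs)
  if (vy <= 0) stop("phenotypes have zero variance; cannot set default priors")
  r2 <- c(e = 0.5, g = 0.25, b = 0.25, h = 0.5)
  pick_df <- function(x) if (is.null(x)) 5 else x
  pick_S2 <- function(x, df, share) {
    if (!is.null(x)) return(x)
    # S2 = E * (df - 2) / df targets prior mean E; for df <= 2 the prior
    # mean is undefined, so the scale falls back to the share itself
    unname(share * vy * if (df > 2) (df - 2) / df else 1)
  }
  hp <- list(df_e = pick_df(df_e), df_g = pick_df(df_g),
             df_b = pick_df(df_b), df_h = pick_df(df_h))
  hp$S2_e <- pick_S2(S2_e, hp$df_e, r2["e"])
  hp$S2_g <- pick_S2(S2_g, hp$df_g, r2["g"])
  hp$S2_b <- pick_S2(S2_b, hp$df_b, r2["b"])
  hp$S2_h <- pick_S2(S2_h, hp$df_h, r2["h"])
  hp <- hp[c("df_e", "S2_e", "df_g", "S2_g", "df_b", "S2_b", "df_h", "S2_h")]
  if (any(unlist(hp) <= 0)) stop("all degrees of freedom and scales must be > 0")
  low <- unlist(hp[c("df_e", "df_g", "df_b", "df_h")]) <= 2
  if (any(low))
    warning("prior degrees of freedom <= 2 for: ",
            paste(sub("df_", "", names(low)[low]), collapse = ", "),
            " (prior variance expectation is not finite; the sampler is still proper)")
  structure(hp, class = "fw_hyper")
}

# Prior expectation E[sigma^2] = df*S2/(df-2); used for initial values.
.prior_mean_var <- function(df, S2) if (df > 2) df * S2 / (df - 2) else S2
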