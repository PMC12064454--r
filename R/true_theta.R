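#' Generator-implied free-parameter vector for a model
#'
#' Maps a generator parameter set onto the free parameters of a model
#' specification, giving the data-generating truth for that model. Used for
#' moment-matching checks, parameter-recovery simulations and coverage
#' experiments. For the binary adherence indicator the structural paths are
#' zero (the generator draws adherence independently of the latents) and its
#' variance is the Bernoulli variance of the target adherent fraction.
#'
#' @param model a [cfm_model()] without covariates.
#' @param gp a [cfm_gen_params()].
#' @return named numeric vector over the model's free parameters.
#' @export
true_theta <- function(model, gp) {
  if (length(model$covariates)) {
    stop("true_theta is defined for models without covariates")
  }
  pt <- model$partable[model$partable$free, , drop = FALSE]
  path_val <- function(level, kind, target) {
    paths <- if (level == "within") gp$paths_within else gp$paths_between
    key <- sub("_(PLWH|partner)$", "", target)
    role <- if (grepl("_(PLWH|partner)$", target)) {
      sub("^.*_(PLWH|partner)$", "\\1", target)
    }
    key <- switch(key,
                  qol = "qol", rs_shared = "rs", post_qol = "post_qol",
                  prep_attitude = "prep", rs_post_shared = "post_rs",
                  adherent = "adherent", key)
    if (key == "adherent") return(0)
    v <- paths[[key]][[kind]]
    if (!is.null(role) && length(v) > 1) v <- v[[role]]
    v
  }
  s_val <- function(level, v) {
    lat <- c(wda_shared = "wda", cdc_shared = "cdc", rs_shared = "rs",
             rs_post_shared = "post_rs")
    if (v == "wda_shared") return(gp$latent_var[[level]][["wda"]])
    if (v %in% names(lat)) return(gp$disturbance_var[[level]][[lat[[v]]]])
    if (v == "adherent") return(gp$adherent_frac * (1 - gp$adherent_frac))
    if (v %in% names(gp$resid_var[[level]])) return(gp$resid_var[[level]][[v]])
    if (v %in% names(gp$resid_var$post)) return(gp$resid_var$post[[v]])
    stop("no generator variance for ", v, " at level ", level)
  }
  mu_val <- function(v) {
    if (v == "adherent") return(gp$adherent_frac)
    if (v %in% names(gp$means$daily)) return(gp$means$daily[[v]])
    if (v %in% names(gp$means$post)) return(gp$means$post[[v]])
    stop("no generator mean for ", v)
  }
  th <- numeric(nrow(pt))
  names(th) <- pt$label
  for (k in seq_len(nrow(pt))) {
    th[k] <- if (pt$level[k] == "mean") {
      mu_val(pt$row[k])
    } else if (pt$mat[k] == "A") {
      kind <- substr(pt$label[k], 1, 1)
      if (kind == "a") {
        if (pt$level[k] == "within") gp$a_within else gp$a_between
      } else {
        path_val(pt$level[k], kind, pt$row[k])
      }
    } else {
      s_val(pt$level[k], pt$row[k])
    }
  }
  th
}
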