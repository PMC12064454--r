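#' Default study profile for the synthetic diary generator
#'
#' The marginal targets the generator is calibrated against: per-variable,
#' per-role means, standard deviations, intraclass correlations, and
#' level-specific standardized loadings for the common-fate constructs, plus
#' the post-diary outcome distributions. These describe a 14-day dyadic diary
#' study of 141 HIV-serodiscordant male couples (one partner living with HIV,
#' one HIV-negative) with daily 7-point items for we-disease appraisal (WDA,
#' 0-6), common dyadic coping (CDC, 0-30), quality of life (QoL, 0-6) and
#' relationship satisfaction (RS, 0-6), and a one-off post-diary assessment.
#'
#' @return a list with `daily` and `post` data frames and a `paths` list of
#'   structural coefficients at the within and between levels.
#' @export
study_profile <- function() {
  daily <- data.frame(
    var      = rep(c("wda", "cdc", "qol", "rs"), each = 2),
    role     = rep(c("PLWH", "partner"), 4),
    mean     = c(4.04, 4.14, 17.32, 17.78, 4.39, 4.41, 4.42, 4.39),
    sd       = c(1.81, 1.66, 8.14, 7.42, 1.34, 1.30, 1.43, 1.33),
    icc      = c(0.83, 0.83, 0.68, 0.70, 0.58, 0.60, 0.58, 0.64),
    lambda_w = c(0.38, 0.41, 0.49, 0.56, NA, NA, 0.45, 0.52),
    lambda_b = c(0.63, 0.69, 0.61, 0.65, NA, NA, 0.61, 0.64),
    stringsAsFactors = FALSE
  )
  post <- data.frame(
    var      = c("post_qol", "post_qol", "prep", "post_rs", "post_rs"),
    role     = c("PLWH", "partner", "partner", "PLWH", "partner"),
    mean     = c(67.06, 56.33, 14.77, 14.06, 14.16),
    sd       = c(16.33, 16.50, 3.98, 4.14, 3.94),
    lambda_b = c(NA, NA, NA, 0.60, 0.63),
    stringsAsFactors = FALSE
  )
  paths <- list(
    a_within = 4.78,
    a_between = 2.08,
    within = list(
      qol = list(b = c(PLWH = 0.07, partner = 0.10),
                 c = c(PLWH = 0.37, partner = -0.02)),
      rs  = list(b = 0.11, c = 0.54)
    ),
    between = list(
      qol      = list(b = c(PLWH = 0.01, partner = 0.02),
                      c = c(PLWH = 0.23, partner = 0.45)),
      rs       = list(b = 0.04, c = 0.37),
      post_qol = list(b = c(PLWH = 0.65, partner = 0.48),
                      c = c(PLWH = 3.84, partner = 6.20)),
      prep     = list(b = 0.11, c = 1.17),
      post_rs  = list(b = 0.15, c = 1.06)
    )
  )
  list(daily = daily, post = post, paths = paths)
}

# variance calibration: solve latent, disturbance and residual variances from
# the profile's SD / ICC / standardized-loading targets, given the structural
# paths. Loadings are fixed at 1 (common fate identification), so a latent's
# total variance is lambda_std^2 * level-variance of its indicator; where the
# two partners imply slightly different values the mean is taken and the
# remainder is absorbed by role-specific residuals.
solve_gen_variances <- function(profile, a_within, a_between) {
  d <- profile$daily
  key <- function(v, r) which(d$var == v & d$role == r)
  lv <- function(v, r, level) {
    i <- key(v, r)
    if (level == "within") (1 - d$icc[i]) * d$sd[i]^2 else d$icc[i] * d$sd[i]^2
  }
  lam <- function(v, r, level) {
    i <- key(v, r)
    if (level == "within") d$lambda_w[i] else d$lambda_b[i]
  }
  roles <- c("PLWH", "partner")
  out <- list()
  for (level in c("within", "between")) {
    a <- if (level == "within") a_within else a_between
    pw <- profile$paths[[level]]
    # exogenous shared-appraisal latent
    phi <- mean(vapply(roles, function(r) lam("wda", r, level)^2 * lv("wda", r, level), 0))
    # shared-coping latent: total variance from loadings, disturbance from a
    v_cdc <- mean(vapply(roles, function(r) lam("cdc", r, level)^2 * lv("cdc", r, level), 0))
    psi_cdc <- v_cdc - a^2 * phi
    cov_wc <- a * phi
    explained <- function(cc, bb) cc^2 * phi + bb^2 * v_cdc + 2 * cc * bb * cov_wc
    # shared daily relationship-satisfaction latent
    v_rs <- mean(vapply(roles, function(r) lam("rs", r, level)^2 * lv("rs", r, level), 0))
    psi_rs <- v_rs - explained(pw$rs$c, pw$rs$b)
    resid <- c(
      setNames(vapply(roles, function(r) lv("wda", r, level) - phi, 0),
               paste0("wda_", roles)),
      setNames(vapply(roles, function(r) lv("cdc", r, level) - v_cdc, 0),
               paste0("cdc_", roles)),
      setNames(vapply(roles, function(r) {
        lv("qol", r, level) - explained(pw$qol$c[[r]], pw$qol$b[[r]])
      }, 0), paste0("qol_", roles)),
      setNames(vapply(roles, function(r) lv("rs", r, level) - v_rs, 0),
               paste0("rs_", roles))
    )
    out[[level]] <- list(
      phi = phi, v_cdc = v_cdc, psi_cdc = psi_cdc,
      v_rs = v_rs, psi_rs = psi_rs, resid = resid
    )
  }
  # post-diary outcomes hang off the between-level latents only
  p <- profile$post
  bw <- out$between
  pb <- profile$paths$between
  expl_b <- function(cc, bb) {
    cc^2 * bw$phi + bb^2 * bw$v_cdc + 2 * cc * bb * a_between * bw$phi
  }
  pk <- function(v, r) which(p$var == v & p$role == r)
  v_post_rs <- mean(vapply(roles, function(r) {
    p$lambda_b[pk("post_rs", r)]^2 * p$sd[pk("post_rs", r)]^2
  }, 0))
  psi_post_rs <- v_post_rs - expl_b(pb$post_rs$c, pb$post_rs$b)
  post_resid <- c(
    post_qol_PLWH = p$sd[pk("post_qol", "PLWH")]^2 -
      expl_b(pb$post_qol$c[["PLWH"]], pb$post_qol$b[["PLWH"]]),
    post_qol_partner = p$sd[pk("post_qol", "partner")]^2 -
      expl_b(pb$post_qol$c[["partner"]], pb$post_qol$b[["partner"]]),
    prep_attitude = p$sd[pk("prep", "partner")]^2 -
      expl_b(pb$prep$c, pb$prep$b),
    post_rs_PLWH = p$sd[pk("post_rs", "PLWH")]^2 - v_post_rs,
    post_rs_partner = p$sd[pk("post_rs", "partner")]^2 - v_post_rs
  )
  list(within = out$within, between = out$between,
       v_post_rs = v_post_rs, psi_post_rs = psi_post_rs, post_resid = post_resid)
}

#' Parameters of the synthetic dyadic-diary generator
#'
#' Builds a fully resolved generator parameter set. Defaults encode the study
#' conditions the package emulates: 141 dyads observed for 14 days with two
#' partner roles, a two-level common fate covariance structure whose
#' intraclass correlations, structural paths and marginal moments match the
#' default [study_profile()], 4.4% person-day records missing completely at
#' random, and 14.9% of people living with HIV taking ART on more than 28 of
#' the last 30 days.
#'
#' Variance components are solved from the profile's SDs, ICCs and
#' standardized loadings given the structural paths (see
#' `solve_gen_variances`); both partners' loadings on each shared latent are
#' fixed at 1, so unequal standardized loadings arise from unequal residual
#' variances.
#'
#' @param n_dyads number of couples.
#' @param n_days diary length in days.
#' @param missing_rate probability a person-day record is absent (MCAR).
#' @param a_within,a_between structural path from the shared we-disease
#'   appraisal latent to the shared dyadic-coping latent at each level.
#' @param adherent_frac target fraction of dyads with adherence > 28 days.
#' @param likert if `TRUE`, round and clip scores to their integer scale
#'   ranges; the default keeps scores continuous (latent-normal), matching
#'   the estimator's distributional assumption.
#' @param seed default seed used by [generate_panel()] when none is passed.
#' @param icc_override optional named list, e.g. `list(wda = c(PLWH = 0.5,
#'   partner = 0.5))`, replacing profile ICCs before calibration.
#' @param profile marginal targets, see [study_profile()].
#' @return an object of class `cfm_gen_params`.
#' @export
#' @examples
#' gp <- cfm_gen_params(n_dyads = 10, n_days = 3, missing_rate = 0)
#' gp$latent_var$within
cfm_gen_params <- function(n_dyads = 141, n_days = 14, missing_rate = 0.044,
                           a_within = NULL, a_between = NULL,
                           adherent_frac = 0.149, likert = FALSE, seed = NULL,
                           icc_override = NULL, profile = study_profile()) {
  if (!is.null(icc_override)) {
    for (v in names(icc_override)) {
      for (r in names(icc_override[[v]])) {
        i <- which(profile$daily$var == v & profile$daily$role == r)
        if (!length(i)) stop("unknown icc_override entry: ", v, "/", r)
        profile$daily$icc[i] <- icc_override[[v]][[r]]
      }
    }
  }
  a_within <- a_within %||% profile$paths$a_within
  a_between <- a_between %||% profile$paths$a_between
  vc <- solve_gen_variances(profile, a_within, a_between)
  d <- profile$daily
  p <- profile$post
  gp <- structure(class = "cfm_gen_params", list(
    n_dyads = n_dyads, n_days = n_days, missing_rate = missing_rate,
    a_within = a_within, a_between = a_between,
    paths_within = profile$paths$within,
    paths_between = profile$paths$between,
    latent_var = list(
      within = c(wda = vc$within$phi, cdc = vc$within$v_cdc, rs = vc$within$v_rs),
      between = c(wda = vc$between$phi, cdc = vc$between$v_cdc,
                  rs = vc$between$v_rs, post_rs = vc$v_post_rs)
    ),
    disturbance_var = list(
      within = c(cdc = vc$within$psi_cdc, rs = vc$within$psi_rs),
      between = c(cdc = vc$between$psi_cdc, rs = vc$between$psi_rs,
                  post_rs = vc$psi_post_rs)
    ),
    resid_var = list(within = vc$within$resid, between = vc$between$resid,
                     post = vc$post_resid),
    means = list(
      daily = setNames(d$mean, paste0(d$var, "_", d$role)),
      post = c(post_qol_PLWH = p$mean[1], post_qol_partner = p$mean[2],
               prep_attitude = p$mean[3], post_rs_PLWH = p$mean[4],
               post_rs_partner = p$mean[5])
    ),
    var_within = setNames((1 - d$icc) * d$sd^2, paste0(d$var, "_", d$role)),
    var_between = setNames(d$icc * d$sd^2, paste0(d$var, "_", d$role)),
    adherent_frac = adherent_frac, likert = likert, seed = seed
  ))
  validate_gen_params(gp)
  gp
}

#' Validate generator parameters
#'
#' Checks the structural invariants: positive variance components (which
#' guarantees positive-definite implied covariance matrices at both levels,
#' since loadings are fixed and all disturbances are independent), admissible
#' missingness rate and design sizes, and a between-level share of total
#' variance strictly inside (0, 1) for every indicator.
#'
#' @param gp a `cfm_gen_params` object.
#' @return `gp`, invisibly; errors if any invariant fails.
#' @export
validate_gen_params <- function(gp) {
  stopifnot(inherits(gp, "cfm_gen_params"))
  if (gp$n_dyads < 2) stop("n_dyads must be >= 2")
  if (gp$n_days < 1) stop("n_days must be >= 1")
  if (gp$missing_rate < 0 || gp$missing_rate > 1) {
    stop("missing_rate must be in [0, 1]")
  }
  if (gp$adherent_frac <= 0 || gp$adherent_frac >= 1) {
    stop("adherent_frac must be in (0, 1)")
  }
  vars <- c(unlist(gp$latent_var), unlist(gp$disturbance_var),
            unlist(gp$resid_var))
  bad <- vars[!is.finite(vars) | vars <= 0]
  if (length(bad)) {
    stop("non-positive variance component(s): ",
         paste(names(bad), collapse = ", "),
         " - implied covariance would not be positive definite")
  }
  share <- gp$var_between / (gp$var_between + gp$var_within)
  if (any(share <= 0 | share >= 1)) {
    stop("implied between-level variance share must lie in (0, 1)")
  }
  invisible(gp)
}

#' @export
print.cfm_gen_params <- function(x, ...) {
  cat("<cfm_gen_params>\n")
  cat(sprintf("  design: %d dyads x %d days x 2 roles, missing rate %.3f\n",
              x$n_dyads, x$n_days, x$missing_rate))
  cat(sprintf("  a (WDA_shared -> CDC_shared): within %.2f, between %.2f\n",
              x$a_within, x$a_between))
  cat(sprintf("  latent variances within: %s\n",
              paste(sprintf("%s=%.3f", names(x$latent_var$within),
                            x$latent_var$within), collapse = ", ")))
  cat(sprintf("  latent variances between: %s\n",
              paste(sprintf("%s=%.3f", names(x$latent_var$between),
                            x$latent_var$between), collapse = ", ")))
  invisible(x)
}

#' Write / read generator parameters as a config file
#'
#' Round-trips a `cfm_gen_params` object through JSON or YAML (chosen by file
#' extension). Only the resolved numeric content is stored; reading restores
#' an identical object.
#'
#' @param gp a `cfm_gen_params` object.
#' @param path output file ending in `.json`, `.yaml` or `.yml`.
#' @return `write_gen_params` returns `path` invisibly; `read_gen_params`
#'   returns the restored `cfm_gen_params`.
#' @export
write_gen_params <- function(gp, path) {
  stopifnot(inherits(gp, "cfm_gen_params"))
  # named numeric vectors must become named lists, or the serializers drop
  # the names
  listify <- function(z) {
    if (is.numeric(z) && !is.null(names(z))) as.list(z)
    else if (is.list(z)) lapply(z, listify)
    else z
  }
  x <- listify(unclass(gp))
  if (grepl("\\.(yaml|yml)$", path)) {
    yaml::write_yaml(x, path, precision = 15)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    stop("unsupported config extension: ", path)
  }
  invisible(path)
}

#' @rdname write_gen_params
#' @export
read_gen_params <- function(path) {
  x <- if (grepl("\\.(yaml|yml)$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config extension: ", path)
  }
  # restore named numeric vectors that serializers return as named lists;
  # path blocks keep their list(b =, c =) structure with vector-or-scalar
  # leaves
  renum <- function(z) if (is.list(z)) unlist(z) else z
  for (f in c("latent_var", "disturbance_var", "resid_var", "means")) {
    x[[f]] <- lapply(x[[f]], renum)
  }
  for (f in c("var_within", "var_between")) x[[f]] <- renum(x[[f]])
  for (f in c("paths_within", "paths_between")) {
    x[[f]] <- lapply(x[[f]], function(node) lapply(node, renum))
  }
  for (f in c("n_dyads", "n_days", "missing_rate", "a_within", "a_between",
              "adherent_frac")) {
    x[[f]] <- as.numeric(x[[f]])
  }
  x$likert <- isTRUE(x$likert)
  gp <- structure(x, class = "cfm_gen_params")
  validate_gen_params(gp)
  gp
}
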