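#' Outcome models available for the common fate mediation analysis
#'
#' @return character vector of the six recognized outcome models.
#' @export
cfm_outcomes <- function() {
  c("daily_qol", "post_qol", "post_adherence", "post_prep",
    "daily_rs", "post_rs")
}

pt_row <- function(label, level, mat, row, col, free, value = NA_real_,
                   transform = "identity") {
  data.frame(label = label, level = level, mat = mat, row = row, col = col,
             free = free, value = value, transform = transform,
             stringsAsFactors = FALSE)
}

# one level of the model as a RAM graph: `latents` maps each shared latent to
# its two partner indicators (loadings fixed at 1), `paths` are the free
# structural edges, every observed variable carries a free residual variance,
# exogenous latents a free variance phi, endogenous latents a free
# disturbance psi.
build_level <- function(level, latents, exo_latents, obs, paths) {
  tag <- if (level == "within") "w" else "b"
  pt <- list()
  for (lat in names(latents)) {
    for (ind in latents[[lat]]) {
      pt[[length(pt) + 1L]] <- pt_row(
        sprintf("lambda_%s.%s", tag, ind), level, "A", ind, lat,
        free = FALSE, value = 1)
    }
  }
  if (nrow(paths)) {
    for (k in seq_len(nrow(paths))) {
      pt[[length(pt) + 1L]] <- pt_row(
        sprintf("%s_%s%s", paths$kind[k], tag,
                ifelse(paths$kind[k] == "a", "", paste0(".", paths$to[k]))),
        level, "A", paths$to[k], paths$from[k], free = TRUE)
    }
  }
  for (lat in names(latents)) {
    lab <- if (lat %in% exo_latents) "phi" else "psi"
    pt[[length(pt) + 1L]] <- pt_row(
      sprintf("%s_%s.%s", lab, tag, lat), level, "S", lat, lat,
      free = TRUE, transform = "log")
  }
  for (v in obs) {
    pt[[length(pt) + 1L]] <- pt_row(
      sprintf("theta_%s.%s", tag, v), level, "S", v, v,
      free = TRUE, transform = "log")
  }
  list(vars = c(names(latents), obs), obs = obs, latents = names(latents),
       partable = do.call(rbind, pt))
}

#' Build a common fate mediation model specification
#'
#' Encodes the two-level latent-variable graph for one of the six outcome
#' models. At both levels, both partners' we-disease appraisal reports load
#' (loading fixed at 1) on a shared appraisal latent, which predicts a shared
#' dyadic-coping latent (path `a`), which in turn predicts the outcome (path
#' `b`) alongside a direct appraisal-to-outcome path (`c`). Daily quality of
#' life is modeled as two partner-specific observed outcomes (a non-common
#' fate construct); daily and post-diary relationship satisfaction are shared
#' (common fate) latents with one indicator per partner; post-diary outcomes
#' (quality of life, ART adherence, PrEP attitude, relationship satisfaction)
#' attach at the between level only.
#'
#' @param outcome one of [cfm_outcomes()].
#' @param covariates optional character vector of dyad-level observed
#'   covariates entering the between level as exogenous regressors of every
#'   between-level endogenous variable.
#' @return an object of class `cfm_model` with elements `within`, `between`
#'   (RAM graphs), `distal`, `daily_vars`, and a parameter table `partable`
#'   giving every fixed and free parameter.
#' @export
#' @examples
#' m <- cfm_model("daily_qol")
#' subset(m$partable, free)$label
cfm_model <- function(outcome = cfm_outcomes(), covariates = character()) {
  outcome <- match.arg(outcome)
  roles <- c("PLWH", "partner")
  wda_ind <- paste0("wda_", roles)
  cdc_ind <- paste0("cdc_", roles)
  base_lat <- list(wda_shared = wda_ind, cdc_shared = cdc_ind)
  a_edge <- data.frame(kind = "a", from = "wda_shared", to = "cdc_shared",
                       stringsAsFactors = FALSE)
  med_edges <- function(targets) {
    rbind(a_edge,
          data.frame(kind = "b", from = "cdc_shared", to = targets),
          data.frame(kind = "c", from = "wda_shared", to = targets))
  }

  if (outcome == "daily_qol") {
    qol <- paste0("qol_", roles)
    within <- build_level("within", base_lat, "wda_shared",
                          c(wda_ind, cdc_ind, qol), med_edges(qol))
    between <- build_level("between", base_lat, "wda_shared",
                           c(wda_ind, cdc_ind, qol), med_edges(qol))
    distal <- character()
    daily_vars <- c("wda", "cdc", "qol")
  } else if (outcome == "daily_rs") {
    rs <- paste0("rs_", roles)
    lat <- c(base_lat, list(rs_shared = rs))
    within <- build_level("within", lat, "wda_shared",
                          c(wda_ind, cdc_ind, rs), med_edges("rs_shared"))
    between <- build_level("between", lat, "wda_shared",
                           c(wda_ind, cdc_ind, rs), med_edges("rs_shared"))
    distal <- character()
    daily_vars <- c("wda", "cdc", "rs")
  } else {
    # post-diary outcome models: within level is the shared appraisal ->
    # coping measurement/structural core only
    within <- build_level("within", base_lat, "wda_shared",
                          c(wda_ind, cdc_ind), a_edge)
    daily_vars <- c("wda", "cdc")
    if (outcome == "post_qol") {
      distal <- paste0("post_qol_", roles)
      between <- build_level("between", base_lat, "wda_shared",
                             c(wda_ind, cdc_ind, distal), med_edges(distal))
    } else if (outcome == "post_adherence") {
      distal <- "adherent"
      between <- build_level("between", base_lat, "wda_shared",
                             c(wda_ind, cdc_ind, distal), med_edges(distal))
    } else if (outcome == "post_prep") {
      distal <- "prep_attitude"
      between <- build_level("between", base_lat, "wda_shared",
                             c(wda_ind, cdc_ind, distal), med_edges(distal))
    } else { # post_rs
      distal <- paste0("post_rs_", roles)
      lat <- c(base_lat, list(rs_post_shared = distal))
      between <- build_level("between", lat, "wda_shared",
                             c(wda_ind, cdc_ind, distal),
                             med_edges("rs_post_shared"))
    }
  }

  pt <- rbind(within$partable, between$partable)

  if (length(covariates)) {
    # dyad-level exogenous observed regressors at the between level: free
    # variances/covariances among themselves and with the exogenous shared
    # appraisal latent, and a regression on every between-level endogenous
    # variable
    bpt <- between$partable
    indicators <- bpt$row[bpt$mat == "A" & !bpt$free]
    endo <- setdiff(between$vars, c("wda_shared", indicators))
    rows <- list()
    for (cv in covariates) {
      rows[[length(rows) + 1L]] <- pt_row(
        sprintf("varcov_b.%s.%s", cv, cv), "between", "S", cv, cv,
        free = TRUE, transform = "log")
      rows[[length(rows) + 1L]] <- pt_row(
        sprintf("varcov_b.%s.wda_shared", cv), "between", "S", cv,
        "wda_shared", free = TRUE)
      for (tg in endo) {
        rows[[length(rows) + 1L]] <- pt_row(
          sprintf("gamma_b.%s.%s", cv, tg), "between", "A", tg, cv,
          free = TRUE)
      }
    }
    if (length(covariates) > 1) {
      cmb <- utils::combn(covariates, 2)
      for (k in seq_len(ncol(cmb))) {
        rows[[length(rows) + 1L]] <- pt_row(
          sprintf("varcov_b.%s.%s", cmb[1, k], cmb[2, k]), "between", "S",
          cmb[1, k], cmb[2, k], free = TRUE)
      }
    }
    pt <- rbind(pt, do.call(rbind, rows))
    between$vars <- c(between$vars, covariates)
    between$obs <- c(between$obs, covariates)
  }

  all_obs <- c(within$obs, distal, covariates)
  for (v in all_obs) {
    pt <- rbind(pt, pt_row(paste0("mu.", v), "mean", "mu", v, "",
                           free = TRUE))
  }
  stopifnot(!anyDuplicated(pt$label))

  structure(class = "cfm_model", list(
    outcome = outcome,
    within = within[c("vars", "obs", "latents")],
    between = between[c("vars", "obs", "latents")],
    distal = distal,
    covariates = covariates,
    daily_vars = daily_vars,
    obs_names = all_obs,
    partable = pt
  ))
}

#' @export
print.cfm_model <- function(x, ...) {
  cat("<cfm_model> outcome:", x$outcome, "\n")
  cat(sprintf("  within: %d latents, %d indicators\n",
              length(x$within$latents), length(x$within$obs)))
  cat(sprintf("  between: %d latents, %d observed (%d distal)\n",
              length(x$between$latents), length(x$between$obs),
              length(x$distal)))
  cat(sprintf("  free parameters: %d\n", sum(x$partable$free)))
  invisible(x)
}

free_labels <- function(model) model$partable$label[model$partable$free]

# fill the RAM matrices of one level from a named free-parameter vector
level_matrices <- function(model, level, theta) {
  lv <- model[[level]]
  nv <- length(lv$vars)
  A <- matrix(0, nv, nv, dimnames = list(lv$vars, lv$vars))
  S <- matrix(0, nv, nv, dimnames = list(lv$vars, lv$vars))
  rows <- model$partable[model$partable$level == level, , drop = FALSE]
  for (k in seq_len(nrow(rows))) {
    v <- if (rows$free[k]) theta[[rows$label[k]]] else rows$value[k]
    if (rows$mat[k] == "A") {
      A[rows$row[k], rows$col[k]] <- v
    } else {
      S[rows$row[k], rows$col[k]] <- v
      S[rows$col[k], rows$row[k]] <- v
    }
  }
  list(A = A, S = S, obs = match(lv$obs, lv$vars))
}

#' Model-implied moments
#'
#' Computes the implied covariance matrix at each level and the implied mean
#' vector from a free-parameter vector, using the reticular-action formula
#' per level: `Sigma = F (I - A)^-1 S (I - A)^-T F'` where `A` holds loadings
#' and structural paths, `S` variances and covariances, and `F` selects the
#' observed variables.
#'
#' @param model a [cfm_model()].
#' @param theta named numeric vector of free-parameter values (natural
#'   scale), covering every free label in `model$partable`.
#' @return list with `sigma_within` (p x p), `sigma_between` (m x m, the
#'   between-level set includes distal outcomes and covariates), and `mu`
#'   (length m).
#' @export
implied_moments <- function(model, theta) {
  stopifnot(all(free_labels(model) %in% names(theta)))
  sig <- function(level) {
    mm <- level_matrices(model, level, theta)
    ImA <- diag(nrow(mm$A)) - mm$A
    if (abs(det(ImA)) < 1e-12) stop("(I - A) is singular at this theta")
    Minv <- solve(ImA)
    C <- Minv %*% mm$S %*% t(Minv)
    C[mm$obs, mm$obs, drop = FALSE]
  }
  mu_rows <- model$partable[model$partable$level == "mean", , drop = FALSE]
  mu <- setNames(vapply(seq_len(nrow(mu_rows)), function(k) {
    if (mu_rows$free[k]) theta[[mu_rows$label[k]]] else mu_rows$value[k]
  }, 0), mu_rows$row)
  list(sigma_within = sig("within"), sigma_between = sig("between"),
       mu = mu[model$obs_names])
}

#' Standardized solution
#'
#' Standardizes every path and loading by the model-implied standard
#' deviations at its own level (`beta = b * SD(source) / SD(target)`), and
#' covariances to correlations. With both partners' unstandardized loadings
#' fixed at 1, unequal residual variances yield unequal standardized
#' loadings, which is how the common fate parameterization reproduces
#' partner-asymmetric loadings.
#'
#' @inheritParams implied_moments
#' @return the model's parameter table with the supplied estimates in
#'   `value` and a `std` column; mean rows have `std = NA`.
#' @export
standardize_solution <- function(model, theta) {
  pt <- model$partable
  pt$value[pt$free] <- theta[pt$label[pt$free]]
  pt$std <- NA_real_
  for (level in c("within", "between")) {
    mm <- level_matrices(model, level, theta)
    Minv <- solve(diag(nrow(mm$A)) - mm$A)
    C <- Minv %*% mm$S %*% t(Minv)
    sdv <- sqrt(diag(C))
    if (any(sdv <= 0)) stop("zero implied variance at level ", level)
    idx <- which(pt$level == level)
    for (k in idx) {
      v <- pt$value[k]
      if (pt$mat[k] == "A") {
        pt$std[k] <- v * sdv[pt$col[k]] / sdv[pt$row[k]]
      } else if (pt$row[k] == pt$col[k]) {
        pt$std[k] <- v / (sdv[pt$row[k]]^2)
      } else {
        pt$std[k] <- v / (sdv[pt$row[k]] * sdv[pt$col[k]])
      }
    }
  }
  pt
}

#' Serialize a model specification to JSON
#'
#' Writes the latent/indicator layout and the full fixed/free parameter
#' pattern so a fitted model is a reproducible artifact.
#'
#' @param model a [cfm_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
model_to_json <- function(model, path) {
  x <- list(outcome = model$outcome,
            within = model$within, between = model$between,
            distal = model$distal, covariates = model$covariates,
            observed = model$obs_names,
            partable = model$partable)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
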