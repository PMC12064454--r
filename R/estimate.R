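#' Assemble clustered model data from a diary panel
#'
#' Reshapes the long panel to one row per dyad-day with both partners'
#' scores, drops days on which any required indicator is missing (day-level
#' full-information likelihood: a dyad contributes whatever complete days it
#' has), attaches between-only variables (post-diary outcomes, covariates),
#' and precomputes the sufficient statistics of the structured likelihood:
#' the pooled within-dyad cross-product and, grouped by observed day count
#' `n_j`, the matrix of cluster means joined with the between-only variables.
#'
#' @param model a [cfm_model()].
#' @param panel long diary panel (`dyad_id`, `day`, `role`, scores).
#' @param post post-diary table (one row per dyad), required when the model
#'   has distal outcomes. `adherent` is derived as `adherence_days > 28`.
#' @param covariate_data optional data frame with `dyad_id` and one column
#'   per model covariate.
#' @return an object of class `cfm_data`.
#' @export
cfm_data <- function(model, panel, post = NULL, covariate_data = NULL) {
  vars <- model$daily_vars
  need <- c("dyad_id", "day", "role", vars)
  if (!all(need %in% names(panel))) {
    stop_data("panel lacks required columns: %s",
              paste(setdiff(need, names(panel)), collapse = ", "))
  }
  if (nrow(panel) == 0) stop_data("panel is empty")
  roles <- c("PLWH", "partner")
  if (!all(panel$role %in% roles)) {
    stop_data("role must be one of: %s", paste(roles, collapse = ", "))
  }
  wide <- NULL
  for (r in roles) {
    sub <- panel[panel$role == r, c("dyad_id", "day", vars)]
    names(sub)[-(1:2)] <- paste0(vars, "_", r)
    wide <- if (is.null(wide)) sub else {
      merge(wide, sub, by = c("dyad_id", "day"), all = TRUE)
    }
  }
  obs <- model$within$obs
  ok <- complete.cases(wide[, obs, drop = FALSE])
  wide <- wide[ok, , drop = FALSE]
  all_dyads <- sort(unique(panel$dyad_id))
  used <- sort(unique(wide$dyad_id))
  dropped <- length(all_dyads) - length(used)
  if (dropped > 0) {
    cfm_log("info", sprintf(
      "%d dyad(s) dropped: no complete day after day-level deletion", dropped))
  }
  if (length(used) < 2) stop_data("need at least 2 dyads with complete days")

  cl <- factor(wide$dyad_id, levels = used)
  Y <- as.matrix(wide[, obs, drop = FALSE])
  nj <- as.integer(table(cl))
  ybar <- rowsum(Y, cl) / nj
  Sdev <- crossprod(Y) - crossprod(ybar * sqrt(nj))
  N <- nrow(Y)
  J <- length(used)

  q_names <- c(model$distal, model$covariates)
  Z <- NULL
  if (length(q_names)) {
    if (length(model$distal) && is.null(post)) {
      stop_data("model '%s' needs a post-diary table", model$outcome)
    }
    src <- list()
    if (length(model$distal)) {
      idx <- match(used, post$dyad_id)
      if (anyNA(idx)) stop_data("post-diary table lacks some dyads")
      src_map <- c(post_qol_PLWH = "qol_plwh", post_qol_partner = "qol_partner",
                   prep_attitude = "prep_attitude",
                   post_rs_PLWH = "rs_plwh", post_rs_partner = "rs_partner")
      for (d in model$distal) {
        src[[d]] <- if (d == "adherent") {
          as.numeric(post$adherence_days[idx] > 28)
        } else {
          post[[src_map[[d]]]][idx]
        }
      }
    }
    if (length(model$covariates)) {
      if (is.null(covariate_data)) stop_data("covariate_data is required")
      idx <- match(used, covariate_data$dyad_id)
      if (anyNA(idx)) stop_data("covariate_data lacks some dyads")
      for (cv in model$covariates) src[[cv]] <- covariate_data[[cv]][idx]
    }
    Z <- do.call(cbind, src[q_names])
    if (anyNA(Z)) {
      stop_data("between-only variables must be complete for all used dyads")
    }
  }
  U_all <- cbind(ybar, Z)
  colnames(U_all) <- model$obs_names
  p <- length(obs)
  m <- ncol(U_all)

  grp <- split(seq_len(J), nj)
  stats <- list(NmJ = as.numeric(N - J), Sdev = Sdev,
                nj = as.integer(names(grp)),
                U = lapply(grp, function(i) U_all[i, , drop = FALSE]))

  structure(class = "cfm_data", list(
    stats = stats, p = p, m = m, J = J, N = N,
    nj_all = nj, U_all = U_all,
    S_PW = Sdev / (N - J),
    mean_daily = colSums(Y) / N,
    mean_all = colMeans(U_all),
    dropped = dropped, obs = obs, q_names = q_names
  ))
}

#' @export
print.cfm_data <- function(x, ...) {
  cat(sprintf("<cfm_data> %d dyads, %d person-days, %d within indicators, %d between-only\n",
              x$J, x$N, x$p, length(x$q_names)))
  invisible(x)
}

#' Pooled within-cluster and between-cluster sample moments
#'
#' `S_PW` is the pooled within-cluster covariance (cluster-mean deviations,
#' divisor `N - J`); `S_B` is the conventional between-groups moment matrix
#' of cluster means weighted by cluster size (divisor `J - 1`).
#'
#' @param y numeric matrix or data frame, one row per observation.
#' @param clusters cluster identifier per row.
#' @return list with `s_pooled_within`, `s_between`, `cluster_sizes`.
#' @export
pooled_moments <- function(y, clusters) {
  y <- as.matrix(y)
  cl <- factor(clusters)
  J <- nlevels(cl)
  if (J < 2) stop("between moments are undefined for a single cluster")
  N <- nrow(y)
  if (N <= J) stop("need more observations than clusters")
  nj <- as.integer(table(cl))
  ybar <- rowsum(y, cl) / nj
  S_PW <- (crossprod(y) - crossprod(ybar * sqrt(nj))) / (N - J)
  gbar <- colSums(y) / N
  dev <- sweep(ybar, 2, gbar)
  S_B <- crossprod(dev * sqrt(nj)) / (J - 1)
  list(s_pooled_within = S_PW, s_between = S_B, cluster_sizes = nj)
}

# ---- optimizer plumbing -----------------------------------------------------

build_ctx <- function(model) {
  pt <- model$partable
  lv_idx <- list(within = match(pt$row, model$within$vars),
                 between = match(pt$row, model$between$vars))
  lv_col <- list(within = match(pt$col, model$within$vars),
                 between = match(pt$col, model$between$vars))
  fixed <- function(level, mat) {
    vars <- model[[level]]$vars
    M <- matrix(0, length(vars), length(vars))
    rows <- which(pt$level == level & pt$mat == mat & !pt$free)
    for (k in rows) {
      M[lv_idx[[level]][k], lv_col[[level]][k]] <- pt$value[k]
      if (mat == "S") M[lv_col[[level]][k], lv_idx[[level]][k]] <- pt$value[k]
    }
    M
  }
  free <- which(pt$free)
  fmap <- matrix(0L, length(free), 5)
  for (n in seq_along(free)) {
    k <- free[n]
    if (pt$level[k] == "mean") {
      fmap[n, ] <- c(2L, 0L, match(pt$row[k], model$obs_names) - 1L, 0L, 0L)
    } else {
      lev <- if (pt$level[k] == "within") 0L else 1L
      fmap[n, ] <- c(lev, if (pt$mat[k] == "A") 0L else 1L,
                     lv_idx[[pt$level[k]]][k] - 1L,
                     lv_col[[pt$level[k]]][k] - 1L,
                     if (pt$transform[k] == "log") 1L else 0L)
    }
  }
  p <- length(model$within$obs)
  m <- length(model$obs_names)
  list(kind = 0L, p = as.integer(p), m = as.integer(m),
       AW0 = fixed("within", "A"), SW0 = fixed("within", "S"),
       AB0 = fixed("between", "A"), SB0 = fixed("between", "S"),
       obsW = match(model$within$obs, model$within$vars) - 1L,
       obsB = match(model$between$obs, model$between$vars) - 1L,
       mu0 = numeric(m), fmap = fmap,
       labels = pt$label[free],
       trans = ifelse(pt$transform[free] == "log", 1L, 0L))
}

# unrestricted (saturated) or independence (baseline) two-level model,
# parameterized through Cholesky factors so positive definiteness holds
# throughout optimization
build_chol_ctx <- function(p, m, obs_names, diag_only = FALSE) {
  rows <- list()
  add <- function(lev, i, j) {
    rows[[length(rows) + 1L]] <<- c(lev, 2L, i - 1L, j - 1L,
                                    if (i == j) 1L else 0L)
  }
  labels <- character(0)
  for (lev in 0:1) {
    d <- if (lev == 0) p else m
    tag <- if (lev == 0) "w" else "b"
    for (j in seq_len(d)) {
      for (i in j:d) {
        if (diag_only && i != j) next
        add(lev, i, j)
        labels <- c(labels, sprintf("L%s.%d.%d", tag, i, j))
      }
    }
  }
  for (i in seq_len(m)) {
    rows[[length(rows) + 1L]] <- c(2L, 0L, i - 1L, 0L, 0L)
    labels <- c(labels, paste0("mu.", obs_names[i]))
  }
  fmap <- do.call(rbind, rows)
  storage.mode(fmap) <- "integer"
  list(kind = 1L, p = as.integer(p), m = as.integer(m),
       LW0 = matrix(0, p, p), LB0 = matrix(0, m, m),
       mu0 = numeric(m), fmap = fmap, labels = labels,
       trans = fmap[, 5])
}

to_trans <- function(theta, trans) {
  out <- as.numeric(theta)
  out[trans == 1L] <- log(out[trans == 1L])
  out
}
from_trans <- function(theta, trans) {
  out <- as.numeric(theta)
  out[trans == 1L] <- exp(out[trans == 1L])
  out
}

#' Structured two-level log-likelihood
#'
#' Evaluates the clusterwise Gaussian log-likelihood of the model at a named
#' free-parameter vector (natural scale), using the eigenstructure of the
#' exchangeable day covariance so the dense per-cluster covariance is never
#' formed.
#'
#' @param model a [cfm_model()].
#' @param theta named free-parameter vector (natural scale).
#' @param data a [cfm_data()] object.
#' @return the log-likelihood; `-Inf` if the implied covariance is not
#'   positive definite.
#' @export
cfm_loglik <- function(model, theta, data) {
  ctx <- build_ctx(model)
  v <- cfm_ll_cpp(as.numeric(theta[ctx$labels]), ctx, data$stats, raw = TRUE)
  if (is.na(v)) -Inf else v
}

# moment-based start values: grand means for mu, paths at zero, latent
# variances at half the corresponding indicator-level variance, residuals at
# half their indicator's level variance
start_theta <- function(model, data) {
  pt <- model$partable
  p <- data$p
  nbar <- mean(data$nj_all)
  withinv <- setNames(diag(data$S_PW), data$obs)
  ubar_var <- apply(data$U_all, 2, var)
  betweenv <- setNames(numeric(data$m), model$obs_names)
  for (v in model$obs_names) {
    betweenv[v] <- if (v %in% data$obs) {
      max(ubar_var[v] - withinv[v] / nbar, 0.05 * withinv[v])
    } else {
      ubar_var[v]
    }
  }
  # latent -> indicator map from the fixed loading rows
  lat_ind <- list()
  lrows <- which(pt$mat == "A" & !pt$free)
  for (k in lrows) lat_ind[[pt$col[k]]] <- c(lat_ind[[pt$col[k]]], pt$row[k])
  lvar <- function(level, v) {
    vals <- if (level == "within") withinv else betweenv
    if (v %in% names(vals)) vals[[v]] else {
      mean(vals[unique(lat_ind[[v]])])
    }
  }
  free <- which(pt$free)
  th <- numeric(length(free))
  names(th) <- pt$label[free]
  for (n in seq_along(free)) {
    k <- free[n]
    th[n] <- if (pt$level[k] == "mean") {
      data$mean_all[[pt$row[k]]]
    } else if (pt$mat[k] == "A") {
      0
    } else if (pt$row[k] == pt$col[k]) {
      0.5 * lvar(pt$level[k], pt$row[k])
    } else {
      0
    }
  }
  th
}

run_optim <- function(ctx, stats, theta0_nat, control = list()) {
  trans <- ctx$trans
  par0 <- to_trans(theta0_nat, trans)
  fn <- function(par) {
    v <- cfm_ll_cpp(par, ctx, stats, raw = FALSE)
    if (is.na(v) || !is.finite(v)) 1e10 else -v
  }
  gr <- function(par) {
    g <- cfm_grad_cpp(par, ctx, stats, raw = FALSE)
    g[!is.finite(g)] <- 0
    -g
  }
  maxit <- control$maxit %||% 1000L
  # bounds on the transformed scale keep the search away from numerically
  # degenerate regions (variances between exp(-18) and exp(18))
  lower <- ifelse(trans == 1L, -18, -1e6)
  upper <- ifelse(trans == 1L, 18, 1e6)
  opt <- stats::nlminb(par0, fn, gr, lower = lower, upper = upper,
                       control = list(iter.max = maxit, eval.max = 4 * maxit,
                                      rel.tol = 1e-12))
  opt$par <- opt$par
  opt$value <- opt$objective
  opt$convergence <- if (opt$convergence == 0 ||
                           grepl("relative convergence|both X.*and relative|singular convergence",
                                 opt$message %||% "")) 0L else 1L
  # Newton polish: quadratic refinement until the gradient max-norm meets tol
  tol <- control$tol_grad %||% 1e-5
  par <- opt$par
  ll <- -opt$value
  for (it in seq_len(control$polish_iter %||% 15L)) {
    g <- cfm_grad_cpp(par, ctx, stats, raw = FALSE)
    if (!all(is.finite(g)) || max(abs(g)) < tol) break
    H <- cfm_hess_cpp(par, ctx, stats, raw = FALSE)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- par - step  # H is negative definite near the optimum
    lam <- 1
    repeat {
      v <- cfm_ll_cpp(par - lam * step, ctx, stats, raw = FALSE)
      if (!is.na(v) && v >= ll) { par <- par - lam * step; ll <- v; break }
      lam <- lam / 2
      if (lam < 1e-6) break
    }
    if (lam < 1e-6) break
  }
  g <- cfm_grad_cpp(par, ctx, stats, raw = FALSE)
  list(par_nat = from_trans(par, trans), par_trans = par, loglik = ll,
       grad = g, code = opt$convergence,
       converged = opt$convergence == 0 && all(is.finite(g)) &&
         max(abs(g)) < (control$tol_grad_accept %||% 0.05))
}

#' Fit a common fate mediation model by maximum likelihood
#'
#' Maximizes the structured two-level likelihood by quasi-Newton iteration on
#' an unconstrained reparameterization (variances on the log scale, paths
#' raw) from moment-based starting values, followed by Newton refinement.
#' Standard errors come from the inverse of the numerically differentiated
#' observed information, mapped back to the natural scale; the standardized
#' solution uses model-implied level-specific standard deviations. Fit
#' indices compare the model against ML fits of the two-level saturated and
#' independence models on the identical data.
#'
#' @param model a [cfm_model()].
#' @param panel long diary panel.
#' @param post post-diary table (one row per dyad), when the model needs it.
#' @param covariate_data optional dyad-level covariate data frame.
#' @param config list of options: `se` (default `TRUE`), `fit_indices`
#'   (default `TRUE`; suppressed automatically for the binary adherence
#'   outcome), `maxit`, `tol_grad` (Newton polish target, default `1e-5`),
#'   `start` (named vector overriding the moment-based start).
#' @return an object of class `cfm_fit`: the parameter table with estimates,
#'   standard errors, Wald z and p-values and the standardized solution,
#'   the free-parameter covariance matrix, log-likelihoods, the fit-index
#'   block, and convergence information.
#' @export
cfm_fit <- function(model, panel, post = NULL, covariate_data = NULL,
                    config = list()) {
  data <- cfm_data(model, panel, post, covariate_data)
  ctx <- build_ctx(model)
  df_sat_free <- data$m + data$p * (data$p + 1) / 2 + data$m * (data$m + 1) / 2
  np <- length(ctx$labels)
  df <- df_sat_free - np
  if (df < 0) stop("model has more free parameters than two-level moments")

  theta0 <- config$start %||% start_theta(model, data)
  opt <- run_optim(ctx, data$stats, theta0[ctx$labels],
                   control = config)
  if (!opt$converged) {
    warning("optimizer did not meet the convergence criterion (max |grad| = ",
            signif(max(abs(opt$grad)), 3), ")")
  }
  theta <- setNames(opt$par_nat, ctx$labels)

  variances <- ctx$trans == 1L
  if (any(theta[variances] < 1e-8)) {
    warning("variance estimate(s) at the boundary: ",
            paste(ctx$labels[variances][theta[variances] < 1e-8],
                  collapse = ", "))
  }

  vcov_nat <- NULL
  se <- rep(NA_real_, np)
  if (isTRUE(config$se %||% TRUE)) {
    H <- cfm_hess_cpp(opt$par_trans, ctx, data$stats, raw = FALSE)
    cov_trans <- tryCatch(solve(-H), error = function(e) {
      warning("observed information is singular; using pseudo-inverse")
      MASS::ginv(-H)
    })
    D <- ifelse(variances, theta, 1)
    vcov_nat <- diag(D) %*% cov_trans %*% diag(D)
    dimnames(vcov_nat) <- list(ctx$labels, ctx$labels)
    se <- sqrt(pmax(diag(vcov_nat), 0))
  }

  pt <- standardize_solution(model, theta)
  pt$se <- NA_real_
  pt$se[pt$free] <- se[match(pt$label[pt$free], ctx$labels)]
  pt$z <- pt$value / pt$se
  pt$p <- 2 * pnorm(-abs(pt$z))

  fit <- list(model = model, data = data, partable = pt,
              theta = theta, vcov = vcov_nat,
              loglik = opt$loglik, np = np, df = df,
              converged = opt$converged, grad_norm = max(abs(opt$grad)),
              n_clusters = data$J, n_obs = data$N,
              fit = NULL,
              meta = list(rmsea_n = "total person-days",
                          se_type = "observed information, Wald z"))
  class(fit) <- "cfm_fit"

  want_idx <- isTRUE(config$fit_indices %||% TRUE)
  if (want_idx && model$outcome == "post_adherence") {
    fit$fit_note <- "fit indices not available for binary outcome"
    want_idx <- FALSE
  }
  if (want_idx) {
    ref <- fit_reference_models(data, model$obs_names, config)
    imp <- implied_moments(model, theta)
    fit$fit <- fit_indices(
      loglik_m = opt$loglik, df_m = df,
      loglik_sat = ref$sat$loglik, loglik_base = ref$base$loglik,
      df_base = df_sat_free - ref$base$np, n_obs = data$N,
      s_within = ref$sat$sigma_within, s_between = ref$sat$sigma_between,
      implied = imp)
    fit$loglik_saturated <- ref$sat$loglik
    fit$loglik_baseline <- ref$base$loglik
  }
  fit
}

# ML fits of the two-level saturated model (unrestricted Sigma_W, Sigma_B,
# mu) and the independence baseline (diagonal covariances, free means)
fit_reference_models <- function(data, obs_names, config = list()) {
  p <- data$p; m <- data$m
  start_L <- function(S) {
    L <- tryCatch(t(chol(S)), error = function(e) diag(sqrt(pmax(diag(S), 1e-4))))
    L
  }
  nbar <- mean(data$nj_all)
  SB0 <- cov(data$U_all)
  SB0[seq_len(p), seq_len(p)] <- SB0[seq_len(p), seq_len(p)] -
    data$S_PW / nbar
  diag(SB0)[seq_len(p)] <- pmax(diag(SB0)[seq_len(p)],
                                0.05 * diag(data$S_PW))
  SB0 <- (SB0 + t(SB0)) / 2
  ev <- eigen(SB0, symmetric = TRUE)
  SB0 <- ev$vectors %*% diag(pmax(ev$values, 1e-4), m) %*% t(ev$vectors)

  one <- function(diag_only) {
    ctx <- build_chol_ctx(p, m, obs_names, diag_only)
    LW <- start_L(data$S_PW); LB <- start_L(SB0)
    th <- numeric(nrow(ctx$fmap))
    for (k in seq_len(nrow(ctx$fmap))) {
      f <- ctx$fmap[k, ]
      th[k] <- if (f[1] == 2L) {
        data$mean_all[[f[3] + 1L]]
      } else if (f[1] == 0L) {
        if (diag_only) sqrt(max(diag(data$S_PW)[f[3] + 1L], 1e-4)) else LW[f[3] + 1L, f[4] + 1L]
      } else {
        if (diag_only) sqrt(max(diag(SB0)[f[3] + 1L], 1e-4)) else LB[f[3] + 1L, f[4] + 1L]
      }
      if (f[5] == 1L && th[k] <= 0) th[k] <- 1e-2
    }
    opt <- run_optim(ctx, data$stats, th, control = config)
    # reconstruct the implied covariances for residual-based indices
    LWh <- matrix(0, p, p); LBh <- matrix(0, m, m)
    for (k in seq_len(nrow(ctx$fmap))) {
      f <- ctx$fmap[k, ]
      if (f[1] == 0L) LWh[f[3] + 1L, f[4] + 1L] <- opt$par_nat[k]
      if (f[1] == 1L) LBh[f[3] + 1L, f[4] + 1L] <- opt$par_nat[k]
    }
    list(loglik = opt$loglik, np = nrow(ctx$fmap),
         sigma_within = LWh %*% t(LWh), sigma_between = LBh %*% t(LBh),
         converged = opt$converged)
  }
  sat <- one(FALSE)
  base <- one(TRUE)
  if (!sat$converged) warning("saturated reference model did not converge")
  dimnames(sat$sigma_within) <- list(obs_names[seq_len(p)], obs_names[seq_len(p)])
  dimnames(sat$sigma_between) <- list(obs_names, obs_names)
  list(sat = sat, base = base)
}

#' Fit indices for a two-level model
#'
#' Likelihood-ratio chi-square against the saturated model, incremental
#' indices against the independence baseline, RMSEA with `n_obs` total
#' within-level observations (person-days), and SRMR computed separately at
#' each level from standardized residual moments.
#'
#' @param loglik_m,df_m model log-likelihood and degrees of freedom.
#' @param loglik_sat,loglik_base saturated and baseline log-likelihoods
#'   computed on the identical data and casewise pattern.
#' @param df_base baseline degrees of freedom.
#' @param n_obs total number of within-level observations.
#' @param s_within,s_between sample (or saturated-ML) moment matrices.
#' @param implied model-implied moments, as from [implied_moments()].
#' @return list with `chi2`, `df`, `chi2_baseline`, `df_baseline`, `cfi`,
#'   `tli`, `rmsea`, `srmr_within`, `srmr_between`. With `df_m = 0`, RMSEA
#'   and TLI are reported as `NA` (not applicable).
#' @export
fit_indices <- function(loglik_m, df_m, loglik_sat, loglik_base, df_base,
                        n_obs, s_within = NULL, s_between = NULL,
                        implied = NULL) {
  chi2_m <- max(2 * (loglik_sat - loglik_m), 0)
  chi2_b <- max(2 * (loglik_sat - loglik_base), 0)
  num <- max(chi2_m - df_m, 0)
  den <- max(chi2_b - df_base, chi2_m - df_m, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  cfi <- min(max(cfi, 0), 1)
  tli <- if (df_m == 0 || df_base == 0 || chi2_b == df_base) {
    NA_real_
  } else {
    min(max(((chi2_b / df_base) - (chi2_m / df_m)) /
              ((chi2_b / df_base) - 1), 0), 1)
  }
  rmsea <- if (df_m == 0) NA_real_ else sqrt(num / (df_m * n_obs))
  srmr <- function(S, Sig) {
    if (is.null(S) || is.null(Sig)) return(NA_real_)
    sdS <- sqrt(diag(S)); sdI <- sqrt(diag(Sig))
    R <- S / tcrossprod(sdS) - Sig / tcrossprod(sdI)
    sqrt(mean(R[lower.tri(R, diag = TRUE)]^2))
  }
  list(chi2 = chi2_m, df = df_m, chi2_baseline = chi2_b,
       df_baseline = df_base, cfi = cfi, tli = tli, rmsea = rmsea,
       srmr_within = srmr(s_within, if (!is.null(implied)) implied$sigma_within),
       srmr_between = srmr(s_between, if (!is.null(implied)) implied$sigma_between))
}

#' @export
print.cfm_fit <- function(x, ...) {
  cat("<cfm_fit> outcome:", x$model$outcome, "\n")
  cat(sprintf("  %d dyads, %d person-days; logLik %.2f on %d free parameters (df %d)\n",
              x$n_clusters, x$n_obs, x$loglik, x$np, x$df))
  cat(sprintf("  converged: %s (max |grad| %.2g)\n", x$converged, x$grad_norm))
  if (!is.null(x$fit)) {
    cat(sprintf("  chi2(%d) = %.2f, CFI %.3f, TLI %.3f, RMSEA %.3f, SRMR_w %.3f, SRMR_b %.3f\n",
                x$fit$df, x$fit$chi2, x$fit$cfi, x$fit$tli, x$fit$rmsea,
                x$fit$srmr_within, x$fit$srmr_between))
  }
  if (!is.null(x$fit_note)) cat(" ", x$fit_note, "\n")
  pt <- x$partable[x$partable$mat == "A" & x$partable$free, ]
  if (nrow(pt)) {
    cat("  structural paths:\n")
    for (k in seq_len(nrow(pt))) {
      cat(sprintf("    %-24s %8.3f (SE %.3f, beta %.2f)\n",
                  paste0(pt$col[k], " -> ", pt$row[k]),
                  pt$value[k], pt$se[k], pt$std[k]))
    }
  }
  invisible(x)
}
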