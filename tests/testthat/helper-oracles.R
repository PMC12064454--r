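# Independent oracles used to cross-check the implementation.

# multivariate normal log-density via Cholesky (no package dependency)
dmvn_log <- function(y, mu, S) {
  L <- t(chol(S))
  r <- forwardsolve(L, y - mu)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(r^2))
}

# Brute-force likelihood: materializes the full n_j * p + q covariance of
# each cluster (exchangeable day blocks plus between-only borders) and sums
# dense multivariate-normal log-densities.
dense_loglik <- function(model, theta, panel, post = NULL) {
  imp <- implied_moments(model, theta)
  SW <- imp$sigma_within; SB <- imp$sigma_between; mu <- imp$mu
  dat <- cfm_data(model, panel, post)
  p <- dat$p; m <- dat$m; q <- m - p
  vars <- model$daily_vars
  wide <- NULL
  for (r in c("PLWH", "partner")) {
    sub <- panel[panel$role == r, c("dyad_id", "day", vars)]
    names(sub)[-(1:2)] <- paste0(vars, "_", r)
    wide <- if (is.null(wide)) sub else {
      merge(wide, sub, by = c("dyad_id", "day"), all = TRUE)
    }
  }
  obs <- model$within$obs
  wide <- wide[stats::complete.cases(wide[, obs]), ]
  used <- sort(unique(wide$dyad_id))
  ll <- 0
  for (j in used) {
    Y <- as.matrix(wide[wide$dyad_id == j, obs, drop = FALSE])
    nj <- nrow(Y)
    dimv <- nj * p + q
    V <- matrix(0, dimv, dimv)
    for (t in 1:nj) {
      for (s in 1:nj) {
        V[((t - 1) * p + 1):(t * p), ((s - 1) * p + 1):(s * p)] <-
          SB[1:p, 1:p] + (t == s) * SW
      }
    }
    if (q > 0) {
      z <- dat$U_all[match(j, used), (p + 1):m]
      for (t in 1:nj) {
        V[((t - 1) * p + 1):(t * p), (nj * p + 1):dimv] <- SB[1:p, (p + 1):m]
        V[(nj * p + 1):dimv, ((t - 1) * p + 1):(t * p)] <- SB[(p + 1):m, 1:p]
      }
      V[(nj * p + 1):dimv, (nj * p + 1):dimv] <- SB[(p + 1):m, (p + 1):m]
      y <- c(t(Y), z); mm <- c(rep(mu[1:p], nj), mu[(p + 1):m])
    } else {
      y <- c(t(Y)); mm <- rep(mu[1:p], nj)
    }
    ll <- ll + dmvn_log(y, mm, V)
  }
  ll
}

# Path-tracing oracle for the implied covariance: with an acyclic path
# matrix A, total effects are the finite Neumann sum I + A + A^2 + ... and
# the covariance of all variables is T S T'. Reads the parameter table
# directly, independent of the package's matrix-filling code path.
path_trace_sigma <- function(model, theta, level) {
  vars <- model[[level]]$vars
  nv <- length(vars)
  A <- matrix(0, nv, nv, dimnames = list(vars, vars))
  S <- matrix(0, nv, nv, dimnames = list(vars, vars))
  pt <- model$partable[model$partable$level == level, ]
  for (k in seq_len(nrow(pt))) {
    v <- if (pt$free[k]) theta[[pt$label[k]]] else pt$value[k]
    if (pt$mat[k] == "A") A[pt$row[k], pt$col[k]] <- v
    else { S[pt$row[k], pt$col[k]] <- v; S[pt$col[k], pt$row[k]] <- v }
  }
  Tm <- diag(nv); Ak <- diag(nv)
  for (k in seq_len(nv)) {   # A is nilpotent: the sum terminates
    Ak <- Ak %*% A
    if (all(Ak == 0)) break
    Tm <- Tm + Ak
  }
  C <- Tm %*% S %*% t(Tm)
  dimnames(C) <- list(vars, vars)
  C[model[[level]]$obs, model[[level]]$obs, drop = FALSE]
}

# random admissible parameter vector near the generator truth
perturb_theta <- function(model, gp, scale = 0.3) {
  th <- true_theta(model, gp)
  variances <- grepl("^(phi|psi|theta)_", names(th))
  th[variances] <- th[variances] * exp(runif(sum(variances), -scale, scale))
  th[!variances] <- th[!variances] +
    runif(sum(!variances), -scale, scale) * pmax(abs(th[!variances]), 0.2)
  th
}

# Quantile of the product of two independent normals by numeric integration
# of the exact CDF (quadrature oracle for the Monte Carlo interval).
product_normal_quantile <- function(prob, mu1, sd1, mu2, sd2) {
  cdf <- function(t) {
    f_pos <- function(x) pnorm((t / x - mu2) / sd2) * dnorm(x, mu1, sd1)
    f_neg <- function(x) (1 - pnorm((t / x - mu2) / sd2)) * dnorm(x, mu1, sd1)
    integrate(f_pos, 1e-12, Inf, rel.tol = 1e-10)$value +
      integrate(f_neg, -Inf, -1e-12, rel.tol = 1e-10)$value
  }
  uniroot(function(t) cdf(t) - prob, interval = c(-50, 50),
          tol = 1e-8)$root
}

# complete rectangular diary panel with deterministic filler scores
make_grid_panel <- function(n_dyads, n_days) {
  g <- expand.grid(role = c("PLWH", "partner"), day = seq_len(n_days),
                   dyad_id = seq_len(n_dyads), stringsAsFactors = FALSE)
  g <- g[, c("dyad_id", "day", "role")]
  n <- nrow(g)
  g$wda <- rep_len(c(3, 4, 5), n)
  g$cdc <- rep_len(c(15, 17, 19, 21), n)
  g$qol <- rep_len(c(4, 5), n)
  g$rs <- rep_len(c(4, 3, 5), n)
  g
}
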