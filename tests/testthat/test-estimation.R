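test_that("pooled moments match the hand formula on four numbers", {
  y <- c(0, 2, 4, 6)
  cl <- c(1, 1, 2, 2)
  pm <- pooled_moments(y, cl)
  # S_PW = ((0-1)^2 + (2-1)^2 + (4-5)^2 + (6-5)^2) / (4 - 2) = 2
  expect_equal(pm$s_pooled_within[1, 1], 2)
  # cluster means 1 and 5 around grand mean 3, weighted by n_j = 2
  expect_equal(pm$s_between[1, 1], (2 * 4 + 2 * 4) / 1)
  expect_equal(pm$cluster_sizes, c(2L, 2L))
  # identical rows within each cluster: no within variance
  pm0 <- pooled_moments(c(3, 3, 7, 7), cl)
  expect_equal(pm0$s_pooled_within[1, 1], 0)
  expect_error(pooled_moments(y, rep(1, 4)), "single cluster")
})

test_that("pooled within moments are consistent for the generator", {
  gp <- cfm_gen_params(n_dyads = 5000, n_days = 14, missing_rate = 0)
  model <- cfm_model("post_prep")
  th <- true_theta(model, gp)
  SW <- implied_moments(model, th)$sigma_within
  sim <- generate_panel(gp, seed = 31)
  dat <- cfm_data(model, sim$panel, sim$post)
  se <- sqrt((diag(SW) %o% diag(SW) + SW^2) / dat$N)
  expect_true(all(abs(dat$S_PW - SW) < 3 * se))
})

test_that("structured likelihood equals the dense-covariance oracle", {
  withr::local_seed(2)
  for (om in c("daily_qol", "post_qol", "daily_rs", "post_adherence")) {
    model <- cfm_model(om)
    gp <- cfm_gen_params(n_dyads = 5, n_days = 3, missing_rate = 0.2)
    sim <- generate_panel(gp, seed = 41)
    dat <- cfm_data(model, sim$panel, sim$post)
    for (k in 1:13) {
      th <- perturb_theta(model, gp)
      expect_equal(cfm_loglik(model, th, dat),
                   dense_loglik(model, th, sim$panel, sim$post),
                   tolerance = 1e-8)
    }
  }
})

test_that("a vanishing between level reduces to independent daily densities", {
  gp <- cfm_gen_params(n_dyads = 4, n_days = 3, missing_rate = 0)
  model <- cfm_model("post_prep")
  sim <- generate_panel(gp, seed = 51)
  dat <- cfm_data(model, sim$panel, sim$post)
  th <- true_theta(model, gp)
  # push every between-level (co)variance source toward zero; distal
  # variables keep their own variance but decouple from the daily block
  th[grep("^(phi|psi|theta)_b\\.", names(th))] <- 1e-10
  th[grep("^(b|c|a)_b", names(th))] <- 0
  th[["theta_b.prep_attitude"]] <- 13.5
  imp <- implied_moments(model, th)
  ll <- cfm_loglik(model, th, dat)
  # oracle: iid days plus an independent normal for the distal outcome
  wide <- merge(
    setNames(sim$panel[sim$panel$role == "PLWH", c("dyad_id", "day", "wda", "cdc")],
             c("dyad_id", "day", "wda_PLWH", "cdc_PLWH")),
    setNames(sim$panel[sim$panel$role == "partner", c("dyad_id", "day", "wda", "cdc")],
             c("dyad_id", "day", "wda_partner", "cdc_partner")),
    by = c("dyad_id", "day"))
  obs <- model$within$obs
  ll_days <- sum(apply(wide[, obs], 1, function(y) {
    dmvn_log(as.numeric(y), imp$mu[obs], imp$sigma_within)
  }))
  ll_z <- sum(dnorm(dat$U_all[, "prep_attitude"], imp$mu[["prep_attitude"]],
                    sqrt(13.5 + 3e-10), log = TRUE))
  expect_equal(ll, ll_days + ll_z, tolerance = 1e-4)
})

test_that("fitting is deterministic and monotone from the start values", {
  gp <- cfm_gen_params()
  model <- cfm_model("daily_qol")
  sim <- generate_panel(gp, seed = 61)
  f1 <- cfm_fit(model, sim$panel, config = list(fit_indices = FALSE))
  f2 <- cfm_fit(model, sim$panel, config = list(fit_indices = FALSE))
  expect_equal(f1$theta, f2$theta, tolerance = 1e-10)
  expect_true(f1$converged)
  dat <- cfm_data(model, sim$panel)
  ll_start <- cfm_loglik(model, commonfate:::start_theta(model, dat), dat)
  expect_gte(f1$loglik, ll_start)
  # the reported maximum dominates the likelihood at the generating truth
  expect_gte(f1$loglik, cfm_loglik(model, true_theta(model, gp), dat))
})

test_that("balanced complete data reproduce the closed-form moment estimator", {
  gp <- cfm_gen_params(n_dyads = 141, n_days = 14, missing_rate = 0)
  model <- cfm_model("daily_qol")
  sim <- generate_panel(gp, seed = 71)
  dat <- cfm_data(model, sim$panel)
  ref <- commonfate:::fit_reference_models(dat, model$obs_names)
  # ML of the unrestricted two-level model under balance: Sigma_W = S_PW
  # (divisor N - J) and Sigma_B = cov_ML(cluster means) - S_PW / n
  expect_equal(ref$sat$sigma_within, dat$S_PW, tolerance = 1e-4,
               ignore_attr = TRUE)
  Vm <- crossprod(sweep(dat$U_all, 2, colMeans(dat$U_all))) / dat$J
  SB_closed <- Vm - dat$S_PW / 14
  expect_equal(ref$sat$sigma_between, SB_closed, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("estimates are stable under 10% day-level MCAR deletion", {
  gp <- cfm_gen_params(n_dyads = 2000, n_days = 14, missing_rate = 0)
  model <- cfm_model("daily_qol")
  sim <- generate_panel(gp, seed = 81)
  f_full <- cfm_fit(model, sim$panel,
                    config = list(se = FALSE, fit_indices = FALSE))
  masked <- apply_mcar_mask(sim$panel, 0.10, seed = 82)
  f_miss <- cfm_fit(model, masked,
                    config = list(se = FALSE, fit_indices = FALSE))
  std_full <- standardize_solution(model, f_full$theta)
  std_miss <- standardize_solution(model, f_miss$theta)
  free <- std_full$free & std_full$level != "mean"
  expect_lt(max(abs(std_full$std[free] - std_miss$std[free])), 0.05)
})

test_that("fit indices follow their defining formulas", {
  # chi2_m = 10 on df 5 against chi2_b = 110 on df 10: CFI = 1 - 5/100
  idx <- fit_indices(loglik_m = -5, df_m = 5, loglik_sat = 0,
                     loglik_base = -55, df_base = 10, n_obs = 200)
  expect_equal(idx$chi2, 10)
  expect_equal(idx$cfi, 0.95)
  expect_equal(idx$tli, ((110 / 10) - (10 / 5)) / ((110 / 10) - 1))
  expect_equal(idx$rmsea, sqrt((10 - 5) / (5 * 200)))
  # a model matching the saturated likelihood is a perfect fit
  S <- diag(2); colnames(S) <- rownames(S) <- c("x", "y")
  idx0 <- fit_indices(loglik_m = -3, df_m = 5, loglik_sat = -3,
                      loglik_base = -9, df_base = 3, n_obs = 100,
                      s_within = S, s_between = S,
                      implied = list(sigma_within = S, sigma_between = S))
  expect_equal(idx0$chi2, 0)
  expect_equal(idx0$cfi, 1)
  expect_equal(idx0$rmsea, 0)
  expect_equal(idx0$srmr_within, 0)
  expect_equal(idx0$srmr_between, 0)
  # df = 0: RMSEA and TLI are not applicable
  idxna <- fit_indices(-5, 0, 0, -55, 10, 200)
  expect_true(is.na(idxna$rmsea))
  expect_true(is.na(idxna$tli))
})

test_that("a full fit reports sane indices and standard errors", {
  gp <- cfm_gen_params()
  model <- cfm_model("daily_rs")
  sim <- generate_panel(gp, seed = 91)
  fit <- cfm_fit(model, sim$panel)
  expect_true(fit$converged)
  expect_equal(fit$df,
               6 + 21 + 21 - fit$np)
  expect_gte(fit$fit$chi2, 0)
  expect_true(fit$fit$cfi >= 0 && fit$fit$cfi <= 1)
  expect_gte(fit$fit$rmsea, 0)
  se <- fit$partable$se[fit$partable$free]
  expect_true(all(is.finite(se) & se > 0))
  # Wald z and p are consistent
  pt <- fit$partable[fit$partable$label == "a_w", ]
  expect_equal(pt$p, 2 * pnorm(-abs(pt$value / pt$se)))
})

test_that("binary adherence suppresses fit indices", {
  gp <- cfm_gen_params()
  sim <- generate_panel(gp, seed = 95)
  fit <- cfm_fit(cfm_model("post_adherence"), sim$panel, sim$post)
  expect_null(fit$fit)
  expect_match(fit$fit_note, "binary")
})

test_that("a between-level covariate coefficient is recovered", {
  gp <- cfm_gen_params(n_dyads = 600, missing_rate = 0)
  sim <- generate_panel(gp, seed = 97, keep_latents = TRUE)
  lat <- attr(sim$panel, "latents")
  # dyad-level covariate correlated with the shared appraisal latent,
  # shifted into the coping reports with a known coefficient of 2
  withr::local_seed(98)
  covdat <- data.frame(dyad_id = seq_len(gp$n_dyads),
                       age = 0.5 * lat$between$wda + rnorm(gp$n_dyads))
  panel <- sim$panel
  bump <- 2 * covdat$age[match(panel$dyad_id, covdat$dyad_id)]
  panel$cdc <- panel$cdc + bump
  model <- cfm_model("post_prep", covariates = "age")
  fit <- cfm_fit(model, panel, sim$post, covariate_data = covdat,
                 config = list(fit_indices = FALSE))
  est <- fit$theta[["gamma_b.age.cdc_shared"]]
  se <- fit$partable$se[fit$partable$label == "gamma_b.age.cdc_shared"]
  expect_lt(abs(est - 2), 3 * se)
})
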