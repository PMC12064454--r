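test_that("a complete design yields the full person-day grid", {
  gp <- cfm_gen_params(n_dyads = 5, n_days = 3, missing_rate = 0)
  sim <- generate_panel(gp, seed = 1)
  expect_equal(nrow(sim$panel), 5 * 3 * 2)
  expect_false(anyDuplicated(sim$panel[, c("dyad_id", "day", "role")]) > 0)
  expect_equal(nrow(sim$post), 5)
  # both roles present for every dyad
  expect_true(all(table(sim$panel$dyad_id, sim$panel$role) > 0))
})

test_that("generation is deterministic given the seed", {
  gp <- cfm_gen_params(n_dyads = 10, n_days = 4)
  s1 <- generate_panel(gp, seed = 42)
  s2 <- generate_panel(gp, seed = 42)
  expect_identical(s1, s2)
  s3 <- generate_panel(gp, seed = 43)
  expect_false(identical(s1$panel, s3$panel))
  # byte-identical files on disk
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_diary_csv(s1$panel, f1)
  write_diary_csv(s2$panel, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("MCAR masking behaves at the boundaries and at the study rate", {
  gp <- cfm_gen_params(n_dyads = 141, n_days = 14, missing_rate = 0)
  panel <- generate_panel(gp, seed = 5)$panel
  expect_identical(apply_mcar_mask(panel, 0), panel)
  expect_warning(empty <- apply_mcar_mask(panel, 1, seed = 1), "masked")
  expect_equal(nrow(empty), 0)
  expect_error(apply_mcar_mask(panel, -0.1), "probability")
  # at the study's missingness the retained count sits in the binomial
  # 99% band around 3774 of 3948
  kept <- nrow(apply_mcar_mask(panel, 0.044, seed = 7))
  band <- qbinom(c(0.005, 0.995), 3948, 1 - 0.044)
  expect_gte(kept, band[1])
  expect_lte(kept, band[2])
})

test_that("retained latents reproduce the structural paths at both levels", {
  gp <- cfm_gen_params(n_dyads = 5000, n_days = 14, missing_rate = 0)
  sim <- generate_panel(gp, seed = 11, keep_latents = TRUE)
  lat <- attr(sim$panel, "latents")
  fb <- lm(cdc ~ wda, data = lat$between)
  expect_lt(abs(coef(fb)[["wda"]] - 2.08), 2 * summary(fb)$coefficients["wda", 2])
  fw <- lm(cdc ~ wda, data = lat$within)
  expect_lt(abs(coef(fw)[["wda"]] - 4.78), 2 * summary(fw)$coefficients["wda", 2])
})

test_that("sample moments match the model-implied covariances", {
  gp <- cfm_gen_params(n_dyads = 5000, n_days = 14, missing_rate = 0)
  model <- cfm_model("daily_qol")
  th <- true_theta(model, gp)
  imp <- implied_moments(model, th)
  sim <- generate_panel(gp, seed = 12)
  dat <- cfm_data(model, sim$panel)
  # pooled within covariance, elementwise within 3 Monte Carlo SEs
  SW <- imp$sigma_within
  N <- dat$N
  se_w <- sqrt((diag(SW) %o% diag(SW) + SW^2) / N)
  expect_true(all(abs(dat$S_PW - SW) < 3 * se_w))
  # covariance of cluster means estimates Sigma_B + Sigma_W / n
  SM <- imp$sigma_between + SW / 14
  se_b <- sqrt((diag(SM) %o% diag(SM) + SM^2) / dat$J)
  expect_true(all(abs(cov(dat$U_all) - SM) < 3 * se_b))
  expect_true(all(abs(colMeans(dat$U_all) - imp$mu) < 3 * sqrt(diag(SM) / dat$J)))
})

test_that("generated indicator ICC equals the implied between share", {
  gp <- cfm_gen_params(n_dyads = 2000, n_days = 14, missing_rate = 0)
  sim <- generate_panel(gp, seed = 13)
  share <- gp$var_between / (gp$var_between + gp$var_within)
  for (v in c("wda", "cdc", "qol")) {
    s <- sim$panel[sim$panel$role == "PLWH", ]
    expect_equal(icc_anova(s[[v]], s$dyad_id),
                 unname(share[[paste0(v, "_PLWH")]]), tolerance = 0.02)
  }
})

test_that("the Likert switch produces in-range integer scores", {
  gp <- cfm_gen_params(n_dyads = 50, n_days = 5, likert = TRUE,
                       missing_rate = 0)
  sim <- generate_panel(gp, seed = 3)
  for (v in c("wda", "qol", "rs")) {
    expect_true(all(sim$panel[[v]] == round(sim$panel[[v]])))
    expect_true(all(sim$panel[[v]] >= 0 & sim$panel[[v]] <= 6))
  }
  expect_true(all(sim$panel$cdc >= 0 & sim$panel$cdc <= 30))
  expect_true(all(sim$post$adherence_days %in% 0:30))
  expect_true(all(sim$post$prep_attitude >= 0 & sim$post$prep_attitude <= 20))
})

test_that("the adherent fraction tracks its target", {
  gp <- cfm_gen_params(n_dyads = 20000)
  sim <- generate_panel(gp, seed = 21)
  frac <- mean(sim$post$adherence_days > 28)
  expect_lt(abs(frac - 0.149), 3 * sqrt(0.149 * 0.851 / 20000))
})
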