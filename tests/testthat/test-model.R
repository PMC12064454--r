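test_that("model layouts follow the common fate structure", {
  m1 <- cfm_model("daily_qol")
  expect_setequal(m1$within$latents, c("wda_shared", "cdc_shared"))
  expect_setequal(m1$within$obs,
                  c("wda_PLWH", "wda_partner", "cdc_PLWH", "cdc_partner",
                    "qol_PLWH", "qol_partner"))
  # daily QoL is two partner-specific observed outcomes, not a latent
  expect_false("qol_shared" %in% m1$within$vars)
  expect_true(all(c("b_w.qol_PLWH", "b_w.qol_partner", "c_w.qol_PLWH",
                    "c_w.qol_partner", "a_w", "a_b") %in% m1$partable$label))

  m5 <- cfm_model("daily_rs")
  expect_true("rs_shared" %in% m5$within$latents)
  expect_true("rs_shared" %in% m5$between$latents)
  loadings <- subset(m5$partable, level == "within" & mat == "A" & !free &
                       col == "rs_shared")
  expect_setequal(loadings$row, c("rs_PLWH", "rs_partner"))

  m3 <- cfm_model("post_adherence")
  expect_false("adherent" %in% m3$within$obs)
  expect_true("adherent" %in% m3$between$obs)
  expect_false(any(grepl("^b_w\\.", m3$partable$label)))
  expect_true("b_b.adherent" %in% m3$partable$label)

  m6 <- cfm_model("post_rs")
  expect_true("rs_post_shared" %in% m6$between$latents)
  expect_false("rs_post_shared" %in% m6$within$vars)

  expect_error(cfm_model("daily_mood"), "arg")
})

test_that("every common-fate latent has exactly one indicator per partner", {
  for (om in cfm_outcomes()) {
    m <- cfm_model(om)
    pt <- m$partable
    for (level in c("within", "between")) {
      loadings <- pt[pt$level == level & pt$mat == "A" & !pt$free, ]
      for (lat in unique(loadings$col)) {
        ind <- loadings$row[loadings$col == lat]
        expect_length(ind, 2)
        expect_length(grep("PLWH", ind), 1)
        expect_length(grep("partner", ind), 1)
      }
    }
  }
})

test_that("implied moments reduce to the closed form for a single latent", {
  # with the a-path at zero the shared-appraisal block is a one-factor,
  # two-indicator model: Sigma = [[phi+t1, phi], [phi, phi+t2]]
  m <- cfm_model("post_prep")
  gp <- cfm_gen_params()
  th <- true_theta(m, gp)
  th[c("a_w", "a_b")] <- 0
  imp <- implied_moments(m, th)
  phi <- th[["phi_w.wda_shared"]]
  expect_equal(imp$sigma_within["wda_PLWH", "wda_partner"], phi)
  expect_equal(imp$sigma_within["wda_PLWH", "wda_PLWH"],
               phi + th[["theta_w.wda_PLWH"]])
  expect_equal(imp$sigma_within["wda_PLWH", "cdc_PLWH"], 0)
  psi <- th[["psi_b.cdc_shared"]]
  expect_equal(imp$sigma_between["cdc_PLWH", "cdc_partner"], psi)
})

test_that("implied moments agree with a path-tracing oracle on every spec", {
  gp <- cfm_gen_params()
  withr::local_seed(1)
  for (om in cfm_outcomes()) {
    m <- cfm_model(om)
    for (k in 1:17) {  # ~100 level checks per suite run
      th <- perturb_theta(m, gp)
      imp <- implied_moments(m, th)
      expect_equal(imp$sigma_within,
                   path_trace_sigma(m, th, "within"), tolerance = 1e-10)
      expect_equal(imp$sigma_between,
                   path_trace_sigma(m, th, "between"), tolerance = 1e-10)
      expect_true(isSymmetric(imp$sigma_within, tol = 1e-12))
      ev <- eigen(imp$sigma_between, symmetric = TRUE, only.values = TRUE)
      expect_gte(min(ev$values), -1e-10)
    }
  }
})

test_that("standardization follows b * SD(source) / SD(target)", {
  m <- cfm_model("post_prep")
  gp <- cfm_gen_params()
  th <- true_theta(m, gp)
  pt <- standardize_solution(m, th)
  # hand computation at the within level
  sd_w <- sqrt(th[["phi_w.wda_shared"]])
  v_cdc <- th[["a_w"]]^2 * th[["phi_w.wda_shared"]] + th[["psi_w.cdc_shared"]]
  expect_equal(pt$std[pt$label == "a_w"], th[["a_w"]] * sd_w / sqrt(v_cdc))
  # a zero path standardizes to zero
  th0 <- th; th0[["a_w"]] <- 0
  pt0 <- standardize_solution(m, th0)
  expect_equal(pt0$std[pt0$label == "a_w"], 0)
  # fixed unit loadings give level-specific standardized loadings in (0, 1),
  # unequal when residual variances are unequal
  lw <- pt$std[pt$mat == "A" & !pt$free & pt$level == "within"]
  expect_true(all(lw > 0 & lw < 1))
  expect_gt(max(abs(outer(lw, lw, "-"))), 0.001)
})

test_that("standardized solution is invariant to rescaling an indicator", {
  m <- cfm_model("daily_qol")
  gp <- cfm_gen_params()
  th <- true_theta(m, gp)
  base <- standardize_solution(m, th)
  k <- 10
  # rescale the observed outcome qol_PLWH by k at both levels
  th2 <- th
  for (tag in c("w", "b")) {
    th2[[paste0("b_", tag, ".qol_PLWH")]] <-
      th[[paste0("b_", tag, ".qol_PLWH")]] * k
    th2[[paste0("c_", tag, ".qol_PLWH")]] <-
      th[[paste0("c_", tag, ".qol_PLWH")]] * k
    th2[[paste0("theta_", tag, ".qol_PLWH")]] <-
      th[[paste0("theta_", tag, ".qol_PLWH")]] * k^2
  }
  th2[["mu.qol_PLWH"]] <- th[["mu.qol_PLWH"]] * k
  resc <- standardize_solution(m, th2)
  expect_equal(resc$std[resc$mat != "mu"], base$std[base$mat != "mu"],
               tolerance = 1e-10)
})

test_that("a model specification serializes to JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  m <- cfm_model("daily_rs")
  model_to_json(m, path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(x$outcome, "daily_rs")
  expect_setequal(names(x$partable),
                  c("label", "level", "mat", "row", "col", "free", "value",
                    "transform"))
  expect_equal(sum(x$partable$free), sum(m$partable$free))
})

test_that("covariates enter the between level as exogenous regressors", {
  m <- cfm_model("daily_qol", covariates = c("age", "income"))
  labs <- m$partable$label
  expect_true("gamma_b.age.cdc_shared" %in% labs)
  expect_true("gamma_b.age.qol_PLWH" %in% labs)
  expect_true("varcov_b.age.wda_shared" %in% labs)
  expect_true("varcov_b.age.income" %in% labs)
  expect_false(any(grepl("gamma_b.age.wda_shared", labs, fixed = TRUE)))
  expect_true(all(c("mu.age", "mu.income") %in% labs))
})
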