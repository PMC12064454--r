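#' Generate a synthetic dyadic diary panel and post-diary table
#'
#' Simulates the two-level common fate structure forward: for each dyad a
#' between-level shared we-disease appraisal latent is drawn, shared dyadic
#' coping and relationship-satisfaction latents follow the between-level
#' structural equations, and each day's within-level latents follow the same
#' equations with within-level coefficients. Observed scores are
#' mean + between latent part + between residual + within latent part +
#' within residual, with all loadings fixed at 1. Post-diary outcomes are
#' linear in the between-level latents; ART adherence days are
#' `30 - min(Poisson(lambda), 30)` with `lambda` solved so that
#' `P(days > 28)` equals `params$adherent_frac`. Finally, person-day records
#' are removed completely at random at `params$missing_rate`.
#'
#' @param params a [cfm_gen_params()] object.
#' @param seed integer seed; the run is deterministic given the seed.
#' @param keep_latents if `TRUE`, attach the true latent draws as the
#'   `"latents"` attribute of the returned panel (debug mode, used to verify
#'   the generator against its own structural equations).
#' @return a list with `panel` (long data frame: `dyad_id`, `day`, `role`,
#'   `wda`, `cdc`, `qol`, `rs`; one row per observed person-day) and `post`
#'   (one row per dyad: `qol_plwh`, `qol_partner`, `adherence_days`,
#'   `prep_attitude`, `rs_plwh`, `rs_partner`).
#' @export
#' @examples
#' sim <- generate_panel(cfm_gen_params(n_dyads = 5, n_days = 3,
#'                                      missing_rate = 0), seed = 1)
#' nrow(sim$panel)  # 5 * 3 * 2
generate_panel <- function(params, seed = params$seed, keep_latents = FALSE) {
  validate_gen_params(params)
  J <- params$n_dyads
  D <- params$n_days
  lw <- params$latent_var$within
  lb <- params$latent_var$between
  dw <- params$disturbance_var$within
  db <- params$disturbance_var$between
  rw <- params$resid_var$within
  rb <- params$resid_var$between
  rp <- params$resid_var$post
  mu <- params$means
  pw <- params$paths_within
  pb <- params$paths_between

  with_seed(seed, {
    # between-level latents, one per dyad
    W_B <- rnorm(J, 0, sqrt(lb[["wda"]]))
    C_B <- params$a_between * W_B + rnorm(J, 0, sqrt(db[["cdc"]]))
    RS_B <- pb$rs$c * W_B + pb$rs$b * C_B + rnorm(J, 0, sqrt(db[["rs"]]))
    RSP_B <- pb$post_rs$c * W_B + pb$post_rs$b * C_B +
      rnorm(J, 0, sqrt(db[["post_rs"]]))
    eB <- lapply(rb, function(v) rnorm(J, 0, sqrt(v)))

    # within-level latents, one per dyad-day
    n <- J * D
    dyad <- rep(seq_len(J), each = D)
    day <- rep(seq_len(D), J)
    W_W <- rnorm(n, 0, sqrt(lw[["wda"]]))
    C_W <- params$a_within * W_W + rnorm(n, 0, sqrt(dw[["cdc"]]))
    RS_W <- pw$rs$c * W_W + pw$rs$b * C_W + rnorm(n, 0, sqrt(dw[["rs"]]))
    eW <- lapply(rw, function(v) rnorm(n, 0, sqrt(v)))

    obs <- function(var, role) {
      key <- paste0(var, "_", role)
      bet <- switch(var,
        wda = W_B,
        cdc = C_B,
        rs  = RS_B,
        qol = pb$qol$c[[role]] * W_B + pb$qol$b[[role]] * C_B
      ) + eB[[key]]
      wit <- switch(var,
        wda = W_W,
        cdc = C_W,
        rs  = RS_W,
        qol = pw$qol$c[[role]] * W_W + pw$qol$b[[role]] * C_W
      ) + eW[[key]]
      mu$daily[[key]] + bet[dyad] + wit
    }
    role_frame <- function(role) {
      data.frame(dyad_id = dyad, day = day, role = role,
                 wda = obs("wda", role), cdc = obs("cdc", role),
                 qol = obs("qol", role), rs = obs("rs", role),
                 stringsAsFactors = FALSE)
    }
    panel <- rbind(role_frame("PLWH"), role_frame("partner"))
    panel <- panel[order(panel$dyad_id, panel$day, panel$role), ]
    rownames(panel) <- NULL

    lambda <- uniroot(function(l) ppois(1, l) - params$adherent_frac,
                      c(1e-8, 100))$root
    post <- data.frame(
      dyad_id = seq_len(J),
      qol_plwh = mu$post[["post_qol_PLWH"]] +
        pb$post_qol$c[["PLWH"]] * W_B + pb$post_qol$b[["PLWH"]] * C_B +
        rnorm(J, 0, sqrt(rp[["post_qol_PLWH"]])),
      qol_partner = mu$post[["post_qol_partner"]] +
        pb$post_qol$c[["partner"]] * W_B + pb$post_qol$b[["partner"]] * C_B +
        rnorm(J, 0, sqrt(rp[["post_qol_partner"]])),
      adherence_days = 30L - pmin(rpois(J, lambda), 30L),
      prep_attitude = mu$post[["prep_attitude"]] +
        pb$prep$c * W_B + pb$prep$b * C_B +
        rnorm(J, 0, sqrt(rp[["prep_attitude"]])),
      rs_plwh = mu$post[["post_rs_PLWH"]] + RSP_B +
        rnorm(J, 0, sqrt(rp[["post_rs_PLWH"]])),
      rs_partner = mu$post[["post_rs_partner"]] + RSP_B +
        rnorm(J, 0, sqrt(rp[["post_rs_partner"]]))
    )

    if (params$likert) {
      clip <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)
      for (v in c("wda", "qol", "rs")) panel[[v]] <- clip(panel[[v]], 0, 6)
      panel$cdc <- clip(panel$cdc, 0, 30)
      post$qol_plwh <- clip(post$qol_plwh, 0, 116)
      post$qol_partner <- clip(post$qol_partner, 0, 96)
      post$prep_attitude <- clip(post$prep_attitude, 0, 20)
      post$rs_plwh <- clip(post$rs_plwh, 0, 20)
      post$rs_partner <- clip(post$rs_partner, 0, 20)
    }

    if (params$missing_rate > 0) {
      keep <- runif(nrow(panel)) >= params$missing_rate
      panel <- panel[keep, , drop = FALSE]
      rownames(panel) <- NULL
    }

    if (keep_latents) {
      attr(panel, "latents") <- list(
        between = data.frame(dyad_id = seq_len(J), wda = W_B, cdc = C_B,
                             rs = RS_B, post_rs = RSP_B),
        within = data.frame(dyad_id = dyad, day = day, wda = W_W, cdc = C_W,
                            rs = RS_W)
      )
    }
    list(panel = panel, post = post)
  })
}

#' Remove person-day records completely at random
#'
#' Each record of the panel is removed independently with probability `rate`,
#' emulating skipped diary days under the weakest missingness mechanism
#' compatible with full-information maximum likelihood.
#'
#' @param panel a diary panel (long data frame, one row per person-day).
#' @param rate probability of removal, in \[0, 1\].
#' @param seed optional seed; `NULL` draws from the current RNG stream.
#' @return the masked panel; a warning is emitted if everything was removed.
#' @export
apply_mcar_mask <- function(panel, rate, seed = NULL) {
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate > 1) {
    stop("rate must be a probability in [0, 1]")
  }
  if (rate == 0) return(panel)
  out <- with_seed(seed, {
    keep <- runif(nrow(panel)) >= rate
    panel[keep, , drop = FALSE]
  })
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("all person-day records were masked out")
  out
}
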