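#' Read and write the tidy diary CSV
#'
#' Fixed dialect: UTF-8, comma separator, header row
#' `dyad_id,day,role,wda,cdc,qol,rs`, empty cell = missing, days 1-based.
#'
#' @param panel diary panel data frame.
#' @param path file path.
#' @return `write_diary_csv` returns `path` invisibly; `read_diary_csv`
#'   returns the panel with a parse error (including the offending row
#'   number) on malformed input.
#' @export
write_diary_csv <- function(panel, path) {
  write.csv(panel[, c("dyad_id", "day", "role", "wda", "cdc", "qol", "rs")],
            path, row.names = FALSE, na = "", fileEncoding = "UTF-8",
            quote = FALSE)
  invisible(path)
}

#' @rdname write_diary_csv
#' @export
read_diary_csv <- function(path) {
  if (!file.exists(path)) stop_data("no such file: %s", path)
  x <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
             na.strings = ""),
    error = function(e) stop_data("cannot parse %s: %s", path, conditionMessage(e)))
  need <- c("dyad_id", "day", "role", "wda", "cdc", "qol", "rs")
  if (!identical(names(x)[seq_along(need)], need)) {
    stop_data("%s: expected header %s", path, paste(need, collapse = ","))
  }
  if (nrow(x) == 0) stop_data("%s: no records", path)
  for (col in c("day", "wda", "cdc", "qol", "rs")) {
    bad <- which(!is.na(x[[col]]) & is.na(suppressWarnings(as.numeric(x[[col]]))))
    if (length(bad)) {
      stop_data("%s: non-numeric '%s' at data row %d", path, col, bad[1])
    }
    x[[col]] <- as.numeric(x[[col]])
  }
  bad_role <- which(!x$role %in% c("PLWH", "partner"))
  if (length(bad_role)) {
    stop_data("%s: unknown role at data row %d", path, bad_role[1])
  }
  if (anyDuplicated(x[, c("dyad_id", "day", "role")])) {
    stop_data("%s: duplicate (dyad_id, day, role) records", path)
  }
  x
}

#' Read and write the post-diary CSV
#'
#' One row per dyad: `dyad_id,qol_plwh,qol_partner,adherence_days,
#' prep_attitude,rs_plwh,rs_partner`; empty cell = missing.
#'
#' @param post post-diary data frame.
#' @param path file path.
#' @export
write_post_csv <- function(post, path) {
  write.csv(post, path, row.names = FALSE, na = "", fileEncoding = "UTF-8",
            quote = FALSE)
  invisible(path)
}

#' @rdname write_post_csv
#' @export
read_post_csv <- function(path) {
  if (!file.exists(path)) stop_data("no such file: %s", path)
  x <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                na.strings = "")
  need <- c("dyad_id", "qol_plwh", "qol_partner", "adherence_days",
            "prep_attitude", "rs_plwh", "rs_partner")
  if (!all(need %in% names(x))) {
    stop_data("%s: missing columns %s", path,
              paste(setdiff(need, names(x)), collapse = ", "))
  }
  if (anyDuplicated(x$dyad_id)) stop_data("%s: duplicate dyad_id", path)
  x
}

#' Serialize a fitted model to JSON
#'
#' Stores the outcome name, the parameter table (estimates, SEs,
#' standardized solution), the free-parameter covariance, log-likelihoods,
#' fit indices and convergence metadata - enough to reconstruct mediation
#' inference without refitting.
#'
#' @param fit a [cfm_fit()] object.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  x <- list(
    outcome = fit$model$outcome,
    covariates = fit$model$covariates,
    partable = fit$partable,
    theta = as.list(fit$theta),
    vcov = fit$vcov,
    vcov_labels = rownames(fit$vcov),
    loglik = fit$loglik,
    loglik_saturated = fit$loglik_saturated,
    loglik_baseline = fit$loglik_baseline,
    np = fit$np, df = fit$df,
    fit = fit$fit, fit_note = fit$fit_note,
    converged = fit$converged, grad_norm = fit$grad_norm,
    n_clusters = fit$n_clusters, n_obs = fit$n_obs,
    meta = fit$meta,
    version = as.character(packageVersion("commonfate")))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", matrix = "rowmajor",
                       null = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- cfm_model(x$outcome, covariates = x$covariates %||% character())
  vcov <- NULL
  if (!is.null(x$vcov)) {
    vcov <- as.matrix(x$vcov)
    dimnames(vcov) <- list(x$vcov_labels, x$vcov_labels)
  }
  fit <- list(model = model,
              partable = as.data.frame(x$partable),
              theta = unlist(x$theta),
              vcov = vcov,
              loglik = x$loglik,
              loglik_saturated = x$loglik_saturated,
              loglik_baseline = x$loglik_baseline,
              np = x$np, df = x$df, fit = x$fit, fit_note = x$fit_note,
              converged = isTRUE(x$converged), grad_norm = x$grad_norm,
              n_clusters = x$n_clusters, n_obs = x$n_obs, meta = x$meta)
  class(fit) <- "cfm_fit"
  fit
}

#' Human-readable parameter table for a fitted model
#'
#' One row per parameter in the conventional layout of multilevel SEM
#' reports: parameter, unstandardized estimate, SE, standardized estimate,
#' Wald z, p.
#'
#' @param fit a `cfm_fit`.
#' @return character vector of formatted lines.
#' @export
fit_table <- function(fit) {
  pt <- fit$partable
  fmt <- function(v, d = 3) ifelse(is.na(v), "-", sprintf(paste0("%.", d, "f"), v))
  lines <- c(
    sprintf("Model: %s   (logLik %.2f, %d dyads, %d person-days)",
            fit$model$outcome, fit$loglik, fit$n_clusters, fit$n_obs),
    sprintf("%-36s %9s %8s %8s %8s %8s",
            "Parameter", "b", "SE", "beta", "z", "p"))
  for (level in c("within", "between")) {
    lines <- c(lines, sprintf("Level: %s", level))
    rows <- pt[pt$level == level & pt$mat == "A", , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      nm <- paste0(rows$col[k], " -> ", rows$row[k])
      lines <- c(lines, sprintf("%-36s %9s %8s %8s %8s %8s", nm,
                                fmt(rows$value[k], 2), fmt(rows$se[k], 2),
                                fmt(rows$std[k], 2), fmt(rows$z[k], 2),
                                fmt(rows$p[k], 3)))
    }
    vrows <- pt[pt$level == level & pt$mat == "S", , drop = FALSE]
    for (k in seq_len(nrow(vrows))) {
      nm <- paste0("var(", vrows$row[k], ")")
      lines <- c(lines, sprintf("%-36s %9s %8s %8s %8s %8s", nm,
                                fmt(vrows$value[k], 2), fmt(vrows$se[k], 2),
                                fmt(vrows$std[k], 2), "-", "-"))
    }
  }
  if (!is.null(fit$fit)) {
    lines <- c(lines, sprintf(
      "Fit: chi2(%d) = %.3f, CFI = %.3f, TLI = %.3f, RMSEA = %.3f, SRMR_within = %.3f, SRMR_between = %.3f",
      fit$fit$df, fit$fit$chi2, fit$fit$cfi, fit$fit$tli, fit$fit$rmsea,
      fit$fit$srmr_within, fit$fit$srmr_between))
  }
  if (!is.null(fit$fit_note)) lines <- c(lines, paste("Fit:", fit$fit_note))
  lines
}

#' One-line report row for a mediation result
#'
#' @param med a `cfm_mediation` object.
#' @return a one-row data frame (est, SE, CI limits).
#' @export
mediation_row <- function(med) {
  data.frame(level = med$level %||% NA_character_,
             outcome = med$outcome %||% NA_character_,
             est = med$est, se = med$se,
             ci_lower = med$ci_lower, ci_upper = med$ci_upper,
             reps = med$reps, conf_level = med$conf_level,
             stringsAsFactors = FALSE)
}

#' Write a descriptive report as CSV
#'
#' @param report a `cfm_descriptives` object.
#' @param path output CSV path for the per-variable table; the cross-partner
#'   correlations are merged in by variable.
#' @return `path`, invisibly.
#' @export
write_descriptives_csv <- function(report, path) {
  tab <- merge(report$daily, report$cross_partner, by = "variable",
               all.x = TRUE, sort = FALSE)
  write.csv(tab, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
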