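#' Intraclass correlation by one-way random-effects ANOVA
#'
#' `icc = (MSB - MSW) / (MSB + (n0 - 1) MSW)`, with the standard unbalanced
#' correction `n0 = (N - sum(n_j^2) / N) / (J - 1)`; negative estimates are
#' truncated to zero.
#'
#' @param values numeric scores, one per observation (NAs dropped).
#' @param clusters cluster identifier per observation.
#' @return the ICC estimate in \[0, 1\].
#' @export
icc_anova <- function(values, clusters) {
  ok <- !is.na(values) & !is.na(clusters)
  values <- values[ok]
  cl <- factor(clusters[ok])
  cl <- droplevels(cl)
  J <- nlevels(cl)
  if (J < 2) stop("need at least 2 clusters")
  nj <- as.integer(table(cl))
  N <- length(values)
  if (N == J) stop("all clusters are singletons; within variance undefined")
  ybar <- tapply(values, cl, mean)
  gbar <- mean(values)
  msb <- sum(nj * (ybar - gbar)^2) / (J - 1)
  msw <- sum((values - ybar[cl])^2) / (N - J)
  n0 <- (N - sum(nj^2) / N) / (J - 1)
  max(0, (msb - msw) / (msb + (n0 - 1) * msw))
}

#' Within- and between-cluster correlations
#'
#' `r_within` is the Pearson correlation of cluster-mean-centered scores;
#' `r_between` is the Pearson correlation of cluster means.
#'
#' @param x,y numeric vectors (pairwise-complete observations are used).
#' @param clusters cluster identifier per observation.
#' @return list with `r_within` and `r_between`.
#' @export
within_between_corr <- function(x, y, clusters) {
  ok <- !is.na(x) & !is.na(y) & !is.na(clusters)
  x <- x[ok]; y <- y[ok]
  cl <- droplevels(factor(clusters[ok]))
  if (nlevels(cl) < 2) stop("need at least 2 clusters")
  xbar <- tapply(x, cl, mean)
  ybar <- tapply(y, cl, mean)
  xw <- x - xbar[cl]
  yw <- y - ybar[cl]
  if (sd(xw) == 0 || sd(yw) == 0 || sd(xbar) == 0 || sd(ybar) == 0) {
    stop("zero variance at one level")
  }
  list(r_within = cor(xw, yw), r_between = cor(xbar, ybar))
}

#' Diary completion rate
#'
#' Observed person-day records as a percentage of the full
#' `n_dyads x n_days x 2` grid, rounded half-up to one decimal.
#'
#' @param panel diary panel (one row per observed person-day).
#' @param n_dyads,n_days expected design size.
#' @return percentage in \[0, 100\].
#' @export
#' @examples
#' # 3774 observed of 141 * 14 * 2 = 3948 slots -> 95.6
completion_rate <- function(panel, n_dyads, n_days) {
  if (n_dyads < 1 || n_days < 1) stop("empty expected grid")
  round_half_up(100 * nrow(panel) / (n_dyads * n_days * 2), 1)
}

#' Categorize ART adherence
#'
#' Adherent means taking medication on more than 28 of the last 30 days
#' (i.e. 29 or 30), the conventional 95% adherence standard.
#'
#' @param days integer vector in \[0, 30\].
#' @return factor with levels `non_adherent`, `adherent`.
#' @export
adherence_category <- function(days) {
  if (any(is.na(days)) || any(days < 0 | days > 30) ||
      any(days != round(days))) {
    stop("days must be integers in [0, 30]")
  }
  factor(ifelse(days > 28, "adherent", "non_adherent"),
         levels = c("non_adherent", "adherent"))
}

#' Screening flow accounting
#'
#' @param reached couples reached by site staff.
#' @param declined,ineligible,baseline_only exclusions.
#' @return list with `analytic_n` and each exclusion as a percent of those
#'   reached (one decimal, half-up).
#' @export
#' @examples
#' screening_flow(173, 20, 4, 8)$analytic_n  # 141
screening_flow <- function(reached, declined, ineligible, baseline_only) {
  counts <- c(reached, declined, ineligible, baseline_only)
  if (any(counts < 0)) stop("counts must be nonnegative")
  n <- reached - declined - ineligible - baseline_only
  if (n < 0) stop("exclusions exceed the number reached")
  pct <- function(k) round_half_up(100 * k / reached, 1)
  list(analytic_n = n,
       declined_percent = pct(declined),
       ineligible_percent = pct(ineligible),
       baseline_only_percent = pct(baseline_only))
}

#' Descriptive report for a diary panel
#'
#' Mean, SD and ANOVA ICC per daily variable and partner role (clustering at
#' the person level: dyad by role), the day-level (within) and person-level
#' (between) correlations between the two partners' reports of each
#' variable, the completion rate, and - when a post-diary table is supplied -
#' the adherent count and percentage.
#'
#' @param panel diary panel.
#' @param post optional post-diary table with `adherence_days`.
#' @param n_dyads,n_days expected design size for the completion rate
#'   (defaults to the observed maxima).
#' @return an object of class `cfm_descriptives`: a list with `daily` (per
#'   variable x role), `cross_partner` (per variable), `completion_percent`,
#'   and optionally `adherent_count` / `adherent_percent`.
#' @export
describe_panel <- function(panel, post = NULL,
                           n_dyads = length(unique(panel$dyad_id)),
                           n_days = max(panel$day)) {
  vars <- intersect(c("wda", "cdc", "qol", "rs"), names(panel))
  roles <- c("PLWH", "partner")
  rows <- list()
  for (v in vars) {
    for (r in roles) {
      s <- panel[panel$role == r, ]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, role = r,
        mean = mean(s[[v]], na.rm = TRUE),
        sd = sd(s[[v]], na.rm = TRUE),
        icc = icc_anova(s[[v]], s$dyad_id),
        stringsAsFactors = FALSE)
    }
  }
  cross <- list()
  for (v in vars) {
    a <- panel[panel$role == "PLWH", c("dyad_id", "day", v)]
    b <- panel[panel$role == "partner", c("dyad_id", "day", v)]
    mm <- merge(a, b, by = c("dyad_id", "day"))
    wc <- within_between_corr(mm[[paste0(v, ".x")]], mm[[paste0(v, ".y")]],
                              mm$dyad_id)
    cross[[length(cross) + 1L]] <- data.frame(
      variable = v, r_within = wc$r_within, r_between = wc$r_between,
      stringsAsFactors = FALSE)
  }
  out <- list(daily = do.call(rbind, rows),
              cross_partner = do.call(rbind, cross),
              completion_percent = completion_rate(panel, n_dyads, n_days))
  if (!is.null(post)) {
    adh <- adherence_category(post$adherence_days)
    out$adherent_count <- sum(adh == "adherent")
    out$adherent_percent <- round_half_up(100 * mean(adh == "adherent"), 1)
  }
  structure(out, class = "cfm_descriptives")
}

#' @export
print.cfm_descriptives <- function(x, ...) {
  cat("Daily diary descriptives (per variable and role):\n")
  d <- x$daily
  d$mean <- round(d$mean, 2); d$sd <- round(d$sd, 2); d$icc <- round(d$icc, 2)
  print(d, row.names = FALSE)
  cat("\nCross-partner correlations:\n")
  cc <- x$cross_partner
  cc$r_within <- round(cc$r_within, 2); cc$r_between <- round(cc$r_between, 2)
  print(cc, row.names = FALSE)
  cat(sprintf("\nCompletion rate: %.1f%%\n", x$completion_percent))
  if (!is.null(x$adherent_count)) {
    cat(sprintf("Adherent (> 28 days): %d (%.1f%%)\n",
                x$adherent_count, x$adherent_percent))
  }
  invisible(x)
}
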