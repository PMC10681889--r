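## Survival validation layer: KM, log-rank, Cox (Efron ties), Harrell's c,
## Schoenfeld proportionality, subgroup forest with Cochran's Q.
## Model fitting is delegated to the survival package; this module owns the
## report structure, the heterogeneity test and the MRD handling.

#' Log-scale transform for continuous MRD
#'
#' End-of-induction minimal residual disease is a fraction spanning several
#' orders of magnitude with a point mass near zero; models enter it as
#' `log10(mrd + 1e-5)`.
#'
#' @param mrd MRD as a fraction (0.0001 = 0.01 percent).
#' @return transformed values.
#' @export
mrd_log10 <- function(mrd) log10(mrd + 1e-5)

#' NCI risk group from age and white cell count
#'
#' Standard risk iff age 1-9 years and WCC < 50 x 10^9/L; high risk
#' otherwise (the conventional NCI definition).
#'
#' @param age_years age at diagnosis in years.
#' @param wcc presenting white cell count, x 10^9/L.
#' @return character vector, `"standard"` or `"high"`.
#' @export
nci_risk <- function(age_years, wcc) {
  ifelse(age_years >= 1 & age_years < 10 & wcc < 50, "standard", "high")
}

## ---- Kaplan-Meier ---------------------------------------------------------

#' Kaplan-Meier estimate per group
#'
#' Product-limit estimator with simultaneous decrement at tied event times,
#' Greenwood variance and log(-log)-transformed 95 percent confidence
#' intervals.
#'
#' @param time follow-up times (years), non-negative.
#' @param status event indicators (0/1).
#' @param group optional grouping factor; omitted = one curve.
#' @return an object of class `heh_km`: a data.frame with columns `group`,
#'   `time`, `n_risk`, `n_event`, `surv`, `std_err`, `lower`, `upper`, with
#'   the underlying `survfit` object in attribute `fit`.
#' @export
km_estimate <- function(time, status, group = NULL) {
  if (any(time < 0)) stop("negative follow-up time", call. = FALSE)
  if (all(time == 0)) stop("all follow-up times are zero", call. = FALSE)
  if (is.null(group)) group <- rep("all", length(time))
  df <- data.frame(time = time, status = status, group = as.factor(group))
  fit <- survival::survfit(survival::Surv(time, status) ~ group, data = df,
                           conf.type = "log-log")
  s <- summary(fit, censored = FALSE)
  grp <- if (is.null(s$strata)) rep(levels(df$group)[1L], length(s$time))
         else sub("^group=", "", as.character(s$strata))
  out <- data.frame(group = grp, time = s$time, n_risk = s$n.risk,
                    n_event = s$n.event, surv = s$surv,
                    std_err = s$std.err, lower = s$lower, upper = s$upper,
                    row.names = NULL)
  attr(out, "fit") <- fit
  attr(out, "groups") <- levels(df$group)
  class(out) <- c("heh_km", "data.frame")
  out
}

#' Read a KM curve at a landmark time
#'
#' Evaluates the step function at `at` years (left-continuous convention:
#' the estimate just after the last event time <= `at`).
#'
#' @param km a `heh_km` from [km_estimate()].
#' @param at landmark time, default 5 years.
#' @return a data.frame with one row per group: `surv`, `lower`, `upper`.
#' @export
km_at <- function(km, at = 5) {
  fit <- attr(km, "fit")
  s <- summary(fit, times = at, extend = TRUE)
  grp <- if (is.null(s$strata)) attr(km, "groups")
         else sub("^group=", "", as.character(s$strata))
  if (!length(s$lower)) s$lower <- rep(NA_real_, length(s$surv))
  if (!length(s$upper)) s$upper <- rep(NA_real_, length(s$surv))
  data.frame(group = grp, time = at, surv = s$surv,
             lower = s$lower, upper = s$upper, row.names = NULL)
}

#' Log-rank test between groups
#'
#' @param time,status follow-up and event indicator.
#' @param group grouping with >= 2 levels.
#' @return a list with `statistic` (chi-square), `df` and `p`.
#' @export
logrank <- function(time, status, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L)
    stop("log-rank requires at least two groups", call. = FALSE)
  fit <- survival::survdiff(survival::Surv(time, status) ~ group)
  df <- length(fit$n) - 1L
  list(statistic = fit$chisq, df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

## ---- Cox models -----------------------------------------------------------

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the partial likelihood with Efron tie handling (better behaved
#' under the heavy year-granularity ties registry data carry). Reports Wald
#' confidence intervals and p-values per covariate plus the likelihood-ratio
#' p for the model, Harrell's concordance, and bookkeeping counts.
#'
#' @param data a data.frame.
#' @param time_col,status_col endpoint columns.
#' @param covariates character vector of covariate column names; the first
#'   is conventionally the risk group.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return an object of class `heh_cox`: a list with a per-covariate
#'   data.frame `terms` (coef, se, hr, ci, p), `loglik`, `lr_p`,
#'   `concordance`, `n`, `n_event` and the underlying `coxph` fit.
#' @examples
#' d <- data.frame(t = c(1, 2, 3, 4, 5, 6), s = c(1, 1, 1, 1, 0, 1),
#'                 g = c(1, 1, 0, 1, 0, 0))
#' cox_fit(d, "t", "s", "g")$terms
#' @export
cox_fit <- function(data, time_col, status_col, covariates,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c(time_col, status_col, covariates) %in% names(data)))
  if (sum(data[[status_col]]) < 1L)
    stop("no events in dataset", call. = FALSE)
  for (v in covariates)
    if (length(unique(data[[v]])) < 2L)
      stop("covariate constant across all rows: ", v, call. = FALSE)

  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", status_col, ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = ties)
  if (!is.null(fit$info) && grepl("infinite", paste(fit$info, collapse = " ")))
    warning("possible complete separation in Cox fit")
  s <- summary(fit)
  terms <- data.frame(term = rownames(s$coefficients),
                      coef = s$coefficients[, "coef"],
                      se = s$coefficients[, "se(coef)"],
                      hr = exp(s$coefficients[, "coef"]),
                      lower = exp(s$coefficients[, "coef"] -
                                    stats::qnorm(0.975) * s$coefficients[, "se(coef)"]),
                      upper = exp(s$coefficients[, "coef"] +
                                    stats::qnorm(0.975) * s$coefficients[, "se(coef)"]),
                      p = s$coefficients[, "Pr(>|z|)"],
                      row.names = NULL)
  structure(list(terms = terms, loglik = fit$loglik,
                 lr_p = unname(s$logtest["pvalue"]),
                 concordance = unname(s$concordance["C"]),
                 n = s$n, n_event = s$nevent, ties = ties, fit = fit),
            class = "heh_cox")
}

#' @export
print.heh_cox <- function(x, ...) {
  cat(sprintf("<heh_cox> n = %d, events = %d (%s ties)\n",
              x$n, x$n_event, x$ties))
  t <- x$terms
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %s: HR %.2f (%.2f-%.2f), p = %.3g\n",
                t$term[i], t$hr[i], t$lower[i], t$upper[i], t$p[i]))
  cat(sprintf("  concordance %.3f\n", x$concordance))
  invisible(x)
}

#' Harrell's concordance index
#'
#' Fraction of usable (comparable) patient pairs in which the model's
#' predicted risk orders the observed survival correctly; tied predictions
#' count one half.
#'
#' @param cox a `heh_cox` fit.
#' @return concordance in \[0, 1\].
#' @export
harrell_c <- function(cox) {
  stopifnot(inherits(cox, "heh_cox"))
  cc <- survival::concordance(cox$fit)
  n_pairs <- sum(cc$count[c("concordant", "discordant", "tied.x")])
  if (n_pairs == 0) stop("no comparable pairs", call. = FALSE)
  unname(cc$concordance)
}

#' Proportional-hazards check via Schoenfeld residuals
#'
#' Scaled Schoenfeld residuals regressed on event time (identity transform);
#' chi-square test per covariate and globally.
#'
#' @param cox a `heh_cox` fit.
#' @return a data.frame with columns `term`, `chisq`, `df`, `p`; the last
#'   row is the global test.
#' @export
schoenfeld_check <- function(cox) {
  stopifnot(inherits(cox, "heh_cox"))
  if (cox$n_event < 2L)
    stop("Schoenfeld test needs at least two events", call. = FALSE)
  z <- survival::cox.zph(cox$fit, transform = "identity")
  data.frame(term = rownames(z$table), chisq = z$table[, "chisq"],
             df = z$table[, "df"], p = z$table[, "p"], row.names = NULL)
}

## ---- subgroup forest and heterogeneity ------------------------------------

#' Cochran's Q heterogeneity test over subgroup log hazard ratios
#'
#' Inverse-variance-weighted fixed-effect heterogeneity statistic:
#' Q = sum w_i (b_i - b_bar)^2 with w_i = 1/se_i^2, compared to chi-square on
#' k - 1 degrees of freedom.
#'
#' @param coefs subgroup log hazard ratios.
#' @param ses their standard errors.
#' @return a list with `Q`, `df`, `p` and the pooled log-HR `pooled`.
#' @export
cochran_q <- function(coefs, ses) {
  keep <- is.finite(coefs) & is.finite(ses) & ses > 0
  coefs <- coefs[keep]; ses <- ses[keep]
  if (length(coefs) < 2L)
    stop("heterogeneity test needs >= 2 subgroup estimates", call. = FALSE)
  w <- 1 / ses^2
  pooled <- sum(w * coefs) / sum(w)
  Q <- sum(w * (coefs - pooled)^2)
  df <- length(coefs) - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE),
       pooled = pooled)
}

#' Subgroup forest of the PR-vs-GR effect
#'
#' Fits the univariate group-effect Cox model within each level of each
#' stratification variable and tests heterogeneity of the log hazard ratios
#' across levels with Cochran's Q. Subgroups without at least one event in
#' each arm are dropped with a warning.
#'
#' @param data classified cohort restricted to merged groups GR/PR.
#' @param time_col,status_col endpoint columns.
#' @param group_col merged risk group column (reference = GR).
#' @param vars named list mapping a display name to a column of subgroup
#'   labels.
#' @return an object of class `heh_forest`: `estimates` (one row per
#'   variable x level: n, events, hr, ci, p) and `heterogeneity` (per
#'   variable: Q, df, p).
#' @export
subgroup_forest <- function(data, time_col, status_col,
                            group_col = "merged_group", vars) {
  stopifnot(is.list(vars), length(vars) > 0L)
  data[[group_col]] <- stats::relevel(factor(data[[group_col]]), ref = "GR")
  est <- NULL
  het <- NULL
  for (vn in names(vars)) {
    col <- vars[[vn]]
    lvls <- unique(as.character(data[[col]]))
    lvls <- lvls[order(lvls)]
    coefs <- ses <- numeric(0)
    for (lv in lvls) {
      sub <- data[as.character(data[[col]]) == lv, ]
      ev <- tapply(sub[[status_col]], sub[[group_col]], sum)
      if (length(ev) < 2L || any(is.na(ev)) || any(ev < 1)) {
        warning(sprintf("subgroup %s=%s dropped: missing events in an arm",
                        vn, lv))
        next
      }
      fit <- cox_fit(sub, time_col, status_col, group_col)
      tr <- fit$terms[1L, ]
      est <- rbind(est, data.frame(
        variable = vn, level = lv, n = fit$n, events = fit$n_event,
        coef = tr$coef, se = tr$se, hr = tr$hr,
        lower = tr$lower, upper = tr$upper, p = tr$p, row.names = NULL))
      coefs <- c(coefs, tr$coef); ses <- c(ses, tr$se)
    }
    if (length(coefs) >= 2L) {
      q <- cochran_q(coefs, ses)
      het <- rbind(het, data.frame(variable = vn, Q = q$Q, df = q$df,
                                   p = q$p, row.names = NULL))
    }
  }
  if (is.null(est)) stop("all subgroups dropped", call. = FALSE)
  structure(list(estimates = est, heterogeneity = het),
            class = "heh_forest")
}

#' @export
print.heh_forest <- function(x, ...) {
  cat("<heh_forest>\n")
  e <- x$estimates
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %s=%s: HR %.2f (%.2f-%.2f), n=%d, events=%d\n",
                e$variable[i], e$level[i], e$hr[i], e$lower[i], e$upper[i],
                e$n[i], e$events[i]))
  if (!is.null(x$heterogeneity)) {
    cat("  heterogeneity:\n")
    h <- x$heterogeneity
    for (i in seq_len(nrow(h)))
      cat(sprintf("    %s: Q = %.2f on %d df, p = %.3f\n",
                  h$variable[i], h$Q[i], h$df[i], h$p[i]))
  }
  invisible(x)
}
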