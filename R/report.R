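## Table-1-style validation report on a classified cohort.

ENDPOINTS <- c(relapse = "Relapse", event = "Event-free survival",
               death = "Overall survival")

# counts and percentages by group with a chi-square test
# (Fisher fallback when any expected cell < 5)
categorical_block <- function(values, group, variable) {
  tab <- table(values, group)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    p <- NA_real_; method <- "none"
  } else {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      p <- stats::fisher.test(tab)$p.value; method <- "fisher"
    } else {
      p <- stats::chisq.test(tab, correct = FALSE)$p.value; method <- "chisq"
    }
  }
  pct <- prop.table(tab, 2L) * 100
  out <- NULL
  for (lv in rownames(tab))
    out <- rbind(out, data.frame(
      variable = variable, level = lv,
      t(as.vector(rbind(tab[lv, ], pct[lv, ]))), row.names = NULL))
  names(out)[-(1:2)] <- as.vector(rbind(paste0("n_", colnames(tab)),
                                        paste0("pct_", colnames(tab))))
  out$p <- c(p, rep(NA_real_, nrow(out) - 1L))
  out$test <- c(method, rep(NA_character_, nrow(out) - 1L))
  out
}

endpoint_block <- function(data, ep, mrd_adjust = TRUE) {
  tcol <- paste0(ep, "_time"); scol <- paste0(ep, "_ind")
  groups <- sort(unique(data$merged_group))
  ev <- tapply(data[[scol]], data$merged_group, sum)
  n <- table(data$merged_group)

  km <- km_estimate(data[[tcol]], data[[scol]], data$merged_group)
  at5 <- km_at(km, 5)
  row <- data.frame(endpoint = ep, label = ENDPOINTS[[ep]],
                    n_total = nrow(data), events_total = sum(data[[scol]]))
  for (g in groups) {
    a <- at5[at5$group == g, ]
    row[[paste0("events_", g)]] <- unname(ev[g])
    row[[paste0("surv5_", g)]] <- a$surv * 100
    row[[paste0("surv5_lo_", g)]] <- a$lower * 100
    row[[paste0("surv5_hi_", g)]] <- a$upper * 100
  }
  hr_unadj <- hr_adj <- NULL
  if (length(groups) >= 2L) {
    lr <- logrank(data[[tcol]], data[[scol]], data$merged_group)
    row$logrank_p <- lr$p
    d <- data
    d$pr <- as.integer(d$merged_group == "PR")
    fit_u <- cox_fit(d, tcol, scol, "pr")
    tr <- fit_u$terms[1L, ]
    row$hr <- tr$hr; row$hr_lo <- tr$lower; row$hr_hi <- tr$upper
    row$hr_p <- tr$p
    row$concordance <- harrell_c(fit_u)
    hr_unadj <- fit_u
    if (mrd_adjust && "mrd" %in% names(d)) {
      d$log_mrd <- mrd_log10(d$mrd)
      fit_a <- cox_fit(d, tcol, scol, c("pr", "log_mrd"))
      ta <- fit_a$terms[fit_a$terms$term == "pr", ]
      row$hr_adj <- ta$hr; row$hr_adj_lo <- ta$lower
      row$hr_adj_hi <- ta$upper; row$hr_adj_p <- ta$p
      hr_adj <- fit_a
    }
  }
  list(row = row, km = km, unadjusted = hr_unadj, adjusted = hr_adj)
}

#' Run the full statistical validation on a classified cohort
#'
#' Restricts to patients in the merged good/poor risk groups and reproduces
#' the cohort-table analyses: counts and percentages by group for sex, age
#' band, WCC band and MRD positivity at 0.01 and 0.03 percent with
#' chi-square tests (Fisher fallback for sparse tables); per endpoint the
#' event counts, 5-year Kaplan-Meier estimates with log(-log) intervals,
#' log-rank test, unadjusted and MRD-adjusted PR-vs-GR hazard ratios with
#' concordance; Schoenfeld proportionality diagnostics; a subgroup forest
#' with Cochran's Q; and a definite-vs-provisional comparison.
#'
#' @param data a classified cohort (from [classify_cohort()]) with endpoint
#'   columns `<endpoint>_time` / `<endpoint>_ind` for relapse, event, death.
#' @param endpoints endpoints to analyze.
#' @param forest_vars named list of subgroup columns; defaults to sex, age
#'   band, WCC band, NCI risk, MRD band and (when present) diagnosis-era
#'   band. NCI risk and MRD bands are derived if absent.
#' @return an object of class `heh_validation_report`.
#' @export
run_validation <- function(data,
                           endpoints = c("relapse", "event", "death"),
                           forest_vars = NULL) {
  stopifnot("merged_group" %in% names(data))
  warnings <- character(0)
  d <- data[data$merged_group %in% c("GR", "PR"), , drop = FALSE]
  if (!nrow(d)) stop("no GR/PR patients to validate", call. = FALSE)
  for (ep in endpoints) {
    tc <- paste0(ep, "_time")
    if (!tc %in% names(d)) stop("missing endpoint column: ", tc, call. = FALSE)
    if (any(d[[tc]] < 0)) stop("negative time in ", tc, call. = FALSE)
  }
  one_group <- length(unique(d$merged_group)) < 2L
  if (one_group)
    warnings <- c(warnings,
                  "only one merged risk group present; no hazard ratios computed")

  if (!"nci" %in% names(d) && all(c("age_years", "wcc") %in% names(d)))
    d$nci <- nci_risk(d$age_years, d$wcc)
  if (!"mrd_band" %in% names(d) && "mrd" %in% names(d))
    d$mrd_band <- ifelse(d$mrd >= 1e-4, ">=0.01%", "<0.01%")
  if (!"mrd_heh_band" %in% names(d) && "mrd" %in% names(d))
    d$mrd_heh_band <- ifelse(d$mrd >= 3e-4, ">=0.03%", "<0.03%")

  # ---- Table-1 categorical blocks ----
  table1 <- NULL
  cat_vars <- c(sex = "sex", `age band` = "age_band",
                `WCC band` = "wcc_band", `MRD 0.01%` = "mrd_band",
                `MRD 0.03%` = "mrd_heh_band")
  for (vn in names(cat_vars))
    if (cat_vars[[vn]] %in% names(d))
      table1 <- rbind(table1,
                      categorical_block(d[[cat_vars[[vn]]]], d$merged_group, vn))

  # ---- endpoints ----
  survival_rows <- NULL
  km <- list(); cox <- list(); diagnostics <- list()
  for (ep in endpoints) {
    blk <- endpoint_block(d, ep, mrd_adjust = !one_group)
    survival_rows <- rbind(survival_rows, blk$row)
    km[[ep]] <- blk$km
    cox[[ep]] <- list(unadjusted = blk$unadjusted, adjusted = blk$adjusted)
    if (!is.null(blk$unadjusted))
      diagnostics[[ep]] <- list(
        schoenfeld = schoenfeld_check(blk$unadjusted),
        concordance = harrell_c(blk$unadjusted))
  }

  # ---- subgroup forest ----
  forest <- list()
  if (!one_group) {
    if (is.null(forest_vars)) {
      forest_vars <- list(sex = "sex", age = "age_band", wcc = "wcc_band",
                          nci = "nci", mrd = "mrd_band")
      if ("era" %in% names(d)) forest_vars$era <- "era"
      forest_vars <- forest_vars[unlist(forest_vars) %in% names(d)]
    }
    for (ep in endpoints)
      forest[[ep]] <- tryCatch(
        withCallingHandlers(
          subgroup_forest(d, paste0(ep, "_time"), paste0(ep, "_ind"),
                          vars = forest_vars),
          warning = function(w) {
            warnings <<- c(warnings, conditionMessage(w))
            invokeRestart("muffleWarning")
          }),
        error = function(e) {
          warnings <<- c(warnings, paste0("forest(", ep, "): ",
                                          conditionMessage(e)))
          NULL
        })
  }

  # ---- definite vs provisional ----
  def_prov <- NULL
  if ("group" %in% names(d)) {
    d$assignment <- ifelse(startsWith(d$group, "D-"), "definite", "provisional")
    if (length(unique(d$assignment)) == 2L) {
      for (ep in endpoints) {
        lr <- tryCatch(logrank(d[[paste0(ep, "_time")]],
                               d[[paste0(ep, "_ind")]], d$assignment),
                       error = function(e) NULL)
        def_prov <- rbind(def_prov, data.frame(
          endpoint = ep,
          n_definite = sum(d$assignment == "definite"),
          n_provisional = sum(d$assignment == "provisional"),
          logrank_p = if (is.null(lr)) NA_real_ else lr$p, row.names = NULL))
      }
    }
  }

  structure(list(table1 = table1, survival = survival_rows, km = km,
                 cox = cox, diagnostics = diagnostics, forest = forest,
                 definite_vs_provisional = def_prov,
                 n_analyzed = nrow(d), warnings = warnings),
            class = "heh_validation_report")
}

#' @export
print.heh_validation_report <- function(x, ...) {
  cat("<heh_validation_report> n analyzed:", x$n_analyzed, "\n")
  s <- x$survival
  if (!is.null(s)) for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: %d events", s$label[i], s$events_total[i]))
    if (!is.null(s$surv5_GR))
      cat(sprintf("; 5y GR %.0f%% (%.0f-%.0f) vs PR %.0f%% (%.0f-%.0f)",
                  s$surv5_GR[i], s$surv5_lo_GR[i], s$surv5_hi_GR[i],
                  s$surv5_PR[i], s$surv5_lo_PR[i], s$surv5_hi_PR[i]))
    if (!is.null(s$hr) && !is.na(s$hr[i]))
      cat(sprintf("; HR %.2f (%.2f-%.2f)", s$hr[i], s$hr_lo[i], s$hr_hi[i]))
    cat("\n")
  }
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Write a validation report as CSV/JSON artifacts
#'
#' Produces `table1.csv`, `survival.csv`, `km_<endpoint>.csv`,
#' `forest_<endpoint>.csv`, `heterogeneity.csv`, `definite_vs_provisional.csv`
#' and `diagnostics.json` under `dir`. Numeric fields carry 10 significant
#' digits for regression testing; every file opens with a header giving
#' package version, seed and config hash.
#'
#' @param report a `heh_validation_report`.
#' @param dir output directory (created if needed).
#' @param seed seed recorded in the headers.
#' @param cfg optional config recorded (hashed) in the headers.
#' @return `dir`, invisibly.
#' @export
write_validation_report <- function(report, dir, seed = NA, cfg = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- output_header(seed, cfg)
  sig <- function(df) {
    for (j in seq_along(df))
      if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 10)
    df
  }
  wr <- function(df, name)
    if (!is.null(df)) write_with_header(sig(df), file.path(dir, name), hdr)
  wr(report$table1, "table1.csv")
  wr(report$survival, "survival.csv")
  wr(report$definite_vs_provisional, "definite_vs_provisional.csv")
  het <- NULL
  for (ep in names(report$km))
    wr(as.data.frame(report$km[[ep]]), paste0("km_", ep, ".csv"))
  for (ep in names(report$forest)) {
    f <- report$forest[[ep]]
    if (is.null(f)) next
    wr(f$estimates, paste0("forest_", ep, ".csv"))
    if (!is.null(f$heterogeneity))
      het <- rbind(het, cbind(endpoint = ep, f$heterogeneity))
  }
  wr(het, "heterogeneity.csv")
  diag <- lapply(report$diagnostics, function(dd)
    list(concordance = signif(dd$concordance, 10),
         schoenfeld = sig(dd$schoenfeld)))
  jsonlite::write_json(list(header = hdr, diagnostics = diag),
                       file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
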