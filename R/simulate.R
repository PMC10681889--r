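## Synthetic cohorts: karyotypes with the statistical structure the classifier
## assumes, clinical covariates, and exponential time-to-event endpoints under
## configured proportional hazards.

#' Configuration for a synthetic HeH cohort
#'
#' Defaults emulate the published cohort: a GR:PR ratio near 74:26 among HeH
#' cases, an overall ambiguity rate near 27 percent (markers and incomplete
#' karyotypes), age/sex/white-cell-count margins matching the cohort table,
#' MRD positivity of 30 percent at the 0.01 percent threshold and 19 percent
#' at the HeH-specific 0.03 percent threshold (independent of risk group by
#' default), group hazard ratios of 3.52 / 2.80 / 3.21 for relapse / event /
#' death with good-risk 5-year cumulative risks of 6 / 9 / 5 percent, and
#' censoring by a 10-year administrative horizon with 4 years of uniform
#' entry (median follow-up 8 years).
#'
#' @param n number of patients.
#' @param seed integer seed; all cohort draws are a pure function of
#'   (config, seed).
#' @param group_mix named probabilities over latent labels `GR`, `PR`,
#'   `not_heh`, `ph_positive`, `masked_doubled`; must sum to 1.
#' @param ambiguity_rates named probabilities `mar` (replace one non-profile
#'   gain with `+mar`) and `inc` (truncate with `inc`).
#' @param gain_probs per-chromosome gain probabilities for the non-profile
#'   chromosomes; `21b` is the probability of a second +21.
#' @param profile_gain_probs marginal gain probabilities for chromosomes
#'   5/17/18/20 before conditioning on the target rule class.
#' @param hr named true PR-vs-GR hazard ratios per endpoint.
#' @param baseline_5yr_risk named GR-arm 5-year cumulative risks per endpoint.
#' @param horizon,accrual administrative censoring horizon and uniform entry
#'   window, years.
#' @param weibull_shape event-time shape; 1 (default) gives exponential times
#'   and exact proportional hazards.
#' @param female_prob,age_band_probs,wcc_band_probs covariate margins.
#' @param mrd_pos_prob probability MRD >= 0.01 percent; `mrd_heh_pos_prob`
#'   the probability MRD >= 0.03 percent.
#' @param mrd_group_logodds log-odds shift of MRD positivity in the PR group
#'   (0 = independence, the cohort-table null).
#' @return a list of class `heh_cohort_config`.
#' @export
cohort_config <- function(n = 1169L, seed = 20230929L,
                          group_mix = c(GR = 0.62, PR = 0.22, not_heh = 0.10,
                                        ph_positive = 0.04,
                                        masked_doubled = 0.02),
                          ambiguity_rates = c(mar = 0.18, inc = 0.09),
                          gain_probs = c("X" = 0.80, "4" = 0.70, "6" = 0.80,
                                         "8" = 0.30, "10" = 0.50, "14" = 0.80,
                                         "21" = 0.99, "21b" = 0.70,
                                         "2" = 0.05, "3" = 0.05, "9" = 0.08,
                                         "11" = 0.05, "12" = 0.05,
                                         "16" = 0.05, "22" = 0.10),
                          profile_gain_probs = c("5" = 0.25, "17" = 0.55,
                                                 "18" = 0.75, "20" = 0.20),
                          hr = c(relapse = 3.52, event = 2.80, death = 3.21),
                          baseline_5yr_risk = c(relapse = 0.06, event = 0.09,
                                                death = 0.05),
                          horizon = 10, accrual = 4, weibull_shape = 1,
                          female_prob = 0.47,
                          age_band_probs = c("1-9" = 0.78, "10-14" = 0.09,
                                             "15-24" = 0.09, "25+" = 0.04),
                          wcc_band_probs = c("0-49" = 0.91, "50-99" = 0.06,
                                             "100+" = 0.03),
                          mrd_pos_prob = 0.30, mrd_heh_pos_prob = 0.19,
                          mrd_group_logodds = 0) {
  if (n <= 0L) stop("n must be positive", call. = FALSE)
  if (abs(sum(group_mix) - 1) > 1e-8)
    stop("group_mix must sum to 1", call. = FALSE)
  if (any(ambiguity_rates < 0 | ambiguity_rates > 1))
    stop("ambiguity rates must be in [0, 1]", call. = FALSE)
  if (any(hr <= 0)) stop("hazard ratios must be positive", call. = FALSE)
  structure(as.list(environment()), class = "heh_cohort_config")
}

#' @export
print.heh_cohort_config <- function(x, ...) {
  cat("<heh_cohort_config> n =", x$n, " seed =", x$seed, "\n")
  cat("  group mix:", paste(names(x$group_mix), x$group_mix, sep = "=",
                            collapse = " "), "\n")
  cat("  HR (relapse/event/death):", paste(x$hr, collapse = "/"), "\n")
  invisible(x)
}

## ---- karyotype synthesis --------------------------------------------------

iscn_sort_gains <- function(gains) {
  # sex chromosome gains first, then autosomes ascending (ISCN order)
  sex <- gains[gains %in% c("X", "Y")]
  aut <- gains[!gains %in% c("X", "Y")]
  c(sort(sex, decreasing = TRUE), aut[order(as.integer(aut))])
}

build_karyotype_string <- function(modal, sex_token, gains,
                                   extra_tokens = character(0),
                                   mar = FALSE, inc = FALSE, cells = 20L) {
  toks <- c(sprintf("%d", modal), sex_token, extra_tokens,
            paste0("+", iscn_sort_gains(gains)),
            if (mar) "+mar", if (inc) "inc")
  paste0(paste(toks, collapse = ","), sprintf("[%d]", cells))
}

draw_profile_bits <- function(cfg, target, rule, max_tries = 1000L) {
  p <- cfg$profile_gain_probs[PROFILE_CHROMS]
  for (i in seq_len(max_tries)) {
    bits <- stats::rbinom(4L, 1L, p)
    cls <- rule_lookup(rule, bits[1L], bits[2L], bits[3L], bits[4L])
    if (cls == target) return(stats::setNames(bits, PROFILE_CHROMS))
  }
  stop("unsatisfiable target '", target, "' under profile gain probabilities",
       call. = FALSE)
}

#' Generate one synthetic ISCN karyotype
#'
#' For HeH targets (`GR`, `PR`) the 5/17/18/20 gain pattern is drawn
#' conditioned on the target's rule-table class, non-profile gains are drawn
#' from the configured marginal probabilities until the modal number lands in
#' 51-67, and ambiguity is injected at the configured rates (`+mar` replaces
#' one non-profile gain; `inc` truncates the karyotype). `ph_positive`
#' karyotypes carry t(9;22)(q34;q11); `masked_doubled` karyotypes carry
#' pairwise-even gains (>= 4 tetrasomies); `not_heh` karyotypes sit outside
#' the 51-67 window. Uses the current RNG state.
#'
#' @param cfg a `heh_cohort_config`.
#' @param target latent label, one of the `group_mix` names.
#' @param rule a `heh_risk_rule`.
#' @param sex `"XX"` or `"XY"`.
#' @return a single ISCN karyotype string.
#' @export
generate_karyotype <- function(cfg, target, rule = load_risk_rule(),
                               sex = "XX") {
  if (!target %in% names(cfg$group_mix))
    stop("unknown target label: ", target, call. = FALSE)

  if (target == "not_heh") {
    if (stats::runif(1) < 0.3)
      return(build_karyotype_string(47L, sex, "21"))
    return(sprintf("46,%s[20]", sex))
  }

  if (target == "masked_doubled") {
    k <- sample(4:8, 1L)
    tetra <- sort(sample(c(1L, 5L, 8L, 9L, 10L, 11L, 14L, 18L, 19L, 21L, 22L), k))
    gains <- rep(as.character(tetra), each = 2L)
    return(build_karyotype_string(46L + 2L * k, sex, gains))
  }

  profile_target <- if (target == "ph_positive") "GR" else target
  bits <- draw_profile_bits(cfg, profile_target, rule)

  for (i in seq_len(200L)) {
    gp <- cfg$gain_probs
    draw <- stats::rbinom(length(gp), 1L, gp) == 1L
    others <- names(gp)[draw]
    if ("21b" %in% others)
      others <- if ("21" %in% others) c(others[others != "21b"], "21")
                else others[others != "21b"]
    gains <- c(names(bits)[bits == 1L], others)
    modal <- 46L + length(gains)
    if (modal >= 51L && modal <= 67L) break
    gains <- NULL
  }
  if (is.null(gains))
    stop("could not reach a 51-67 modal number under gain probabilities",
         call. = FALSE)

  if (target == "ph_positive")
    return(build_karyotype_string(modal, sex, gains,
                                  extra_tokens = "t(9;22)(q34;q11)"))

  mar <- stats::runif(1) < cfg$ambiguity_rates[["mar"]]
  inc <- stats::runif(1) < cfg$ambiguity_rates[["inc"]]
  non_profile <- setdiff(gains, PROFILE_CHROMS)
  if (mar && length(non_profile)) {
    drop <- sample(non_profile, 1L)
    gains <- gains[-match(drop, gains)]   # modal unchanged: +mar replaces it
  } else mar <- FALSE
  build_karyotype_string(modal, sex, gains, mar = mar, inc = inc)
}

## ---- survival endpoint simulation -----------------------------------------

#' Simulate one censored time-to-event endpoint
#'
#' Event times follow a Weibull hazard calibrated so the good-risk arm's
#' cumulative risk at 5 years equals `baseline_5yr_risk`; the poor-risk arm's
#' hazard is multiplied by `hr`. With `shape = 1` (default) times are
#' exponential and proportional hazards hold exactly. Censoring is
#' administrative: entry is uniform over the accrual window, so follow-up is
#' uniform on `[horizon - accrual, horizon]`; the indicator is 1 when the
#' event precedes censoring.
#'
#' @param n number of subjects.
#' @param baseline_5yr_risk cumulative event risk at 5 years in the reference
#'   (GR) arm; must be in (0, 1).
#' @param hr hazard ratio applied to these subjects (1 = reference arm).
#' @param horizon,accrual censoring parameters, years.
#' @param shape Weibull shape (1 = exponential).
#' @return a data.frame with columns `time` (years) and `status` (0/1).
#' @export
simulate_endpoint <- function(n, baseline_5yr_risk, hr = 1,
                              horizon = 10, accrual = 4, shape = 1) {
  if (baseline_5yr_risk <= 0 || baseline_5yr_risk >= 1)
    stop("baseline_5yr_risk must lie strictly inside (0, 1)", call. = FALSE)
  if (hr <= 0) stop("hr must be positive", call. = FALSE)
  # cumulative hazard H(t) = lambda * t^shape with H(5) = -log(1 - risk)
  lambda <- -log(1 - baseline_5yr_risk) / 5^shape
  e <- stats::rexp(n)
  t_event <- (e / (lambda * hr))^(1 / shape)
  t_cens <- horizon - stats::runif(n, 0, accrual)
  data.frame(time = pmin(t_event, t_cens),
             status = as.integer(t_event <= t_cens))
}

draw_mrd <- function(n, is_pr, cfg) {
  # three-piece log-uniform mixture hitting both positivity thresholds:
  # P(mrd >= 1e-4) = mrd_pos_prob, P(mrd >= 3e-4) = mrd_heh_pos_prob
  p_pos <- stats::plogis(stats::qlogis(cfg$mrd_pos_prob) +
                           cfg$mrd_group_logodds * is_pr)
  frac_heh <- cfg$mrd_heh_pos_prob / cfg$mrd_pos_prob
  u <- stats::runif(n)
  pos <- u < p_pos
  high <- pos & (stats::runif(n) < frac_heh)
  mrd <- 10^stats::runif(n, -6, -4)                       # negative: < 0.01%
  mrd[pos] <- 10^stats::runif(sum(pos), log10(1e-4), log10(3e-4))
  mrd[high] <- 10^stats::runif(sum(high), log10(3e-4), -1.5)
  mrd
}

#' Generate a synthetic patient cohort
#'
#' Draws latent risk labels from the configured mix, synthesizes one ISCN
#' karyotype per patient, clinical covariates (age, sex, white cell count,
#' end-of-induction MRD) and three censored endpoints (relapse, any event,
#' death) under the configured proportional hazards. Endpoint hazards depend
#' only on the latent merged group (contaminant labels use good-risk
#' hazards; they are excluded downstream anyway). The latent label column
#' `intended_group` is intended for test oracles; [write_cohort()] moves it
#' to a sidecar file so validation cannot read it by accident.
#'
#' @param cfg a `heh_cohort_config`.
#' @param rule the risk rule used to condition karyotype synthesis.
#' @return a data.frame of class `heh_cohort`, one row per patient, fully
#'   reproducible from (cfg, cfg$seed).
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 50, seed = 1))
#' table(cohort$intended_group)
#' @export
generate_cohort <- function(cfg, rule = load_risk_rule()) {
  stopifnot(inherits(cfg, "heh_cohort_config"))
  set.seed(cfg$seed)
  n <- as.integer(cfg$n)

  labels <- sample(names(cfg$group_mix), n, replace = TRUE,
                   prob = cfg$group_mix)
  sex <- ifelse(stats::runif(n) < cfg$female_prob, "Female", "Male")
  sex_tok <- ifelse(sex == "Female", "XX", "XY")
  karyo <- vapply(seq_len(n), function(i)
    generate_karyotype(cfg, labels[i], rule, sex_tok[i]), "")

  age_band <- sample(names(cfg$age_band_probs), n, replace = TRUE,
                     prob = cfg$age_band_probs)
  age_lims <- list("1-9" = c(1, 10), "10-14" = c(10, 15),
                   "15-24" = c(15, 25), "25+" = c(25, 60))
  age <- vapply(age_band, function(b)
    stats::runif(1, age_lims[[b]][1], age_lims[[b]][2]), 0)

  wcc_band <- sample(names(cfg$wcc_band_probs), n, replace = TRUE,
                     prob = cfg$wcc_band_probs)
  wcc_lims <- list("0-49" = c(0.5, 50), "50-99" = c(50, 100),
                   "100+" = c(100, 300))
  wcc <- vapply(wcc_band, function(b)
    stats::runif(1, wcc_lims[[b]][1], wcc_lims[[b]][2]), 0)

  is_pr <- as.integer(labels == "PR")
  mrd <- draw_mrd(n, is_pr, cfg)

  diag_year <- sample(1995:2020, n, replace = TRUE)
  era <- cut(diag_year, c(-Inf, 2004, 2014, Inf),
             labels = c("1995-2004", "2005-2014", "2015+"))

  out <- data.frame(id = seq_len(n), karyotype = karyo,
                    intended_group = labels,
                    age_years = round(age, 1), age_band = age_band,
                    sex = sex, wcc = round(wcc, 1), wcc_band = wcc_band,
                    mrd = signif(mrd, 6), diag_year = diag_year,
                    era = as.character(era), stringsAsFactors = FALSE,
                    row.names = NULL)
  for (ep in c("relapse", "event", "death")) {
    sim <- simulate_endpoint(n, cfg$baseline_5yr_risk[[ep]], hr = 1,
                             horizon = cfg$horizon, accrual = cfg$accrual,
                             shape = cfg$weibull_shape)
    # PR hazards: regenerate those rows under the group hazard ratio
    if (any(is_pr == 1L)) {
      sim_pr <- simulate_endpoint(sum(is_pr), cfg$baseline_5yr_risk[[ep]],
                                  hr = cfg$hr[[ep]], horizon = cfg$horizon,
                                  accrual = cfg$accrual,
                                  shape = cfg$weibull_shape)
      sim[is_pr == 1L, ] <- sim_pr
    }
    out[[paste0(ep, "_time")]] <- round(sim$time, 4)
    out[[paste0(ep, "_ind")]] <- sim$status
  }
  class(out) <- c("heh_cohort", "data.frame")
  attr(out, "config") <- cfg
  out
}

## ---- cohort I/O -----------------------------------------------------------

# cheap FNV-1a hash over the deparsed config, for output headers;
# I/O locations and verbosity do not change the science, so they are
# excluded to keep artifact bytes identical across working directories
config_hash <- function(x) {
  x <- unclass(x)
  if (is.list(x)) x <- x[setdiff(names(x), c("out_dir", "input", "verbose"))]
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

output_header <- function(seed = NA, cfg = NULL) {
  c(sprintf("# hehrisk %s", as.character(utils::packageVersion("hehrisk"))),
    sprintf("# seed: %s", seed),
    sprintf("# config: %s", if (is.null(cfg)) "none" else config_hash(cfg)))
}

write_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a cohort to CSV with the latent labels in a sidecar file
#'
#' The main CSV omits `intended_group`; the generator's latent labels go to
#' `<path>.labels.csv` keyed by `id`, so a validation run cannot silently use
#' them. Both files carry a header with package version, seed and config
#' hash.
#'
#' @param cohort a `heh_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cfg <- attr(cohort, "config")
  hdr <- output_header(seed = if (is.null(cfg)) NA else cfg$seed, cfg = cfg)
  main <- cohort[, setdiff(names(cohort), "intended_group")]
  write_with_header(main, path, hdr)
  labels <- cohort[, c("id", "intended_group")]
  write_with_header(labels, paste0(path, ".labels.csv"), hdr)
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort()]
#' @param path CSV path.
#' @return a data.frame.
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
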