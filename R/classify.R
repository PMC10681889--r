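## HeH eligibility, exclusions, and the four-trisomy risk engine.

#' High-hyperdiploidy eligibility by modal chromosome number
#'
#' A karyotype is HeH-eligible when the classification clone's chromosome
#' count range intersects 51-67. Count ranges that only partially overlap the
#' window (e.g. 50-52) are eligible with a boundary warning.
#'
#' @param pk a `heh_karyotype`.
#' @return a list with `eligible` (logical), `reason` (one of `in_range`,
#'   `below_range`, `above_range`) and `warnings`.
#' @export
is_heh_eligible <- function(pk) {
  cl <- select_classification_clone(pk)
  warnings <- character(0)
  if (cl$count_high >= 51L && cl$count_low <= 67L) {
    if (cl$count_low < 51L || cl$count_high > 67L)
      warnings <- sprintf("count range %d-%d only partially overlaps 51-67",
                          cl$count_low, cl$count_high)
    return(list(eligible = TRUE, reason = "in_range", warnings = warnings))
  }
  reason <- if (cl$count_high < 51L) "below_range" else "above_range"
  list(eligible = FALSE, reason = reason, warnings = warnings)
}

#' Detect a masked near-haploid / low-hypodiploid pattern
#'
#' A doubled hypodiploid genome mimics HeH but shows tetrasomy/disomy (even
#' copy-number) patterns instead of odd-count trisomies. The detector fires
#' when the profile is fully certain, every autosome copy number is even, and
#' at least `min_tetrasomies` autosomes are tetrasomic. It never fires on
#' uncertain evidence: karyotypes with markers, `inc` or `?` tokens are not
#' excluded on this pattern (a warning downstream flags them instead).
#'
#' @param profile a `heh_cn_profile`.
#' @param min_tetrasomies minimum number of 4-copy autosomes (default 4).
#' @return `TRUE` if the masked-doubled pattern is present.
#' @export
detect_masked_doubled <- function(profile, min_tetrasomies = 4L) {
  stopifnot(inherits(profile, "heh_cn_profile"))
  if (any(profile$certainty[AUTOSOMES] != "certain")) return(FALSE)
  counts <- profile$counts[AUTOSOMES]
  all(counts %% 2L == 0L) && sum(counts == 4L) >= min_tetrasomies
}

#' Exclusion rules for the HeH cohort
#'
#' Karyotypes carrying t(9;22)(q34;q11) (Ph-positive ALL) or a chromosome
#' pattern indicative of masked near-haploidy / low hypodiploidy constitute
#' distinct subtypes and are excluded before risk profiling.
#'
#' @param pk a `heh_karyotype`.
#' @param profile the classification clone's `heh_cn_profile`.
#' @param min_tetrasomies passed to [detect_masked_doubled()].
#' @return a list with `excluded` (logical) and `reason` (`ph_positive`,
#'   `masked_doubled` or `none`).
#' @export
exclusion_check <- function(pk, profile, min_tetrasomies = 4L) {
  if (has_structural(pk, "t(9;22)(q34;q11)"))
    return(list(excluded = TRUE, reason = "ph_positive"))
  if (detect_masked_doubled(profile, min_tetrasomies))
    return(list(excluded = TRUE, reason = "masked_doubled"))
  list(excluded = FALSE, reason = "none")
}

#' Trisomy status of a profile chromosome
#'
#' @param profile a `heh_cn_profile`.
#' @param chromosome one of 5, 17, 18, 20.
#' @return `"gained"` (certain copy number >= 3), `"not_gained"` (certain
#'   copy number <= 2) or `"uncertain"`.
#' @export
trisomy_status <- function(profile, chromosome) {
  chromosome <- as.character(chromosome)
  if (!chromosome %in% PROFILE_CHROMS)
    stop("trisomy status is defined for chromosomes 5, 17, 18, 20; got ",
         chromosome, call. = FALSE)
  if (profile$certainty[chromosome] == "uncertain") return("uncertain")
  if (profile$counts[chromosome] >= 3L) "gained" else "not_gained"
}

## ---- definite / provisional assignment ------------------------------------

# enumerate every resolution of the uncertain statuses to gained/not_gained,
# evaluate the rule on each; agreement => definite, disagreement => provisional
# named from the baseline resolution (uncertain -> not_gained)
enumerate_resolutions <- function(statuses) {
  unc <- names(statuses)[statuses == "uncertain"]
  base <- ifelse(statuses == "gained", 1L, 0L)
  if (!length(unc)) return(matrix(base, nrow = 1L,
                                  dimnames = list(NULL, names(statuses))))
  grid <- as.matrix(expand.grid(rep(list(0:1), length(unc))))
  colnames(grid) <- unc
  out <- matrix(rep(base, each = nrow(grid)), nrow = nrow(grid),
                dimnames = list(NULL, names(statuses)))
  out[, unc] <- grid
  out
}

#' Assign a risk group from four trisomy statuses
#'
#' Every resolution of the uncertain statuses to gained/not-gained (at most
#' 2^4 = 16) is evaluated against the decision table. If all resolutions
#' agree the assignment is definite (`D-GR` / `D-PR`); if they disagree it is
#' provisional (`P-GR` / `P-PR`), named from the baseline resolution in which
#' every uncertain chromosome is taken as not gained — a karyotype shows what
#' was seen.
#'
#' @param statuses named character vector with entries `"5"`, `"17"`, `"18"`,
#'   `"20"`, each `"gained"`, `"not_gained"` or `"uncertain"`.
#' @param rule a `heh_risk_rule`.
#' @return a list with `group` (`D-GR`, `P-GR`, `D-PR`, `P-PR`),
#'   `merged_group` (`GR`/`PR`), `definite` (logical) and `resolutions`
#'   (groups over the enumeration, for audit).
#' @export
assign_risk <- function(statuses, rule) {
  validate_risk_rule(rule)
  statuses <- statuses[PROFILE_CHROMS]
  if (anyNA(statuses) ||
      !all(statuses %in% c("gained", "not_gained", "uncertain")))
    stop("statuses must cover chromosomes 5, 17, 18, 20", call. = FALSE)

  res <- enumerate_resolutions(statuses)
  groups <- apply(res, 1L, function(r)
    rule_lookup(rule, r["5"], r["17"], r["18"], r["20"]))
  baseline <- groups[1L]   # first row of the enumeration is the baseline
  definite <- length(unique(groups)) == 1L
  group <- paste0(if (definite) "D-" else "P-", baseline)
  list(group = group, merged_group = baseline, definite = definite,
       resolutions = groups)
}

## ---- end-to-end classification --------------------------------------------

#' Classify one karyotype string into a UKALL-HeH risk group
#'
#' Runs the full decision path: parse, clone selection, copy-number profile,
#' HeH eligibility (modal 51-67), exclusions (Ph-positive, masked
#' hypodiploidy), trisomy statuses of 5/17/18/20, and table-driven
#' definite/provisional assignment. Non-eligible and excluded karyotypes
#' short-circuit with `merged_group = "none"`. Every decision is appended to
#' a machine-readable reason trail.
#'
#' @param text an ISCN karyotype string.
#' @param rule a `heh_risk_rule`; default [load_risk_rule()].
#' @param min_tetrasomies passed to [detect_masked_doubled()].
#' @return an object of class `heh_risk_assignment` with `group` (one of
#'   `D-GR`, `P-GR`, `D-PR`, `P-PR`, `not_heh`, `excluded`), `merged_group`
#'   (`GR`, `PR`, `none`), `reasons`, `statuses` and `warnings`.
#' @examples
#' classify_karyotype("57,XX,+X,+4,+6,+10,+14,+17,+18,+21,+21[12]/46,XX[8]")
#' @export
classify_karyotype <- function(text, rule = load_risk_rule(),
                               min_tetrasomies = 4L) {
  pk <- if (inherits(text, "heh_karyotype")) text else parse_karyotype(text)
  reasons <- character(0)
  warnings <- pk$parse_warnings
  if (pk$is_composite)
    warnings <- c(warnings, "composite (cp) karyotype; classified with caution")

  result <- function(group, merged, statuses = NULL) {
    structure(list(karyotype = pk$raw, group = group, merged_group = merged,
                   definite = group %in% c("D-GR", "D-PR"),
                   statuses = statuses, reasons = reasons,
                   warnings = warnings, rule_version = rule$version),
              class = "heh_risk_assignment")
  }

  elig <- is_heh_eligible(pk)
  warnings <- c(warnings, elig$warnings)
  reasons <- c(reasons, paste0("eligibility:", elig$reason))
  if (!elig$eligible) return(result("not_heh", "none"))

  clone <- select_classification_clone(pk)
  profile <- copy_number_profile(clone)
  warnings <- c(warnings, profile$warnings)

  excl <- exclusion_check(pk, profile, min_tetrasomies)
  reasons <- c(reasons, paste0("exclusion:", excl$reason))
  if (excl$excluded) return(result("excluded", "none"))

  statuses <- vapply(PROFILE_CHROMS, trisomy_status, "", profile = profile)
  reasons <- c(reasons,
               paste0("status:", PROFILE_CHROMS, "=", statuses))
  asg <- assign_risk(statuses, rule)
  reasons <- c(reasons, paste0("assignment:",
                               if (asg$definite) "definite" else "provisional"))
  result(asg$group, asg$merged_group, statuses)
}

#' @export
print.heh_risk_assignment <- function(x, ...) {
  cat("<heh_risk_assignment>", x$karyotype, "\n")
  cat(sprintf("  group: %s (merged: %s)\n", x$group, x$merged_group))
  if (!is.null(x$statuses))
    cat("  trisomy status:",
        paste(names(x$statuses), x$statuses, sep = "=", collapse = " "), "\n")
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Classify every karyotype in a cohort table
#'
#' @param data a data.frame with one karyotype string per row.
#' @param karyotype_col name of the karyotype column.
#' @param rule a `heh_risk_rule`.
#' @return `data` with columns `heh_eligible`, `excluded`, `reason`, `group`
#'   and `merged_group` appended. Unparseable karyotypes get
#'   `group = "parse_error"` rather than aborting the run.
#' @export
classify_cohort <- function(data, karyotype_col = "karyotype",
                            rule = load_risk_rule()) {
  stopifnot(is.data.frame(data))
  if (!karyotype_col %in% names(data))
    stop("column not found: ", karyotype_col, call. = FALSE)
  res <- lapply(data[[karyotype_col]], function(k) {
    tryCatch(classify_karyotype(k, rule = rule),
             error = function(e)
               list(group = "parse_error", merged_group = "none",
                    reasons = conditionMessage(e)))
  })
  data$group <- vapply(res, `[[`, "", "group")
  data$merged_group <- vapply(res, `[[`, "", "merged_group")
  data$heh_eligible <- !data$group %in% c("not_heh", "parse_error")
  data$excluded <- data$group == "excluded"
  data$reason <- vapply(res, function(r) paste(r$reasons, collapse = ";"), "")
  data
}
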