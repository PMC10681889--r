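PROFILE_CHROMS <- c("5", "17", "18", "20")

#' Load a four-trisomy risk decision table
#'
#' The decision table maps every combination of trisomy status for
#' chromosomes 5, 17, 18 and 20 to a good-risk (`GR`) or poor-risk (`PR`)
#' call. It is shipped as versioned JSON data rather than code, so a
#' transcription correction never touches the engine: the file holds a
#' `version` string and a `table` object with 16 keys `"g5,g17,g18,g20"`
#' (each 0/1) mapping to `"GR"` or `"PR"`.
#'
#' @param path path to a rule JSON file; the default loads the bundled
#'   `ukall_heh_v1` table (good risk = +17 and/or +18 with neither +5 nor
#'   +20).
#' @return an object of class `heh_risk_rule`.
#' @examples
#' rule <- load_risk_rule()
#' rule$table[["0,1,1,0"]]  # +17 and +18, no +5/+20
#' @export
load_risk_rule <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rules", "ukall_heh_v1.json",
                        package = "hehrisk", mustWork = TRUE)
  if (!file.exists(path))
    stop("risk rule file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  rule <- structure(list(version = raw$version,
                         description = raw$description,
                         table = as.list(raw$table)),
                    class = "heh_risk_rule")
  validate_risk_rule(rule)
  rule
}

validate_risk_rule <- function(rule) {
  combos <- expand.grid(g5 = 0:1, g17 = 0:1, g18 = 0:1, g20 = 0:1)
  keys <- apply(combos, 1L, paste, collapse = ",")
  missing <- setdiff(keys, names(rule$table))
  if (length(missing))
    stop("risk rule table incomplete; missing combinations: ",
         paste(missing, collapse = " "), call. = FALSE)
  vals <- unlist(rule$table[keys])
  if (!all(vals %in% c("GR", "PR")))
    stop("risk rule table values must be 'GR' or 'PR'", call. = FALSE)
  invisible(rule)
}

#' @export
print.heh_risk_rule <- function(x, ...) {
  cat("<heh_risk_rule>", x$version, "\n")
  n_gr <- sum(unlist(x$table) == "GR")
  cat(sprintf("  16-entry table: %d GR, %d PR combinations\n", n_gr, 16L - n_gr))
  invisible(x)
}

rule_lookup <- function(rule, g5, g17, g18, g20) {
  rule$table[[paste(as.integer(c(g5, g17, g18, g20)), collapse = ",")]]
}
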