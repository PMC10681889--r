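CHROMOSOMES <- c(as.character(1:22), "X", "Y")
AUTOSOMES <- as.character(1:22)

## ---- token classification -------------------------------------------------

# one abnormality token -> record with kind in {gain, loss, structural,
# marker, other} plus target chromosome and uncertainty flag
parse_token <- function(tok) {
  rec <- list(raw = tok, kind = "other", chrom = NA_character_,
              uncertain = FALSE, mult = 1L, constitutional = FALSE,
              type = NA_character_, chroms = character(0),
              breakpoints = character(0), gained = FALSE, lost = FALSE,
              warning = NULL)

  # gained marker chromosome(s): +mar, +2mar, +mar1, +?mar
  m <- regmatches(tok, regexec("^\\+(\\?)?([0-9]+)?mar[0-9]*$", tok))[[1]]
  if (length(m)) {
    rec$kind <- "marker"
    rec$mult <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    rec$uncertain <- TRUE   # identity unknown by definition
    return(rec)
  }

  # whole-chromosome gain / loss, optional "?" uncertainty, optional
  # constitutional "c" suffix
  m <- regmatches(tok, regexec("^([+-])(\\?)?([0-9]{1,2}|X|Y)(c)?$", tok))[[1]]
  if (length(m)) {
    rec$kind <- if (m[2] == "+") "gain" else "loss"
    rec$uncertain <- nzchar(m[3])
    rec$chrom <- m[4]
    rec$constitutional <- nzchar(m[5])
    if (!m[4] %in% CHROMOSOMES) {
      rec$kind <- "other"
      rec$chrom <- NA_character_
      rec$warning <- sprintf("token '%s' names no valid chromosome", tok)
    }
    if (rec$constitutional)
      rec$warning <- sprintf("constitutional abnormality '%s' retained", tok)
    return(rec)
  }

  # structural rearrangements: t, del, der, dup, i, inv, add, ins, dic, r
  m <- regmatches(
    tok,
    regexec("^([+-])?(\\?)?(t|del|der|dup|inv|ins|i|add|dic|r)\\(([^)]*)\\)(\\(([^)]*)\\))?",
            tok))[[1]]
  if (length(m)) {
    rec$kind <- "structural"
    rec$gained <- identical(m[2], "+")
    rec$lost <- identical(m[2], "-")
    rec$uncertain <- nzchar(m[3])
    rec$type <- m[4]
    rec$chroms <- strsplit(m[5], ";", fixed = TRUE)[[1]]
    rec$breakpoints <- if (nzchar(m[6])) strsplit(m[7], ";", fixed = TRUE)[[1]]
                       else character(0)
    return(rec)
  }

  rec$warning <- sprintf("unrecognized token '%s' kept as-is", tok)
  rec
}

## ---- clone parsing --------------------------------------------------------

parse_clone <- function(clone_text, index) {
  cl <- list(count_low = NA_integer_, count_high = NA_integer_,
             sex_token = NA_character_, abnormalities = list(),
             cell_count = NA_integer_, lineage_ref = NA_character_,
             incomplete = FALSE, composite = FALSE, warnings = character(0))

  # trailing cell count, possibly composite: [12] or [cp12]
  m <- regmatches(clone_text, regexec("\\[(cp)?([0-9]+)\\]$", clone_text))[[1]]
  if (length(m)) {
    cl$composite <- nzchar(m[2])
    cl$cell_count <- as.integer(m[3])
    clone_text <- sub("\\[(cp)?[0-9]+\\]$", "", clone_text)
  }

  toks <- strsplit(clone_text, ",", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks))
    stop(sprintf("clone %d is empty", index), call. = FALSE)

  # leading chromosome count: "57" or a range "51-56" / "51~56"
  m <- regmatches(toks[1], regexec("^([0-9]+)([-~]([0-9]+))?$", toks[1]))[[1]]
  if (!length(m))
    stop(sprintf("clone %d: malformed chromosome count token '%s'",
                 index, toks[1]), call. = FALSE)
  cl$count_low <- as.integer(m[2])
  cl$count_high <- if (nzchar(m[4])) as.integer(m[4]) else cl$count_low
  if (cl$count_high < cl$count_low)
    stop(sprintf("clone %d: inverted count range '%s'", index, toks[1]),
         call. = FALSE)
  toks <- toks[-1]

  # sex chromosome complement or a stemline reference
  if (length(toks)) {
    if (grepl("^(idem|sl[0-9]*|sdl[0-9]*)$", toks[1])) {
      cl$lineage_ref <- toks[1]
      toks <- toks[-1]
    } else if (grepl("^\\??[XY?]{1,4}$", toks[1])) {
      cl$sex_token <- toks[1]
      toks <- toks[-1]
    } else {
      cl$warnings <- c(cl$warnings,
                       sprintf("clone %d: no sex token found", index))
    }
  }

  for (tok in toks) {
    if (tok == "inc") { cl$incomplete <- TRUE; next }
    if (grepl("^(idem|sl[0-9]*|sdl[0-9]*)$", tok)) {
      cl$lineage_ref <- tok
      next
    }
    rec <- parse_token(tok)
    if (!is.null(rec$warning))
      cl$warnings <- c(cl$warnings, sprintf("clone %d: %s", index, rec$warning))
    cl$abnormalities <- c(cl$abnormalities, list(rec))
  }
  cl
}

## ---- public parser --------------------------------------------------------

#' Parse an ISCN karyotype string
#'
#' Splits a karyotype into clones (on `/`), parses each clone's leading
#' chromosome count (single value or a `51-56` range), sex token and
#' abnormality tokens, and flags marker chromosomes (`+mar`), incomplete
#' karyotypes (`inc`), composite clones (`cp`) and stemline references
#' (`idem`/`sl`/`sdl`). Tokens prefixed with `?` are flagged uncertain.
#' Unrecognized tokens are preserved with a parse warning; the parser only
#' fails hard on an empty string or a malformed leading count.
#'
#' @param text a single ISCN karyotype string; internal whitespace is ignored.
#' @return an object of class `heh_karyotype` with elements `clones`,
#'   `is_incomplete`, `marker_count` (markers in the clone selected for
#'   classification), `is_composite` and `parse_warnings`.
#' @examples
#' pk <- parse_karyotype("57,XX,+X,+4,+6,+10,+14,+17,+18,+21,+21,+mar[12]/46,XX[8]")
#' pk$marker_count
#' @export
parse_karyotype <- function(text) {
  if (length(text) != 1L || is.na(text))
    stop("expected a single karyotype string", call. = FALSE)
  raw <- text
  text <- gsub("[[:space:]]+", "", text)
  if (!nzchar(text))
    stop("empty karyotype string", call. = FALSE)

  clone_texts <- strsplit(text, "/", fixed = TRUE)[[1]]
  clone_texts <- clone_texts[nzchar(clone_texts)]
  if (!length(clone_texts))
    stop("empty karyotype string", call. = FALSE)

  clones <- lapply(seq_along(clone_texts),
                   function(i) parse_clone(clone_texts[i], i))

  pk <- structure(
    list(raw = raw,
         clones = clones,
         is_incomplete = any(vapply(clones, `[[`, TRUE, "incomplete")),
         is_composite = any(vapply(clones, `[[`, TRUE, "composite")),
         marker_count = 0L,
         parse_warnings = unlist(lapply(clones, `[[`, "warnings"),
                                 use.names = FALSE)),
    class = "heh_karyotype")
  cc <- select_classification_clone(pk)
  pk$marker_count <- clone_marker_count(cc)
  pk
}

#' @export
print.heh_karyotype <- function(x, ...) {
  cat("<heh_karyotype> ", x$raw, "\n", sep = "")
  cat(sprintf("  %d clone(s); incomplete: %s; markers in classified clone: %d\n",
              length(x$clones), x$is_incomplete, x$marker_count))
  if (length(x$parse_warnings))
    cat("  warnings:", paste(x$parse_warnings, collapse = "; "), "\n")
  invisible(x)
}

clone_marker_count <- function(clone) {
  sum(vapply(clone$abnormalities,
             function(a) if (a$kind == "marker") a$mult else 0L, 0L))
}

## ---- lineage resolution & clone selection ---------------------------------

# expand an idem/sl/sdl clone against the stemline (first clone): the
# stemline's abnormalities are unioned with the subclone's own changes
resolve_clone <- function(clone, stemline) {
  if (is.na(clone$lineage_ref)) return(clone)
  clone$abnormalities <- c(stemline$abnormalities, clone$abnormalities)
  if (is.na(clone$sex_token)) clone$sex_token <- stemline$sex_token
  clone$incomplete <- clone$incomplete || stemline$incomplete
  clone
}

#' Select the clone used for risk classification
#'
#' Returns the first clone in document order whose chromosome-count range
#' intersects the high-hyperdiploid window 51-67, after stemline (`idem`)
#' resolution; if no clone intersects, the clone with the highest count is
#' returned. ISCN convention lists the stemline first, so this picks the
#' stemline when several related hyperdiploid clones are present.
#'
#' @param pk a `heh_karyotype` from [parse_karyotype()].
#' @return the selected clone (a list), lineage-resolved.
#' @export
select_classification_clone <- function(pk) {
  stopifnot(inherits(pk, "heh_karyotype"))
  clones <- lapply(pk$clones, resolve_clone, stemline = pk$clones[[1]])
  for (cl in clones)
    if (cl$count_high >= 51L && cl$count_low <= 67L) return(cl)
  highs <- vapply(clones, `[[`, 0L, "count_high")
  clones[[which.max(highs)]]
}

## ---- copy-number profile --------------------------------------------------

sex_baseline <- function(sex_token) {
  warn <- character(0)
  tok <- if (is.na(sex_token)) "" else gsub("\\?", "", sex_token)
  nx <- lengths(regmatches(tok, gregexpr("X", tok)))
  ny <- lengths(regmatches(tok, gregexpr("Y", tok)))
  if (nx + ny == 0L) {
    nx <- 2L; ny <- 0L
    warn <- "unknown sex token; assuming XX baseline"
  }
  list(X = nx, Y = ny, warnings = warn)
}

#' Per-chromosome copy numbers for one clone
#'
#' Starts from a 46,XX / 46,XY baseline according to the clone's sex token and
#' applies each whole-chromosome gain (+1) and loss (-1). Marker gains add to
#' the modal count but to no named chromosome; structural tokens (der, del,
#' dup, i, ...) change no whole-chromosome copy number. Certainty labels: with
#' no markers, no `inc` and no `?`-flagged tokens, every chromosome is
#' `certain`; otherwise only chromosomes carrying a named, certain gain stay
#' `certain` — a marker or unrecorded abnormality could hide a gain anywhere
#' else.
#'
#' @param clone a clone, typically from [select_classification_clone()].
#' @return an object of class `heh_cn_profile`: `counts` and `certainty`
#'   named over 1-22, X, Y, plus `modal_low`, `modal_high`, `marker_count`,
#'   `has_uncertain_tokens`, `incomplete` and `warnings`.
#' @export
copy_number_profile <- function(clone) {
  counts <- stats::setNames(rep(2L, 24L), CHROMOSOMES)
  sb <- sex_baseline(clone$sex_token)
  counts["X"] <- sb$X
  counts["Y"] <- sb$Y
  warnings <- sb$warnings

  gained <- character(0)
  n_uncertain <- 0L
  for (a in clone$abnormalities) {
    if (a$kind == "gain") {
      if (a$uncertain) { n_uncertain <- n_uncertain + 1L; next }
      counts[a$chrom] <- counts[a$chrom] + 1L
      gained <- c(gained, a$chrom)
    } else if (a$kind == "loss") {
      if (a$uncertain) { n_uncertain <- n_uncertain + 1L; next }
      counts[a$chrom] <- counts[a$chrom] - 1L
      if (counts[a$chrom] < 0L)
        stop(sprintf("inconsistent karyotype: copy number of chromosome %s below 0",
                     a$chrom), call. = FALSE)
    } else if (a$uncertain && a$kind != "marker") {
      n_uncertain <- n_uncertain + 1L
    }
  }
  marker_count <- clone_marker_count(clone)

  ambiguous <- marker_count > 0L || clone$incomplete || n_uncertain > 0L
  certainty <- stats::setNames(rep("certain", 24L), CHROMOSOMES)
  if (ambiguous)
    certainty[setdiff(CHROMOSOMES, unique(gained))] <- "uncertain"

  structure(
    list(counts = counts, certainty = certainty,
         modal_low = clone$count_low, modal_high = clone$count_high,
         marker_count = marker_count,
         has_uncertain_tokens = n_uncertain > 0L,
         incomplete = clone$incomplete,
         warnings = warnings),
    class = "heh_cn_profile")
}

#' @export
print.heh_cn_profile <- function(x, ...) {
  gains <- names(x$counts)[x$counts > ifelse(names(x$counts) %in% c("X", "Y"), 1L, 2L)]
  cat(sprintf("<heh_cn_profile> modal %d-%d; gains: %s; markers: %d\n",
              x$modal_low, x$modal_high,
              if (length(gains)) paste(gains, collapse = ",") else "none",
              x$marker_count))
  unc <- names(x$certainty)[x$certainty == "uncertain"]
  if (length(unc)) cat("  uncertain:", paste(unc, collapse = ","), "\n")
  invisible(x)
}

## ---- structural matching --------------------------------------------------

# breakpoint comparison tolerating sub-band refinement (q11 ~ q11.2) and "?"
breakpoint_matches <- function(tok_bp, spec_bp) {
  a <- gsub("\\?", "", tok_bp)
  b <- gsub("\\?", "", spec_bp)
  !nzchar(a) || !nzchar(b) || startsWith(a, b) || startsWith(b, a)
}

structural_token_matches <- function(tok, type, chroms, breakpoints) {
  if (tok$kind != "structural" || tok$type != type) return(FALSE)
  if (length(tok$chroms) != length(chroms)) return(FALSE)
  perms <- list(seq_along(chroms))
  if (length(chroms) == 2L) perms <- list(1:2, 2:1)
  for (p in perms) {
    if (!all(tok$chroms == chroms[p])) next
    if (!length(breakpoints) || !length(tok$breakpoints)) return(TRUE)
    if (length(tok$breakpoints) == length(breakpoints) &&
        all(mapply(breakpoint_matches, tok$breakpoints, breakpoints[p])))
      return(TRUE)
  }
  FALSE
}

#' Test for a structural abnormality anywhere in a karyotype
#'
#' @param pk a `heh_karyotype`.
#' @param pattern a structural abnormality written in ISCN, e.g.
#'   `"t(9;22)(q34;q11)"`. Breakpoints may be omitted; matching tolerates
#'   sub-band refinements (`q11.2` matches `q11`) and `?` within breakpoints,
#'   and is order-insensitive in the chromosome pair.
#' @return `TRUE` if any clone carries a matching structural token.
#' @examples
#' has_structural(parse_karyotype("54,XY,t(9;22)(q34;q11.2),+6,+10,+14,+17,+18,+21,+21[9]"),
#'                "t(9;22)(q34;q11)")
#' @export
has_structural <- function(pk, pattern) {
  stopifnot(inherits(pk, "heh_karyotype"))
  spec <- parse_token(gsub("[[:space:]]", "", pattern))
  if (spec$kind != "structural")
    stop("pattern is not a structural abnormality: ", pattern, call. = FALSE)
  for (cl in pk$clones)
    for (a in cl$abnormalities)
      if (structural_token_matches(a, spec$type, spec$chroms, spec$breakpoints))
        return(TRUE)
  FALSE
}
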