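# ISCN parser: token grammar, clone selection, copy-number arithmetic,
# structural matching, and parser totality under fuzzing.

test_that("parser decomposes clones, counts, gains, markers and cell counts", {
  pk <- parse_karyotype("57,XX,+X,+4,+6,+10,+14,+17,+18,+21,+21,+mar[12]/46,XX[8]")
  expect_length(pk$clones, 2L)
  c1 <- pk$clones[[1]]
  expect_equal(c1$count_low, 57L)
  expect_equal(c1$cell_count, 12L)
  gains <- vapply(Filter(function(a) a$kind == "gain", c1$abnormalities),
                  `[[`, "", "chrom")
  expect_equal(sort(gains), sort(c("X", "4", "6", "10", "14", "17", "18", "21", "21")))
  expect_equal(pk$marker_count, 1L)
  expect_equal(pk$clones[[2]]$count_low, 46L)
  expect_false(pk$is_incomplete)

  pk2 <- parse_karyotype("46,XY[20]")
  expect_length(pk2$clones, 1L)
  expect_length(pk2$clones[[1]]$abnormalities, 0L)
  expect_equal(pk2$marker_count, 0L)

  pk3 <- parse_karyotype("52,XY,+5,+8,+10,+17,inc[10]")
  expect_true(pk3$is_incomplete)
  expect_length(pk3$parse_warnings, 0L)
})

test_that("count ranges, whitespace, composite and uncertain tokens parse", {
  pk <- parse_karyotype(" 51-56 , XY ,+X,+6,+10,+17,+18,+21 [cp12]")
  expect_equal(pk$clones[[1]]$count_low, 51L)
  expect_equal(pk$clones[[1]]$count_high, 56L)
  expect_true(pk$is_composite)

  pk2 <- parse_karyotype("55,XY,+?4,+6,+17[10]")
  uncert <- vapply(pk2$clones[[1]]$abnormalities, `[[`, TRUE, "uncertain")
  expect_true(any(uncert))
})

test_that("declared parse errors fire; unknown tokens only warn", {
  expect_error(parse_karyotype(""), "empty")
  expect_error(parse_karyotype("   "), "empty")
  expect_error(parse_karyotype("XX,+4"), "count")
  expect_error(parse_karyotype("abc"), "count")
  pk <- parse_karyotype("57,XX,+4,+6,+10,+14,+17,+18,+21,wibble[10]")
  expect_true(any(grepl("wibble", pk$parse_warnings)))
})

test_that("classification clone: first in 51-67, stemline before idem, fallback", {
  pk <- parse_karyotype("46,XY[5]/55,XY,+4,+6,+10,+14,+17,+18,+21,+21,+21[15]")
  expect_equal(select_classification_clone(pk)$count_low, 55L)

  pk2 <- parse_karyotype("55,XY,+4,+6,+10,+14,+17,+18,+21,+21,+21[10]/56,idem,+5[4]")
  expect_equal(select_classification_clone(pk2)$count_low, 55L)

  pk3 <- parse_karyotype("46,XY[20]")
  expect_equal(select_classification_clone(pk3)$count_low, 46L)
})

test_that("idem subclones inherit the stemline's abnormalities and sex token", {
  pk <- parse_karyotype("46,XY[10]/56,idem,+5[4]")
  # no clone in window except idem resolved against normal stemline
  cl <- select_classification_clone(pk)
  expect_equal(cl$count_low, 56L)
  expect_equal(cl$sex_token, "XY")
  p <- copy_number_profile(cl)
  expect_equal(unname(p$counts[["5"]]), 3L)
})

test_that("copy-number arithmetic from the sexed baseline", {
  cl <- select_classification_clone(
    parse_karyotype("55,XX,+X,+4,+6,+10,+14,+17,+18,+21,+21[12]"))
  p <- copy_number_profile(cl)
  expect_equal(unname(p$counts[["X"]]), 3L)
  expect_equal(unname(p$counts[["21"]]), 4L)
  expect_equal(unname(p$counts[["5"]]), 2L)
  expect_equal(unname(p$counts[["Y"]]), 0L)
  expect_true(all(p$certainty == "certain"))
  # fully certain, arithmetically consistent profile sums to the written modal
  expect_equal(sum(p$counts), 55L)

  cl2 <- select_classification_clone(parse_karyotype("51,XX,-7,+4,+6,+10,+14,+18,+21[9]"))
  p2 <- copy_number_profile(cl2)
  expect_equal(unname(p2$counts[["7"]]), 1L)
  expect_equal(sum(p2$counts), 51L)

  expect_error(copy_number_profile(select_classification_clone(
    parse_karyotype("44,XY,-7,-7,-7[4]"))), "below 0")
})

test_that("certainty: markers and inc spare only explicitly gained chromosomes", {
  p <- copy_number_profile(select_classification_clone(
    parse_karyotype("57,XX,+X,+4,+6,+10,+14,+17,+18,+21,+21,+mar[12]")))
  expect_equal(unname(p$certainty[["17"]]), "certain")
  expect_equal(unname(p$certainty[["18"]]), "certain")
  expect_equal(unname(p$certainty[["5"]]), "uncertain")
  expect_equal(unname(p$certainty[["20"]]), "uncertain")
  expect_equal(unname(p$counts[["5"]]), 2L)

  p2 <- copy_number_profile(select_classification_clone(
    parse_karyotype("52,XY,+5,+8,+10,+17,inc[10]")))
  expect_equal(unname(p2$certainty[["5"]]), "certain")
  expect_equal(unname(p2$certainty[["17"]]), "certain")
  expect_equal(unname(p2$certainty[["18"]]), "uncertain")
})

test_that("unknown sex token falls back to XX with a warning", {
  p <- copy_number_profile(select_classification_clone(
    parse_karyotype("51,??,+4,+6,+10,+14,+18[9]")))
  expect_equal(unname(p$counts[["X"]]), 2L)
  expect_true(any(grepl("sex", p$warnings)))
})

test_that("structural matching: exact, sub-band, '?', order and absence", {
  ph <- "t(9;22)(q34;q11)"
  expect_true(has_structural(
    parse_karyotype("54,XY,t(9;22)(q34;q11),+4,+6,+10,+14,+17,+18,+21,+21[9]"), ph))
  expect_true(has_structural(
    parse_karyotype("54,XY,t(9;22)(q34;q11.2),+4,+6,+10,+14,+17,+18,+21,+21[9]"), ph))
  expect_true(has_structural(
    parse_karyotype("54,XY,t(9;22)(q34;q?11),+6,+10,+14,+17,+18,+21,+21,+X[9]"), ph))
  expect_true(has_structural(
    parse_karyotype("54,XY,t(22;9)(q11;q34),+6,+10,+14,+17,+18,+21,+21,+X[9]"), ph))
  expect_false(has_structural(
    parse_karyotype("57,XX,+X,+4,+6,+10,+14,+17,+18,+21,+21[12]"), ph))
  expect_false(has_structural(
    parse_karyotype("54,XY,t(4;11)(q21;q23),+6,+10,+14,+17,+18,+21,+21,+X[9]"), ph))
})

test_that("monotonicity: appending +N raises chromosome N and the modal sum by 1", {
  base <- "52,XY,+4,+6,+10,+14,+18,+21"
  for (ch in c("5", "17", "20", "X", "2")) {
    p0 <- copy_number_profile(select_classification_clone(
      parse_karyotype(paste0(base, "[10]"))))
    p1 <- copy_number_profile(select_classification_clone(
      parse_karyotype(paste0(base, ",+", ch, "[10]"))))
    expect_equal(unname(p1$counts[[ch]] - p0$counts[[ch]]), 1L)
    expect_equal(sum(p1$counts) - sum(p0$counts), 1L)
  }
})

test_that("round-trip: generator karyotypes without ambiguity sum to the written modal", {
  cfg <- cohort_config(n = 1, seed = 1, ambiguity_rates = c(mar = 0, inc = 0))
  set.seed(42)
  for (i in 1:50) {
    target <- sample(c("GR", "PR"), 1)
    k <- generate_karyotype(cfg, target, default_rule,
                            sex = sample(c("XX", "XY"), 1))
    pk <- parse_karyotype(k)
    cl <- select_classification_clone(pk)
    p <- copy_number_profile(cl)
    expect_equal(sum(p$counts), cl$count_low, info = k)
  }
})

test_that("parser totality: fuzzed strings parse with warnings or raise declared errors", {
  cfg <- cohort_config(n = 1, seed = 1)
  set.seed(99)
  n_err <- 0L
  for (i in 1:300) {
    k <- generate_karyotype(cfg, sample(c("GR", "PR", "not_heh"), 1), default_rule)
    for (j in 1:3) k <- mutate_karyotype(k)
    out <- tryCatch(parse_karyotype(k), error = function(e) e)
    if (inherits(out, "error")) {
      n_err <- n_err + 1L
      expect_match(conditionMessage(out), "count|empty", info = k)
    } else {
      expect_s3_class(out, "heh_karyotype")
    }
  }
  expect_gt(n_err, 0L)  # the fuzzer does reach the error branches
})
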