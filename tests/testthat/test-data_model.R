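test_that("schema has 53 uniquely ordered items on the 1-4 scale", {
  s <- questionnaire_schema()
  expect_length(s$items, 53L)
  expect_false(anyDuplicated(s$items) > 0)
  expect_identical(s$items, sort(s$items))
  expect_identical(s$scale, 1:4)
})

test_that("loading a well-formed file round-trips value-for-value", {
  rec <- generate_cohort(
    list(group_profile(group = "RD", diagnosis = "PAH"),
         group_profile(group = "NRO", diagnosis = "none",
                       missing_rate = 0.1)),
    c(5L, 5L), seed = 11L)
  attr(rec, "truth") <- NULL
  f <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, f)
  back <- load_records(f)
  expect_identical(back, rec)
  # and re-saving reproduces the file byte-for-byte
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_records(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("out-of-range and malformed rows raise naming the item and record", {
  rec <- make_records(3L)
  rec$q10[2L] <- 5L
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rec, f, row.names = FALSE, na = "")
  expect_error(load_records(f), "q10.*r2")
  rec <- make_records(2L)
  rec$group[1L] <- "OTHER"
  expect_error(validate_records(rec), "group")
  expect_error(validate_records(make_records(2L)[, -5L]), "missing required")
  bad_age <- make_records(1L); bad_age$age <- 130L
  expect_error(validate_records(bad_age), "age")
})

test_that("completeness filter partitions records by missing answers or demographics", {
  rec <- make_records(4L)
  rec$q07[2L] <- NA_integer_
  rec$age[3L] <- NA_integer_
  out <- completeness_filter(rec)
  expect_identical(out$kept$record_id, c("r1", "r4"))
  expect_identical(out$excluded$record_id, c("r2", "r3"))
  expect_equal(nrow(out$kept) + nrow(out$excluded), nrow(rec))
})

test_that("filter exclusions match the generator's missingness bookkeeping", {
  prof <- group_profile(group = "NRO", missing_rate = 0.1)
  rec <- generate_cohort(prof, 1000L, seed = 21L)
  truth <- attr(rec, "truth")
  out <- completeness_filter(rec)
  expect_equal(nrow(out$excluded), sum(truth$n_missing > 0L))
  expect_setequal(out$excluded$record_id,
                  truth$record_id[truth$n_missing > 0L])
  # expected exclusion rate 1 - 0.9^53 is essentially 1 at rate 0.1;
  # check against the binomial expectation at 3 sigma
  p_excl <- 1 - 0.9^53
  expect_lt(abs(nrow(out$excluded) - 1000 * p_excl),
            3 * sqrt(1000 * p_excl * (1 - p_excl)) + 1)
})

test_that("encoding produces the 55-element vector with documented coding", {
  rec <- make_records(1L, answer = 1L, age = 40L, gender = "F")
  v <- encode_records(rec)[1L, ]
  expect_length(v, 55L)
  expect_equal(unname(v), c(rep(1, 53), 0, 40))
  rec2 <- make_records(1L, answer = 4L, age = 7L, gender = "M")
  expect_equal(unname(encode_records(rec2)[1L, ]), c(rep(4, 53), 1, 7))
  # configurable gender coding
  v3 <- encode_records(rec, gender_codes = c(F = 1, M = 0))[1L, ]
  expect_equal(unname(v3[54L]), 1)
})

test_that("encode refuses incomplete records and decode inverts encode", {
  rec <- make_records(2L)
  rec$q01[1L] <- NA_integer_
  expect_error(encode_records(rec), "complete")
  cohort <- generate_cohort(group_profile(group = "CD", diagnosis = "asthma"),
                            25L, seed = 31L)
  x <- encode_records(cohort)
  dec <- decode_features(x)
  expect_identical(unname(as.matrix(dec[, items])),
                   unname(as.matrix(cohort[, items])))
  expect_identical(dec$age, cohort$age)
  expect_identical(dec$gender, cohort$gender)
})
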