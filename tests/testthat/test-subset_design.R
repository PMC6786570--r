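test_that("default designs carry the published pairings and sizes", {
  d <- default_designs()
  expect_length(d, 3L)
  expect_equal(sapply(d, function(x) x$n1 + x$n2), c(180L, 180L, 80L))
  expect_equal(d[[3L]]$n1, 42L)
  expect_equal(d[[3L]]$n2, 38L)
  expect_equal(sum(sapply(d, function(x) x$n1 + x$n2)), 440L)
  expect_equal(sapply(d, `[[`, "class2_label"), c("NRO", "CD", "PSY"))
  expect_true("PAH" %in% d[[1L]]$class1_diagnoses)
  expect_true("sarcoidosis" %in% d[[2L]]$class1_diagnoses)
  expect_true("Fabry disease" %in% d[[3L]]$class1_diagnoses)
})

test_that("a pool with exactly the target counts is consumed whole, any seed", {
  pool <- rbind(make_records(6L, group = "RD", diagnosis = "PAH",
                             id_prefix = "a"),
                make_records(5L, group = "NRO", diagnosis = "none",
                             id_prefix = "b"))
  des <- subset_design(1L, "RD1", "PAH", "NRO", 6L, 5L, seed = 123L)
  for (s in c(1L, 99L)) {
    des$seed <- s
    ds <- assemble_subset(pool, des)
    expect_setequal(ds$record_ids, pool$record_id)
    expect_equal(as.vector(table(ds$y)), c(6L, 5L))
  }
})

test_that("assembly is deterministic under a fixed seed", {
  pool <- rbind(make_records(30L, group = "RD", diagnosis = "PAH",
                             id_prefix = "a"),
                make_records(30L, group = "NRO", diagnosis = "none",
                             id_prefix = "b"))
  des <- subset_design(1L, "RD1", "PAH", "NRO", 10L, 10L, seed = 7L)
  expect_identical(assemble_subset(pool, des)$record_ids,
                   assemble_subset(pool, des)$record_ids)
})

test_that("insufficient eligible records raise a capacity error naming the class", {
  pool <- rbind(make_records(5L, group = "RD", diagnosis = "PAH",
                             id_prefix = "a"),
                make_records(50L, group = "NRO", diagnosis = "none",
                             id_prefix = "b"))
  des <- subset_design(1L, "RD1", "PAH", "NRO", 10L, 10L)
  expect_error(assemble_subset(pool, des), "capacity error.*RD1")
  des2 <- subset_design(1L, "RD1", "PAH", "CD", 5L, 10L)
  expect_error(assemble_subset(pool, des2), "capacity error.*CD")
})

test_that("record ids are pairwise disjoint across assembled subsets", {
  pool <- simulate_study_pool(seed = 17L)
  subsets <- assemble_subsets(completeness_filter(pool)$kept,
                              default_designs(17L))
  ids <- lapply(subsets, `[[`, "record_ids")
  expect_equal(sapply(ids, length), c(180L, 180L, 80L))
  expect_equal(length(unique(unlist(ids))), 440L)
})

test_that("sampling is uniform over eligible records (Monte-Carlo)", {
  # 200 eligible per class, draw 90: per-record inclusion frequency 0.45
  pool <- rbind(make_records(200L, group = "RD", diagnosis = "PAH",
                             id_prefix = "a"),
                make_records(200L, group = "NRO", diagnosis = "none",
                             id_prefix = "b"))
  n_rep <- 400L
  counts <- stats::setNames(integer(400L), pool$record_id)
  for (s in seq_len(n_rep)) {
    des <- subset_design(1L, "RD1", "PAH", "NRO", 90L, 90L, seed = s)
    drawn <- assemble_subset(pool, des)$record_ids
    counts[drawn] <- counts[drawn] + 1L
  }
  p <- 90 / 200
  tol <- 5 * sqrt(p * (1 - p) / n_rep)  # per-record binomial band
  expect_true(all(abs(counts / n_rep - p) < tol))
  # and the average inclusion frequency is essentially exact
  expect_lt(abs(mean(counts / n_rep) - p), 0.005)
})

test_that("designs round-trip through the YAML design file", {
  d <- default_designs(5L)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_designs(d, f)
  back <- read_designs(f)
  expect_equal(back, d)
})
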