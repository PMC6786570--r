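#' Pairwise subset designs
#'
#' A subset design declares one of the three pairwise diagnostic challenges:
#' a rare-disease composite (class 1, matched by diagnosis label within the
#' RD group) against one whole comparison group (class 2: NRO, CD or PSY),
#' with exact per-class target sizes drawn by seeded uniform sampling.
#'
#' @param subset_id integer in 1..3 (or beyond for custom designs).
#' @param class1_label label for the rare-disease side, e.g. `"RD1"`.
#' @param class1_diagnoses character vector of diagnosis labels eligible for
#'   class 1 (matched case-insensitively within group `RD`).
#' @param class2_label label of the comparison group; also the `group` value
#'   records must carry to be eligible for class 2 (`NRO`, `CD` or `PSY`).
#' @param n1,n2 exact class sizes to draw.
#' @param seed integer seed for the random draw.
#' @return An object of class `rd_subset_design`.
#' @export
subset_design <- function(subset_id, class1_label, class1_diagnoses,
                          class2_label, n1, n2, seed = 1L) {
  stopifnot(length(class1_diagnoses) >= 1L, n1 >= 1L, n2 >= 1L)
  if (any(tolower(class1_diagnoses) %in% tolower(class2_label))) {
    stop("invalid design: class 1 and class 2 memberships overlap",
         call. = FALSE)
  }
  structure(
    list(subset_id = as.integer(subset_id),
         class1_label = class1_label,
         class1_diagnoses = class1_diagnoses,
         class2_label = class2_label,
         n1 = as.integer(n1), n2 = as.integer(n2),
         seed = as.integer(seed)),
    class = "rd_subset_design"
  )
}

#' @export
print.rd_subset_design <- function(x, ...) {
  cat(sprintf("Subset design %d: %s (n=%d) vs %s (n=%d), seed %d\n",
              x$subset_id, x$class1_label, x$n1, x$class2_label, x$n2, x$seed))
  cat("  class 1 diagnoses:", paste(x$class1_diagnoses, collapse = ", "), "\n")
  invisible(x)
}

#' The three default pairwise subset designs
#'
#' The default designs contrast: (1) pulmonary hypertension (PAH) and cystic
#' fibrosis against other non-rare diseases (NRO), 90:90; (2) sarcoidosis,
#' syringomyelia, SLE, acromegaly, Ehlers-Danlos syndromes, Morbus Still and
#' Nail-Patella syndrome against chronic diseases (CD), 90:90; (3) CIDP,
#' cluster headache, Meniere's disease and Fabry disease against
#' psychosomatic disorders (PSY), 42:38. Totals 180 + 180 + 80 = 440 training
#' questionnaires. The diagnosis-to-class mapping is user-editable: pass
#' modified designs to [assemble_subsets()].
#'
#' @param seed base seed; each design derives its own sampling seed from it.
#' @return List of three `rd_subset_design` objects.
#' @export
default_designs <- function(seed = 1L) {
  list(
    subset_design(1L, "RD1",
                  c("PAH", "cystic fibrosis"),
                  "NRO", 90L, 90L, derive_seed(seed, 1L)),
    subset_design(2L, "RD2",
                  c("sarcoidosis", "syringomyelia", "SLE", "acromegaly",
                    "Ehlers-Danlos syndrome", "Morbus Still",
                    "Nail-Patella syndrome"),
                  "CD", 90L, 90L, derive_seed(seed, 2L)),
    subset_design(3L, "RD3",
                  c("CIDP", "cluster headache", "Meniere disease",
                    "Fabry disease"),
                  "PSY", 42L, 38L, derive_seed(seed, 3L))
  )
}

#' Materialize one pairwise training subset from a record pool
#'
#' Draws exactly `n1` class-1 and `n2` class-2 complete records by seeded
#' uniform sampling without replacement. Records named in `exclude_ids` are
#' treated as already consumed by earlier subsets, enforcing the rule that
#' each questionnaire belongs to at most one subset.
#'
#' @param pool validated record data.frame (complete records; incomplete rows
#'   are ignored).
#' @param design an `rd_subset_design`.
#' @param exclude_ids record ids already consumed elsewhere.
#' @param gender_codes passed to [encode_records()].
#' @return An object of class `rd_subset_dataset`: list with `subset_id`,
#'   `x` (n x 55 feature matrix), `y` (factor, class-1 level first),
#'   `record_ids`, `class_labels` and the `design`.
#' @export
assemble_subset <- function(pool, design, exclude_ids = character(),
                            gender_codes = c(F = 0, M = 1)) {
  pool <- completeness_filter(pool)$kept
  avail <- !(pool$record_id %in% exclude_ids)
  elig1 <- avail & pool$group == "RD" &
    tolower(pool$diagnosis) %in% tolower(design$class1_diagnoses)
  elig2 <- avail & pool$group == design$class2_label
  if (sum(elig1) < design$n1) {
    stop(sprintf(
      "capacity error: class 1 (%s) needs %d eligible records, pool has %d",
      design$class1_label, design$n1, sum(elig1)), call. = FALSE)
  }
  if (sum(elig2) < design$n2) {
    stop(sprintf(
      "capacity error: class 2 (%s) needs %d eligible records, pool has %d",
      design$class2_label, design$n2, sum(elig2)), call. = FALSE)
  }
  set.seed(design$seed)
  ids1 <- sample(pool$record_id[elig1], design$n1)
  ids2 <- sample(pool$record_id[elig2], design$n2)
  chosen <- pool[match(c(ids1, ids2), pool$record_id), , drop = FALSE]
  y <- factor(rep(c(design$class1_label, design$class2_label),
                  c(design$n1, design$n2)),
              levels = c(design$class1_label, design$class2_label))
  new_subset_dataset(design$subset_id,
                     encode_records(chosen, gender_codes), y,
                     chosen$record_id,
                     c(design$class1_label, design$class2_label),
                     design)
}

new_subset_dataset <- function(subset_id, x, y, record_ids, class_labels,
                               design = NULL) {
  stopifnot(nrow(x) == length(y), nlevels(y) == 2L)
  structure(list(subset_id = as.integer(subset_id), x = x, y = y,
                 record_ids = record_ids, class_labels = class_labels,
                 design = design),
            class = "rd_subset_dataset")
}

#' @export
print.rd_subset_dataset <- function(x, ...) {
  cat(sprintf("Subset dataset %d: %s\n", x$subset_id,
              paste(sprintf("%s=%d", levels(x$y), table(x$y)),
                    collapse = " vs ")))
  invisible(x)
}

#' Assemble all subsets from a pool with one-subset-per-record consumption
#'
#' Subsets are assembled in design order; records drawn by an earlier subset
#' are consumed and never reused, so record-id sets are pairwise disjoint
#' across the returned datasets.
#'
#' @param pool validated record data.frame.
#' @param designs list of `rd_subset_design` objects, e.g.
#'   [default_designs()].
#' @param gender_codes passed to [encode_records()].
#' @return List of `rd_subset_dataset`, one per design.
#' @export
assemble_subsets <- function(pool, designs = default_designs(),
                             gender_codes = c(F = 0, M = 1)) {
  used <- character()
  out <- vector("list", length(designs))
  for (i in seq_along(designs)) {
    out[[i]] <- assemble_subset(pool, designs[[i]], exclude_ids = used,
                                gender_codes = gender_codes)
    used <- c(used, out[[i]]$record_ids)
  }
  out
}

#' Read / write subset designs as YAML
#'
#' @param path YAML file declaring a list of designs with keys `subset_id`,
#'   `class1_label`, `class1_diagnoses`, `class2_label`, `n1`, `n2`, `seed`.
#' @return `read_designs` returns a list of `rd_subset_design`;
#'   `write_designs` returns `path` invisibly.
#' @export
read_designs <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(d) {
    subset_design(d$subset_id, d$class1_label, unlist(d$class1_diagnoses),
                  d$class2_label, d$n1, d$n2, d$seed)
  })
}

#' @rdname read_designs
#' @param designs list of `rd_subset_design` objects.
#' @export
write_designs <- function(designs, path) {
  yaml::write_yaml(lapply(designs, unclass), path)
  invisible(path)
}

# training-time row order is canonicalized by record id so that fitted models
# (and hence output probabilities) are invariant to the order records arrive in
canonical_order <- function(dataset) {
  ord <- order(dataset$record_ids)
  new_subset_dataset(dataset$subset_id, dataset$x[ord, , drop = FALSE],
                     dataset$y[ord], dataset$record_ids[ord],
                     dataset$class_labels, dataset$design)
}

# deterministic sub-seed derivation so that one run seed drives every source
# of randomness without reuse; stays below 2^31 - 1
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) %% 65536) * 32749 + 7919 * (offset %% 65536)) %% 2147483647L
}
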