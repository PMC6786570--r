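#' Respondent record table: columns and validation
#'
#' Records are held as a plain data.frame, one row per answered questionnaire,
#' in the canonical column order
#' `record_id, q01..q53, age, gender, diagnosis, group, rd_subgroup`.
#' Missing answers are `NA`; gender is `"F"`/`"M"`; `group` is one of
#' `RD, NRO, CD, PSY, HEALTHY, UNKNOWN`.
#' @name record-table
NULL

record_columns <- function(schema = questionnaire_schema()) {
  c("record_id", schema$items, "age", "gender", "diagnosis", "group",
    "rd_subgroup")
}

#' Validate a respondent record table
#'
#' Checks the structural invariants of a record table: required columns
#' present, every non-missing answer in `{1,2,3,4}`, age within 0--120,
#' gender in `{F, M}`, and group one of the six enumerated values. Violations
#' raise an error naming the offending item and record id; values are never
#' silently coerced.
#'
#' @param records data.frame of respondent records.
#' @param schema questionnaire schema, see [questionnaire_schema()].
#' @return The validated data.frame, invisibly typed (answers and age
#'   integer, character ids).
#' @export
validate_records <- function(records, schema = questionnaire_schema()) {
  required <- setdiff(record_columns(schema), "rd_subgroup")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"rd_subgroup" %in% names(records)) records$rd_subgroup <- NA_character_
  records <- records[, record_columns(schema), drop = FALSE]
  records$record_id <- as.character(records$record_id)
  if (anyDuplicated(records$record_id)) {
    stop("validation error: duplicated record_id", call. = FALSE)
  }
  for (item in schema$items) {
    v <- records[[item]]
    if (is.character(v)) v[!nzchar(trimws(v))] <- NA
    vn <- suppressWarnings(as.numeric(v))
    bad <- which((!is.na(v) & is.na(vn)) |
                   (!is.na(vn) & (!vn %in% schema$scale)))
    if (length(bad) > 0L) {
      stop(sprintf(
        "validation error: answer outside {1,2,3,4} in item %s (record %s)",
        item, records$record_id[bad[1L]]), call. = FALSE)
    }
    records[[item]] <- as.integer(vn)
  }
  age <- suppressWarnings(as.numeric(records$age))
  bad_age <- which((!is.na(records$age) & is.na(age) &
                      nzchar(trimws(as.character(records$age)))) |
                     (!is.na(age) & (age < 0 | age > 120)))
  if (length(bad_age) > 0L) {
    stop(sprintf("validation error: age outside 0-120 (record %s)",
                 records$record_id[bad_age[1L]]), call. = FALSE)
  }
  records$age <- as.integer(round(age))
  g <- as.character(records$gender)
  g[!is.na(g) & !nzchar(trimws(g))] <- NA
  bad_g <- which(!is.na(g) & !g %in% rd_genders())
  if (length(bad_g) > 0L) {
    stop(sprintf("validation error: gender must be F or M (record %s)",
                 records$record_id[bad_g[1L]]), call. = FALSE)
  }
  records$gender <- g
  grp <- as.character(records$group)
  bad_grp <- which(is.na(grp) | !grp %in% rd_groups())
  if (length(bad_grp) > 0L) {
    stop(sprintf("validation error: group must be one of %s (record %s)",
                 paste(rd_groups(), collapse = "/"),
                 records$record_id[bad_grp[1L]]), call. = FALSE)
  }
  records$group <- grp
  records$diagnosis <- as.character(records$diagnosis)
  records$rd_subgroup <- as.character(records$rd_subgroup)
  rownames(records) <- NULL
  records
}

#' Load respondent records from a delimited text file
#'
#' Reads the canonical UTF-8 CSV (one row per respondent, header
#' `record_id,q01..q53,age,gender,diagnosis,group,rd_subgroup`; missing
#' answers empty) and validates every row. Rows with out-of-range codes raise
#' an error naming the item and record; they are never coerced.
#'
#' @param path path to a CSV file.
#' @param schema questionnaire schema.
#' @return A validated record data.frame.
#' @seealso [write_records()], [validate_records()]
#' @export
load_records <- function(path, schema = questionnaire_schema()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = c("NA", ""))
  validate_records(raw, schema)
}

#' Write respondent records to the canonical CSV
#'
#' @param records validated record data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  records <- validate_records(records)
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Partition records into complete and incomplete questionnaires
#'
#' A record is complete when all 53 answers and both demographics (age,
#' gender) are present. Incomplete questionnaires are excluded from all
#' training and evaluation, mirroring the study design that discards
#' incomplete forms; no imputation is performed.
#'
#' @param records validated record data.frame.
#' @param schema questionnaire schema.
#' @return A list with data.frames `kept` and `excluded`; together they
#'   partition the input.
#' @export
completeness_filter <- function(records, schema = questionnaire_schema()) {
  ans <- as.matrix(records[, schema$items, drop = FALSE])
  complete <- rowSums(is.na(ans)) == 0L &
    !is.na(records$age) & !is.na(records$gender)
  list(kept = records[complete, , drop = FALSE],
       excluded = records[!complete, , drop = FALSE])
}

#' Encode complete records as 55-element feature vectors
#'
#' Each complete questionnaire becomes a numeric vector of 55 elements: the
#' 53 answers copied verbatim on their 1--4 scale, then the gender code
#' (female = 0, male = 1 by default), then the age in years. This is the
#' input representation consumed by all base classifiers.
#'
#' @param records validated, complete record data.frame.
#' @param gender_codes named numeric vector mapping `F` and `M` to codes.
#' @param schema questionnaire schema.
#' @return Numeric matrix with one row per record (rownames = record ids) and
#'   55 named columns (`q01..q53, gender, age`).
#' @examples
#' rec <- data.frame(record_id = "r1", t(setNames(rep(1L, 53), sprintf("q%02d", 1:53))),
#'                   age = 40L, gender = "F", diagnosis = "PAH", group = "RD",
#'                   rd_subgroup = NA)
#' encode_records(rec)[1, c(1, 54, 55)] # 1, 0, 40
#' @export
encode_records <- function(records, gender_codes = c(F = 0, M = 1),
                           schema = questionnaire_schema()) {
  stopifnot(setequal(names(gender_codes), rd_genders()))
  records <- validate_records(records, schema)
  ans <- as.matrix(records[, schema$items, drop = FALSE])
  if (anyNA(ans) || anyNA(records$age) || anyNA(records$gender)) {
    stop("precondition error: encode requires complete records; ",
         "apply completeness_filter() first", call. = FALSE)
  }
  x <- cbind(ans,
             gender = unname(gender_codes[records$gender]),
             age = as.numeric(records$age))
  storage.mode(x) <- "double"
  rownames(x) <- records$record_id
  x
}

#' Decode feature vectors back into answers, gender and age
#'
#' Inverse of [encode_records()] up to the documented coding; round-trips
#' exactly on complete records.
#'
#' @param x numeric matrix with 55 columns as produced by [encode_records()].
#' @param gender_codes the coding used at encode time.
#' @return data.frame with columns `q01..q53`, `age`, `gender`.
#' @export
decode_features <- function(x, gender_codes = c(F = 0, M = 1)) {
  x <- feature_matrix(x)
  schema <- questionnaire_schema()
  out <- as.data.frame(x[, seq_len(53L), drop = FALSE])
  names(out) <- schema$items
  out[] <- lapply(out, as.integer)
  out$age <- as.integer(x[, 55L])
  inv <- stats::setNames(names(gender_codes), as.character(gender_codes))
  out$gender <- unname(inv[as.character(x[, 54L])])
  rownames(out) <- rownames(x)
  out
}

# coerce a single 55-vector or matrix to the n x 55 feature matrix contract
feature_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != 55L) {
    stop("contract error: feature vectors must have exactly 55 elements, got ",
         ncol(x), call. = FALSE)
  }
  storage.mode(x) <- "double"
  colnames(x) <- c(questionnaire_schema()$items, "gender", "age")
  x
}
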