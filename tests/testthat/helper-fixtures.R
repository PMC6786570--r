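# shared fixtures built in code

items <- questionnaire_schema()$items

# a small well-formed record table; all answers fixed unless overridden
make_records <- function(n = 3L, answer = 1L, group = "RD",
                         diagnosis = "PAH", age = 40L, gender = "F",
                         id_prefix = "r") {
  ans <- matrix(answer, nrow = n, ncol = 53L,
                dimnames = list(NULL, items))
  df <- data.frame(record_id = paste0(id_prefix, seq_len(n)), ans,
                   age = age, gender = gender, diagnosis = diagnosis,
                   group = group, rd_subgroup = NA_character_,
                   stringsAsFactors = FALSE)
  validate_records(df)
}

# linearly separable toy subset: two clusters in the first feature only,
# embedded in the 55-element questionnaire encoding
make_toy_dataset <- function(n_per_class = 10L, seed = 99L) {
  set.seed(seed)
  a <- make_records(n_per_class, answer = 1L, group = "RD",
                    diagnosis = "case", id_prefix = "a")
  b <- make_records(n_per_class, answer = 4L, group = "NRO",
                    diagnosis = "ctrl", id_prefix = "b")
  # jitter answers of two mid items so no feature is constant within class
  for (it in c("q30", "q31")) {
    a[[it]] <- sample(1:2, n_per_class, replace = TRUE)
    b[[it]] <- sample(3:4, n_per_class, replace = TRUE)
  }
  a$age <- sample(30:50, n_per_class, replace = TRUE)
  b$age <- sample(30:50, n_per_class, replace = TRUE)
  a$gender <- sample(c("F", "M"), n_per_class, replace = TRUE)
  b$gender <- sample(c("F", "M"), n_per_class, replace = TRUE)
  rec <- rbind(a, b)
  y <- factor(rep(c("case", "ctrl"), each = n_per_class),
              levels = c("case", "ctrl"))
  rdscreen:::new_subset_dataset(1L, encode_records(rec), y, rec$record_id,
                                c("case", "ctrl"))
}

# independent AUC oracle: exhaustive pair counting with ties counted half
auc_oracle <- function(truth, scores) {
  pos <- scores[truth]
  neg <- scores[!truth]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

base_result <- function(family, idx, p) {
  structure(list(family = family, predicted_index = idx, probability = p),
            class = "rd_base_result")
}

base_result_list <- function(idx = c(0L, 0L, 1L, 0L),
                             p = c(0.9, 0.8, 0.6, 0.7)) {
  mapply(base_result, base_families(), idx, p, SIMPLIFY = FALSE,
         USE.NAMES = FALSE)
}
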