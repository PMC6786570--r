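#' Questionnaire schema
#'
#' The fixed schema of the screening questionnaire: 53 ordinal items answered
#' on a 1--4 scale (1 = "completely false" ... 4 = "completely true"), plus
#' the respondent's age in years and gender.
#'
#' @return An object of class `rd_schema` with components `items` (ordered
#'   item ids `"q01".."q53"`), `scale` (the integer levels `1:4`),
#'   `scale_anchors` (named anchors for the extreme levels) and
#'   `demographics` (`"age"`, `"gender"`).
#' @examples
#' s <- questionnaire_schema()
#' length(s$items) # 53
#' @export
questionnaire_schema <- function() {
  structure(
    list(
      items = sprintf("q%02d", seq_len(53L)),
      scale = 1:4,
      scale_anchors = c(`1` = "completely false", `4` = "completely true"),
      demographics = c("age", "gender")
    ),
    class = "rd_schema"
  )
}

#' @export
print.rd_schema <- function(x, ...) {
  cat("Questionnaire schema:", length(x$items), "items,",
      "answer scale", paste(range(x$scale), collapse = "-"),
      sprintf("(%s ... %s)\n", x$scale_anchors[["1"]], x$scale_anchors[["4"]]))
  invisible(x)
}

# enumerated diagnostic groups; HEALTHY and UNKNOWN exist only for pool
# bookkeeping and are never eligible for subset assembly
rd_groups <- function() c("RD", "NRO", "CD", "PSY", "HEALTHY", "UNKNOWN")

rd_genders <- function() c("F", "M")
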