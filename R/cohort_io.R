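# Cohort CSV dialect: one header row; participant_id, group, age, gender,
# aq_total, icar, then one column per task feature; missing cells empty.
# Numerics are written with 17 significant digits so a write/read round trip
# reproduces every double bit-exactly.

DEMO_COLUMNS <- c("participant_id", "group", "age", "gender", "aq_total", "icar")

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a cohort to CSV
#'
#' @param records cohort data frame (see [generate_cohort()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_cohort()] for the inverse; the round trip is exact,
#'   including missing markers (empty cells).
#' @export
write_cohort <- function(records, path) {
  feats <- cohort_feature_names(records)
  stopifnot(all(DEMO_COLUMNS %in% names(records)),
            all(feats %in% names(records)))
  out <- data.frame(
    participant_id = as.character(records$participant_id),
    group = as.character(records$group),
    age = fmt_num(records$age),
    gender = as.character(records$gender),
    aq_total = fmt_num(records$aq_total),
    icar = fmt_num(records$icar),
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  for (f in feats) out[[f]] <- fmt_num(records[[f]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Validates the file against the task-block schema: the feature columns
#' must match the schema exactly, and every feature cell must be numeric or
#' empty (the missing marker).
#'
#' @param path CSV file written by [write_cohort()] (or matching its dialect).
#' @param task_blocks task-block schema the feature columns must match.
#' @return A cohort data frame, as from [generate_cohort()].
#' @export
read_cohort <- function(path, task_blocks = default_task_blocks()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  feats <- feature_names_from_blocks(task_blocks)
  missing_cols <- setdiff(c(DEMO_COLUMNS, feats), names(raw))
  if (length(missing_cols)) {
    stop("cohort file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(raw), c(DEMO_COLUMNS, feats))
  if (length(unknown)) {
    stop("cohort file has column(s) absent from the schema: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  parse_num <- function(col, allow_missing = TRUE) {
    x <- raw[[col]]
    empty <- !nzchar(x)
    if (!allow_missing && any(empty)) {
      stop("empty cell in required column '", col, "' at row ",
           which(empty)[1], call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(x))
    bad <- !empty & is.na(val)
    if (any(bad)) {
      stop("non-numeric value '", x[which(bad)[1]], "' in column '", col,
           "' at row ", which(bad)[1], call. = FALSE)
    }
    val
  }

  records <- data.frame(
    participant_id = raw$participant_id,
    group = factor(raw$group, levels = c("autistic", "nonautistic")),
    age = parse_num("age", allow_missing = FALSE),
    gender = factor(raw$gender, levels = c("w", "m")),
    aq_total = parse_num("aq_total", allow_missing = FALSE),
    icar = parse_num("icar", allow_missing = FALSE),
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  if (anyNA(records$group)) {
    stop("unrecognized group label at row ", which(is.na(records$group))[1],
         call. = FALSE)
  }
  for (f in feats) records[[f]] <- parse_num(f)
  structure(records, task_blocks = task_blocks,
            class = c("cohort", "data.frame"))
}
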