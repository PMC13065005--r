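#' Read a drug-review CSV
#'
#' Expects the Kaggle drug-review dialect: at least the columns `drugName`,
#' `condition` and `review` (quoted fields with embedded commas or newlines
#' are handled by the CSV parser). A `review_id` column (or the common
#' `uniqueID`) is used when present, otherwise row numbers become ids.
#'
#' @param path CSV file path
#' @param condition_filter optional condition name; rows are matched
#'   case-insensitively on exact condition equality
#' @return data.frame with columns `review_id`, `drug_name`, `condition`,
#'   `text`
#' @export
read_reviews <- function(path, condition_filter = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("drugName", "condition", "review")) {
    if (!(col %in% names(raw))) {
      stop_aspectrx(paste0("input CSV is missing required column '", col, "'"),
                    "aspectrx_format_error")
    }
  }
  id <- if ("review_id" %in% names(raw)) raw$review_id
        else if ("uniqueID" %in% names(raw)) raw$uniqueID
        else paste0("r", seq_len(nrow(raw)))
  out <- data.frame(
    review_id = as.character(id),
    drug_name = as.character(raw$drugName),
    condition = as.character(raw$condition),
    text = as.character(raw$review),
    stringsAsFactors = FALSE
  )
  if (!is.null(condition_filter)) {
    keep <- tolower(out$condition) == tolower(condition_filter)
    if (!any(keep)) {
      warning("condition filter '", condition_filter, "' matched no rows",
              call. = FALSE)
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

record_to_json <- function(record) {
  jsonlite::toJSON(unclass(record), auto_unbox = TRUE, digits = NA,
                   null = "null")
}

#' Write annotation records as JSONL
#'
#' One record per line, UTF-8, stable key order (construction order of the
#' record fields), full numeric precision — byte-identical across runs for
#' identical inputs and configuration.
#'
#' @param records list of `annotation_record`s
#' @param path output file
#' @return `path`, invisibly
#' @export
write_annotations <- function(records, path) {
  lines <- vapply(records, function(r) as.character(record_to_json(r)),
                  character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) {
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Read annotation records from JSONL
#'
#' @param path JSONL file written by [write_annotations()]
#' @return list of `annotation_record`s
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    structure(jsonlite::fromJSON(l, simplifyVector = FALSE),
              class = "annotation_record")
  })
}

# BIO labels for one sentence entry: a kept-aspect token opens a span (B-ASP)
# unless the previous token is also covered, in which case it continues it
# (I-ASP); adjacent distinct aspects therefore merge into one span.
sentence_bio <- function(entry) {
  n <- length(entry$tokens)
  if (!n) return(character())
  covered <- rep(FALSE, n)
  for (a in entry$aspects) {
    for (idx in unlist(a$indices)) covered[idx + 1L] <- TRUE
  }
  labels <- rep("O", n)
  for (k in seq_len(n)) {
    if (covered[k]) {
      labels[k] <- if (k > 1L && covered[k - 1L]) "I-ASP" else "B-ASP"
    }
  }
  labels
}

#' Export annotations in CoNLL BIO format
#'
#' One `token TAB label` line per token with labels `O`, `B-ASP`, `I-ASP`;
#' a blank line between sentences and a `-DOCSTART-` line between reviews.
#' The config fingerprint is written as a leading comment line.
#'
#' @param records list of `annotation_record`s
#' @param path output file
#' @return `path`, invisibly
#' @export
write_conll <- function(records, path) {
  lines <- character()
  fp <- if (length(records)) records[[1]]$fingerprint else ""
  lines <- c(lines, paste0("# fingerprint: ", fp))
  for (r in records) {
    lines <- c(lines, "-DOCSTART-\tO", "")
    for (entry in r$sentences) {
      toks <- unlist(entry$tokens)
      if (!length(toks)) next
      bio <- sentence_bio(entry)
      lines <- c(lines, paste(toks, bio, sep = "\t"), "")
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a run configuration as YAML
#'
#' @param config a [run_config()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to [run_config()]
#' defaults. The fingerprint is recomputed, never trusted from the file.
#'
#' @param path YAML file
#' @return a [run_config()]
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$fingerprint <- NULL
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop_aspectrx(paste0("unknown config keys: ", paste(bad, collapse = ", ")),
                  "aspectrx_config_error")
  }
  if (!is.null(vals$thresholds)) {
    vals$thresholds <- do.call(thresholds, vals$thresholds)
  }
  do.call(run_config, vals)
}

#' Read annotator label files
#'
#' TSV with columns `item_id`, `annotator_id`, `label`, one row per
#' (item, annotator) pair.
#'
#' @param path TSV file
#' @return data.frame of the three columns
#' @export
read_annotator_labels <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#", quote = "")
  need <- c("item_id", "annotator_id", "label")
  if (!all(need %in% names(tab))) {
    stop_aspectrx(paste0("annotator label file needs columns: ",
                         paste(need, collapse = ", ")),
                  "aspectrx_format_error")
  }
  tab
}
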