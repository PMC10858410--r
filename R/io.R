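#' Delimited-text dataset and table IO
#'
#' All tables are written as comma-delimited text with an explicit header.
#' Missing heart rates are written as empty fields; temperatures carry two
#' decimals. Each file starts with a `#` comment line recording the package
#' stage, the seed (when known) and a short configuration hash, so a result
#' file can be traced to the run that produced it.
#'
#' @param data dataset data frame (see [generate_dataset()]).
#' @param path file path.
#' @param seed seed recorded in the header comment.
#' @param config object whose hash is recorded in the header comment.
#' @param stage stage label for the header comment.
#' @return `write_dataset`/`write_table_stamped` return `path` invisibly;
#'   `read_dataset` returns the dataset data frame.
#' @export
write_dataset <- function(data, path, seed = NA, config = NULL,
                          stage = "simulate") {
  d <- data
  d$incubation_C <- sprintf("%.2f", d$incubation_C)
  d$step_temp_C <- sprintf("%.2f", d$step_temp_C)
  d$f_H_bpm <- ifelse(is.na(d$f_H_bpm), "", sprintf("%.15g", d$f_H_bpm))
  d$arrhythmic <- ifelse(d$arrhythmic, "TRUE", "FALSE")
  write_table_stamped(d, path, seed = seed, config = config, stage = stage)
}

#' @rdname write_dataset
#' @export
write_table_stamped <- function(data, path, seed = NA, config = NULL,
                                stage = "table") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cardiotherm %s; seed=%s; config=%s", stage,
                     as.character(seed), config_hash(config)), con)
  utils::write.csv(data, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# polynomial rolling hash over the deparsed object; a stable fingerprint
config_hash <- function(config) {
  if (is.null(config)) return("none")
  txt <- paste(deparse(config), collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("cannot read dataset: ", path)
  d <- utils::read.csv(path, comment.char = "#", na.strings = "")
  if (nrow(d) == 0) stop("dataset file is empty: ", path)
  needed <- c("individual_id", "clutch_id", "incubation_C", "step_temp_C",
              "f_H_bpm", "arrhythmic")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols))
    stop("dataset file missing columns: ", paste(missing_cols, collapse = ", "))
  d$arrhythmic <- as.logical(d$arrhythmic)
  d
}

#' Validate a population dataset against its structural invariants
#'
#' Checks that every individual appears at exactly the same set of protocol
#' steps, that heart rate is missing exactly on arrhythmic rows, and that
#' arrhythmia flags are upward-closed in temperature for each individual.
#' Violations are reported with the individual and row context.
#'
#' @param x dataset data frame or path to a dataset file.
#' @return A list of class `dataset_report`: `n_individuals`,
#'   `group_counts` (individuals per incubation temperature), `n_rows`,
#'   `violations` (character vector, empty when valid), `valid`.
#' @export
validate_dataset <- function(x) {
  d <- if (is.character(x)) read_dataset(x) else x
  if (nrow(d) == 0) stop("empty dataset")
  viol <- character(0)
  bad_na <- xor(is.na(d$f_H_bpm), d$arrhythmic)
  if (any(bad_na))
    viol <- c(viol, sprintf("row %d (individual %s): f_H missing must match arrhythmic flag",
                            which(bad_na), d$individual_id[bad_na]))
  parts <- split(d, factor(d$individual_id, unique(d$individual_id)))
  step_sets <- unique(lapply(parts, function(p) sort(p$step_temp_C)))
  if (length(step_sets) > 1)
    viol <- c(viol, "individuals observed at differing step sets")
  for (p in parts) {
    p <- p[order(p$step_temp_C), ]
    if (is.unsorted(p$arrhythmic))
      viol <- c(viol, sprintf("individual %s: arrhythmia flags not upward-closed in temperature",
                              p$individual_id[1]))
  }
  firsts <- d[!duplicated(d$individual_id), ]
  counts <- table(firsts$incubation_C)
  structure(list(n_individuals = nrow(firsts),
                 group_counts = counts,
                 n_rows = nrow(d),
                 violations = viol,
                 valid = length(viol) == 0),
            class = "dataset_report")
}

#' @export
print.dataset_report <- function(x, ...) {
  cat("Dataset:", x$n_individuals, "individuals,", x$n_rows, "rows\n")
  cat("  per incubation group:",
      paste(sprintf("%s degC: %d", names(x$group_counts), x$group_counts),
            collapse = "; "), "\n")
  if (x$valid) cat("  all invariants hold\n")
  else cat("  VIOLATIONS:\n", paste(" -", x$violations, collapse = "\n"), "\n")
  invisible(x)
}
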