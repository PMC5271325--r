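# Canonical file formats: the trial-table CSV (one row per trial) and a
# YAML run configuration. CSV is the interchange format on purpose: the
# tables are small (<= 696 rows per subject) and diffable.

trial_table_columns <- c(
  subject_id = "c", phase = "c", block = "i", trial_index = "i",
  r1_cm = "d", r2_cm = "d", rho = "d", s_true_cm = "d", jitter_cm = "d",
  perturbation_level = "d", b_cm = "d", uncertainty_class = "c",
  feedback = "l", r_cm = "d", delta_s_cm = "d", score = "d"
)

#' Write a trial table to CSV
#'
#' Writes the canonical trial-table schema (fixed column set, units in
#' the column names, UTF-8, header). Missing scores (no-feedback trials)
#' are written as empty fields. Round-trips losslessly through
#' [read_trial_table()].
#'
#' @param records A response tibble (all schema columns present).
#' @param path Output file path.
#' @return `records`, invisibly.
#' @export
write_trial_table <- function(records, path) {
  cols <- names(trial_table_columns)
  missing <- setdiff(cols, names(records))
  if (length(missing) > 0) {
    abort(paste0("Trial table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "comreach_schema_error")
  }
  readr::write_csv(records[cols], path, na = "")
  invisible(records)
}

#' Read a trial table from CSV
#'
#' Header-keyed (column order free), full-precision numeric parsing,
#' row order preserved. Missing or extra columns and non-numeric cells
#' raise a schema error naming the offender.
#'
#' @param path CSV file path.
#' @return A trial-table tibble.
#' @export
read_trial_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  cols <- names(trial_table_columns)
  missing <- setdiff(cols, names(raw))
  extra <- setdiff(names(raw), cols)
  if (length(missing) > 0 || length(extra) > 0) {
    abort(paste0(
      "Trial table schema mismatch.",
      if (length(missing)) paste0(" Missing: ",
                                  paste(missing, collapse = ", "), "."),
      if (length(extra)) paste0(" Unexpected: ",
                                paste(extra, collapse = ", "), ".")
    ), class = "comreach_schema_error")
  }
  raw <- raw[cols]
  parse_col <- function(x, type, name) {
    if (type == "c") return(x)
    if (type == "l") {
      out <- as.logical(x)
    } else {
      out <- suppressWarnings(as.numeric(x))
      if (type == "i") out <- as.integer(round(out))
    }
    bad <- which(is.na(out) & !is.na(x) & x != "")
    if (length(bad) > 0) {
      abort(sprintf("Column `%s`: non-%s value at row %d (\"%s\").",
                    name, if (type == "l") "logical" else "numeric",
                    bad[1], x[bad[1]]),
            class = "comreach_schema_error")
    }
    out
  }
  out <- Map(function(type, name) parse_col(raw[[name]], type, name),
             trial_table_columns, names(trial_table_columns))
  as_tibble(out)
}

#' Save / load a run configuration
#'
#' Serializes seeds, session parameters, observer parameters or fit
#' ranges and output settings to YAML, round-tripping exactly.
#'
#' @param config A named list.
#' @param path YAML file path.
#' @return `save_run_config()` returns `config` invisibly;
#'   `load_run_config()` returns the list.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(config)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  yaml::read_yaml(path)
}
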