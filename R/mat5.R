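# Minimal MAT-file (v5) reader: numeric arrays, character arrays, cell
# arrays and structs, with zlib-compressed elements. Written here because
# no installed R package reads MAT containers; it covers what the subject
# dataset import needs and no more.

mi_types <- c("int8" = 1, "uint8" = 2, "int16" = 3, "uint16" = 4,
              "int32" = 5, "uint32" = 6, "single" = 7, "double" = 9,
              "int64" = 12, "uint64" = 13, "matrix" = 14,
              "compressed" = 15, "utf8" = 16, "utf16" = 17)

mat5_cursor <- function(buf) {
  env <- new.env(parent = emptyenv())
  env$buf <- buf
  env$pos <- 1L
  env
}

mat5_take <- function(cur, n) {
  if (n == 0) return(raw(0))
  out <- cur$buf[cur$pos:(cur$pos + n - 1L)]
  cur$pos <- cur$pos + as.integer(n)
  out
}

mat5_int <- function(raw, size, signed = TRUE, endian = "little") {
  # R has no unsigned 32-bit reads; MAT sizes/types fit in signed range
  if (size == 4) signed <- TRUE
  readBin(raw, "integer", n = length(raw) %/% size, size = size,
          signed = signed, endian = endian)
}

# one data element: list(type, data_raw); handles the small-element format
mat5_element <- function(cur, endian) {
  tag <- mat5_take(cur, 4L)
  type_small <- mat5_int(tag, 2L, signed = FALSE, endian = endian)
  if (endian == "big") type_small <- rev(type_small)
  if (type_small[2] != 0) {
    # small element: 2-byte type, 2-byte size, data in next 4 bytes
    type <- type_small[1]
    size <- type_small[2]
    data <- mat5_take(cur, 4L)[seq_len(size)]
  } else {
    type <- mat5_int(tag, 4L, signed = FALSE, endian = endian)
    size <- mat5_int(mat5_take(cur, 4L), 4L, signed = FALSE, endian = endian)
    data <- mat5_take(cur, size)
    pad <- (8L - size %% 8L) %% 8L
    if (pad > 0) mat5_take(cur, pad)
  }
  list(type = type, data = data)
}

mat5_numeric <- function(el, endian) {
  d <- el$data
  switch(as.character(el$type),
         "1" = mat5_int(d, 1L, TRUE, endian),
         "2" = as.integer(d),
         "3" = mat5_int(d, 2L, TRUE, endian),
         "4" = mat5_int(d, 2L, FALSE, endian),
         "5" = mat5_int(d, 4L, TRUE, endian),
         "6" = {
           v <- mat5_int(d, 4L, TRUE, endian)  # may wrap; fine for sizes
           as.numeric(v)
         },
         "7" = readBin(d, "numeric", n = length(d) %/% 4L, size = 4L,
                       endian = endian),
         "9" = readBin(d, "numeric", n = length(d) %/% 8L, size = 8L,
                       endian = endian),
         "16" = rawToChar(d),
         abort(sprintf("Unsupported MAT element type %d.", el$type),
               class = "comreach_import_error"))
}

mat5_matrix <- function(raw_data, endian) {
  cur <- mat5_cursor(raw_data)
  flags_el <- mat5_element(cur, endian)
  flags <- mat5_int(flags_el$data, 4L, signed = FALSE, endian = endian)
  class_id <- bitwAnd(flags[1], 255L)
  dims_el <- mat5_element(cur, endian)
  dims <- mat5_int(dims_el$data, 4L, TRUE, endian)
  name_el <- mat5_element(cur, endian)
  name <- rawToChar(name_el$data)
  value <- NULL
  if (class_id %in% 6:15) {                      # numeric classes
    data_el <- mat5_element(cur, endian)
    value <- array(as.numeric(mat5_numeric(data_el, endian)), dim = dims)
  } else if (class_id == 4) {                    # char
    data_el <- mat5_element(cur, endian)
    chars <- if (data_el$type == 16) {
      strsplit(rawToChar(data_el$data), "")[[1]]
    } else {
      intToUtf8(mat5_int(data_el$data, 2L, FALSE, endian), multiple = TRUE)
    }
    value <- paste(chars, collapse = "")
  } else if (class_id == 1) {                    # cell
    n <- prod(dims)
    value <- vector("list", n)
    for (i in seq_len(n)) {
      sub <- mat5_element(cur, endian)
      value[[i]] <- mat5_matrix(sub$data, endian)$value
    }
    dim(value) <- dims
  } else if (class_id == 2) {                    # struct
    len_el <- mat5_element(cur, endian)
    fl <- mat5_int(len_el$data, 4L, TRUE, endian)
    names_el <- mat5_element(cur, endian)
    nf <- length(names_el$data) %/% fl
    fields <- vapply(seq_len(nf), function(i) {
      chunk <- names_el$data[((i - 1) * fl + 1):(i * fl)]
      rawToChar(chunk[chunk != as.raw(0)])
    }, character(1))
    n <- prod(dims)
    value <- vector("list", n)
    for (i in seq_len(n)) {
      rec <- setNames(vector("list", nf), fields)
      for (f in seq_len(nf)) {
        sub <- mat5_element(cur, endian)
        rec[[f]] <- mat5_matrix(sub$data, endian)$value
      }
      value[[i]] <- rec
    }
    if (n == 1) value <- value[[1]]
  } else {
    value <- structure(list(), unsupported_class = class_id)
  }
  list(name = name, value = value)
}

#' Read a MAT-file (v5)
#'
#' Reads the variables of a MATLAB level-5 MAT-file into R: numeric
#' arrays (as arrays), character arrays (as strings), cell arrays (as
#' lists) and structs (as named lists; struct arrays as lists of such).
#' Compressed elements are supported. Unsupported variable classes are
#' returned as empty placeholders rather than failing the whole file.
#'
#' @param path Path to the `.mat` file.
#' @return Named list of variables, with the file's 116-byte description
#'   text attached as attribute `header`.
#' @export
read_mat5 <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("MAT file not found: ", path),
          class = "comreach_import_error")
  }
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 128) {
    abort("File too short to be a MAT v5 container.",
          class = "comreach_import_error")
  }
  header <- rawToChar(buf[1:116][buf[1:116] != as.raw(0)])
  endian_mark <- rawToChar(buf[127:128])
  endian <- if (endian_mark == "IM") "little" else if (endian_mark == "MI")
    "big" else abort("Not a MAT v5 file (bad endian marker).",
                     class = "comreach_import_error")
  cur <- mat5_cursor(buf)
  cur$pos <- 129L
  vars <- list()
  while (cur$pos <= length(buf) - 8L) {
    el <- mat5_element(cur, endian)
    if (el$type == mi_types[["compressed"]]) {
      inner <- mat5_cursor(memDecompress(el$data, type = "gzip"))
      el <- mat5_element(inner, endian)
    }
    if (el$type == mi_types[["matrix"]]) {
      m <- mat5_matrix(el$data, endian)
      vars[[m$name]] <- m$value
    }
  }
  attr(vars, "header") <- header
  vars
}

# dims of an imported value, for diagnostics
mat5_dims <- function(v) {
  if (is.array(v)) paste(dim(v), collapse = "x")
  else if (is.list(v)) paste0("list[", length(v), "]")
  else paste0(class(v)[1], "[", length(v), "]")
}

#' Import a deposited subject dataset (MAT container)
#'
#' Optional adapter from a MAT-file of per-subject trial data onto the
#' canonical trial-table schema. The internal layout of such containers
#' is not standardized, so the adapter discovers the layout rather than
#' assuming it: it looks for a struct array (or cell array of structs)
#' with one element per subject whose fields include the schema column
#' names; anything else raises an informative error listing the
#' variables found, so the caller can supply a `mapping` function.
#' Unmapped fields are dropped with a message. The absence of the file
#' never blocks the synthetic pipeline.
#'
#' @param path Path to the `.mat` file.
#' @param mapping Optional `function(vars)` returning a list of
#'   per-subject trial tibbles, for containers the heuristic cannot
#'   interpret.
#' @return A single trial-table tibble with all subjects.
#' @export
import_s1_dataset <- function(path, mapping = NULL) {
  vars <- read_mat5(path)
  if (!is.null(mapping)) {
    subjects <- mapping(vars)
  } else {
    is_subject_list <- function(v) {
      is.list(v) && length(v) >= 1 && !is.null(names(v[[1]])) &&
        any(names(v[[1]]) %in% names(trial_table_columns))
    }
    cand <- purrr::keep(vars, is_subject_list)
    if (length(cand) != 1) {
      listing <- paste(sprintf("  %s: %s", names(vars),
                               vapply(vars, mat5_dims, character(1))),
                       collapse = "\n")
      abort(paste0(
        "Could not recognize the subject layout of this MAT file.\n",
        "Variables found:\n", listing,
        "\nSupply a `mapping` function to import this container."
      ), class = "comreach_import_error")
    }
    subjects <- purrr::imap(cand[[1]], function(rec, i) {
      known <- intersect(names(rec), names(trial_table_columns))
      dropped <- setdiff(names(rec), names(trial_table_columns))
      if (length(dropped) > 0) {
        message("Dropping unmapped field(s): ",
                paste(dropped, collapse = ", "))
      }
      cols <- purrr::map(setNames(known, known), function(f) {
        v <- rec[[f]]
        if (is.array(v)) as.vector(v) else v
      })
      tb <- as_tibble(cols)
      if (!"subject_id" %in% names(tb)) {
        tb$subject_id <- sprintf("S%02d", i)
      }
      tb
    })
  }
  dplyr::bind_rows(subjects)
}
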