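read_tsv_strict <- function(path, col_types) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "lexrsa_error_io")
  }
  x <- suppressWarnings(readr::read_tsv(path, col_types = col_types, progress = FALSE,
    locale = readr::locale(decimal_mark = "."), na = c("", "NA")
  ))
  pr <- readr::problems(x)
  if (nrow(pr)) {
    p1 <- pr[1, ]
    abort(sprintf(
      "Malformed value in %s at line %d, column %d: expected %s, got %s.",
      path, p1$row, p1$col, p1$expected, p1$actual
    ), class = "lexrsa_error_io")
  }
  missing_cols <- setdiff(names(col_types$cols), names(x))
  if (length(missing_cols)) {
    abort(paste0(path, " is missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "lexrsa_error_io"
    )
  }
  x
}

#' Read and write the package's TSV interchange formats
#'
#' All tables travel as UTF-8 tab-separated files with `.` decimals and
#' a header row; malformed headers or cells are rejected with the file
#' and line identified, never silently coerced. Formats:
#'
#' * words: `token  category  freq_pm` (optional `length`);
#' * embeddings: `token  v1 ... vk`;
#' * events (BIDS-style): `onset  duration  trial_type` (optional
#'   `run`), mapped to/from the internal `condition` column;
#' * patterns: `condition  run  v1 ... vK`, one row per condition and run;
#' * RDM: square numeric matrix with a leading `label` column and one
#'   named column per condition (a long `label_i  label_j  value` writer
#'   is also provided).
#'
#' @param path File path.
#' @param words,embeddings,events,x Object to write.
#' @return Readers return validated tibbles ([read_rdm()] an [rdm];
#'   [read_patterns()] a list of per-run condition-by-voxel matrices).
#'   Writers return the path invisibly.
#' @name lexrsa_io
NULL

#' @rdname lexrsa_io
#' @export
read_words <- function(path) {
  x <- read_tsv_strict(path, readr::cols(
    token = readr::col_character(),
    category = readr::col_character(),
    freq_pm = readr::col_double()
  ))
  validate_words(x)
}

#' @rdname lexrsa_io
#' @export
write_words <- function(words, path) {
  readr::write_tsv(validate_words(words), path)
  invisible(path)
}

#' @rdname lexrsa_io
#' @export
read_embeddings <- function(path) {
  x <- read_tsv_strict(path, readr::cols(token = readr::col_character(),
    .default = readr::col_double()
  ))
  validate_embeddings(x)
}

#' @rdname lexrsa_io
#' @export
write_embeddings <- function(embeddings, path) {
  readr::write_tsv(validate_embeddings(embeddings), path)
  invisible(path)
}

#' @rdname lexrsa_io
#' @export
read_events <- function(path) {
  x <- read_tsv_strict(path, readr::cols(
    onset = readr::col_double(),
    duration = readr::col_double(),
    trial_type = readr::col_character()
  ))
  names(x)[names(x) == "trial_type"] <- "condition"
  if ("run" %in% names(x)) x$run <- as.integer(x$run)
  validate_events(x)
}

#' @rdname lexrsa_io
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  out <- events
  names(out)[names(out) == "condition"] <- "trial_type"
  readr::write_tsv(out[, c("onset", "duration", "trial_type", "run")], path)
  invisible(path)
}

#' @rdname lexrsa_io
#' @export
read_patterns <- function(path) {
  x <- read_tsv_strict(path, readr::cols(
    condition = readr::col_character(),
    run = readr::col_integer(),
    .default = readr::col_double()
  ))
  tbl_to_patterns(x)
}

#' @rdname lexrsa_io
#' @param patterns List of per-run condition-by-voxel matrices.
#' @export
write_patterns <- function(patterns, path) {
  readr::write_tsv(patterns_to_tbl(patterns), path)
  invisible(path)
}

#' Convert between pattern matrices and their tidy table form
#'
#' @param patterns List of per-run condition-by-voxel matrices with
#'   condition rownames.
#' @return `patterns_to_tbl()`: a tibble `condition`, `run`, `v1...vK`;
#'   `tbl_to_patterns()`: the list of matrices.
#' @export
patterns_to_tbl <- function(patterns) {
  patterns <- as_run_list(patterns)
  purrr::map_dfr(seq_along(patterns), function(r) {
    m <- patterns[[r]]
    vals <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
    names(vals) <- paste0("v", seq_len(ncol(m)))
    dplyr::bind_cols(
      tibble::tibble(condition = rownames(m), run = r),
      vals
    )
  })
}

#' @rdname patterns_to_tbl
#' @param x Tidy pattern tibble.
#' @export
tbl_to_patterns <- function(x) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(c("condition", "run"), names(x))
  if (length(missing_cols)) {
    abort(paste0("Pattern table is missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "lexrsa_error_schema"
    )
  }
  vox <- setdiff(names(x), c("condition", "run"))
  lapply(sort(unique(x$run)), function(r) {
    xr <- x[x$run == r, ]
    m <- as.matrix(xr[, vox])
    rownames(m) <- xr$condition
    m
  })
}

#' @rdname lexrsa_io
#' @export
read_rdm <- function(path) {
  x <- read_tsv_strict(path, readr::cols(label = readr::col_character(),
    .default = readr::col_double()
  ))
  labs <- x$label
  m <- as.matrix(x[, setdiff(names(x), "label")])
  if (!identical(colnames(m), labs)) {
    abort(paste0(path, ": column labels do not match the `label` column."),
      class = "lexrsa_error_io"
    )
  }
  rdm(m, labs, allow_negative = TRUE)
}

#' @rdname lexrsa_io
#' @export
write_rdm <- function(x, path) {
  stopifnot(is_rdm(x))
  out <- tibble::as_tibble(as.data.frame(unclass(as.matrix(x))), .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(label = rdm_labels(x)), out)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname lexrsa_io
#' @export
write_rdm_long <- function(x, path) {
  stopifnot(is_rdm(x))
  readr::write_tsv(tidy(x), path)
  invisible(path)
}
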