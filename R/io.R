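#' Read and write expression panels as TSV
#'
#' Wide genes-by-samples layout: first column `gene_id`, remaining column
#' names `line:sex:rep` or `line:sex:rep:probe`. Values are log2
#' expression; missing cells are written as `NA` (never silent zeros).
#' Lines starting with `#` are metadata comments. Both Unix and Windows
#' line endings are accepted on read. Values round-trip to at least 12
#' significant digits.
#'
#' @param data Long expression tibble (`gene_id`, `line`, `sex`, `rep`,
#'   optional `probe`, `value`).
#' @param path File path.
#' @param meta Named list written as `# key=value` comment lines.
#' @return `read_expression_tsv()`: the long tibble; writers return
#'   `path` invisibly.
#' @export
write_expression_tsv <- function(data, path, meta = list()) {
  check_expression_data(data)
  has_probe <- "probe" %in% names(data)
  data <- dplyr::mutate(data, sample = paste(
    .data$line, .data$sex, .data$rep,
    sep = ":"
  ))
  if (has_probe) data$sample <- paste(data$sample, data$probe, sep = ":")
  wide <- tidyr::pivot_wider(data, id_cols = "gene_id",
                             names_from = "sample", values_from = "value")
  write_table_with_meta(wide, path, meta)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  wide <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  if (names(wide)[1] != "gene_id") {
    stop("Malformed expression TSV: first column must be `gene_id` (",
         path, ").")
  }
  long <- tidyr::pivot_longer(wide, -"gene_id", names_to = "sample",
                              values_to = "value")
  parts <- strsplit(long$sample, ":", fixed = TRUE)
  nparts <- lengths(parts)
  if (!all(nparts %in% c(3, 4))) {
    bad <- which(nparts < 3 | nparts > 4)[1]
    stop("Malformed sample header '", long$sample[bad],
         "' (expected line:sex:rep[:probe]).")
  }
  long$line <- vapply(parts, `[`, "", 1)
  long$sex <- vapply(parts, `[`, "", 2)
  long$rep <- as.integer(vapply(parts, `[`, "", 3))
  if (any(nparts == 4)) {
    long$probe <- vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_, "")
  }
  long$sample <- NULL
  dplyr::filter(long, !is.na(.data$value))
}

# Shared writer: "# key=value" comment lines, then a TSV body with full
# numeric precision and "NA" as the missing marker.
write_table_with_meta <- function(tbl, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s=%s", nm, as.character(meta[[nm]])), con)
  }
  body <- vapply(tbl, function(col) {
    if (is.numeric(col)) {
      out <- vapply(col, function(v) {
        if (is.na(v)) "NA" else format(v, digits = 15, scientific = NA)
      }, "")
      out
    } else {
      ifelse(is.na(col), "NA", as.character(col))
    }
  }, character(nrow(tbl)))
  if (nrow(tbl) == 1) body <- matrix(body, nrow = 1)
  writeLines(paste(names(tbl), collapse = "\t"), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param tbl Any tibble (gene summaries, trait scores, response tables).
#' @export
write_pipeline_table <- function(tbl, path, meta = list()) {
  write_table_with_meta(tibble::as_tibble(tbl), path, meta)
}

#' @rdname write_expression_tsv
#' @export
read_pipeline_table <- function(path) {
  readr::read_tsv(path, comment = "#", na = "NA", show_col_types = FALSE,
                  progress = FALSE)
}

#' Read and write sexed G matrices as CSV with a JSON sidecar
#'
#' The CSV has `trait:sex` labels in the first column and a mirrored
#' header row; the sidecar `<path>.json` records `is_correlation`, units
#' and provenance (seed, configuration hash). Round-trips to at least 12
#' significant digits.
#'
#' @param g A `sexed_g` object.
#' @param path CSV path.
#' @param units Unit string stored in the sidecar.
#' @param provenance Named list stored in the sidecar.
#' @return `read_sexed_g()`: the `sexed_g`; `write_sexed_g()`: `path`,
#'   invisibly.
#' @export
write_sexed_g <- function(g, path, units = "log2_expression_sq",
                          provenance = list()) {
  stopifnot(inherits(g, "sexed_g"))
  labels <- rownames(g$cov)
  tbl <- tibble::as_tibble(g$cov, .name_repair = "minimal")
  names(tbl) <- labels
  tbl <- dplyr::bind_cols(tibble::tibble(variable = labels), tbl)
  con <- file(path, "w")
  writeLines(paste(names(tbl), collapse = ","), con)
  body <- apply(g$cov, 1, function(r) {
    paste(vapply(r, function(v) format(v, digits = 15, scientific = NA), ""),
          collapse = ",")
  })
  writeLines(paste(labels, body, sep = ","), con)
  close(con)
  jsonlite::write_json(
    list(is_correlation = g$is_correlation, units = units,
         provenance = provenance),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_sexed_g
#' @export
read_sexed_g <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  labels <- raw[[1]]
  mat <- as.matrix(raw[-1])
  rownames(mat) <- labels
  if (!identical(colnames(mat), as.character(labels))) {
    stop("Malformed G CSV: header labels must mirror the first column (",
         path, ").")
  }
  is_corr <- FALSE
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    js <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    is_corr <- isTRUE(js$is_correlation)
  }
  sexed_g_from_labels(mat, labels) |>
    (\(g) {
      g$is_correlation <- is_corr
      validate_sexed_g(g)
      g
    })()
}
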