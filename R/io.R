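#' Read an intensity matrix from TSV/CSV with a sample sheet
#'
#' The matrix file has feature ids in the first column and sample ids in
#' the header; the sample sheet maps sample id to group (and optionally
#' replicate). Empty cells, `NA` and `NaN` become missing values (never
#' zero). Duplicate feature ids and non-numeric cells are rejected with
#' the offending coordinates.
#'
#' @param path matrix file (TSV by default; `sep = ","` for CSV).
#' @param sample_sheet path to the sample-sheet TSV (columns `sample`,
#'   `group`, optionally `replicate`) or an equivalent data frame.
#' @param scale scale of the stored values, `"raw"` or `"log2"`.
#' @param sep field separator.
#' @return An [intensity_matrix()].
#' @export
read_intensity_matrix <- function(path, sample_sheet, scale = "raw",
                                  sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate feature id(s) in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells[cells %in% c("", "NA", "NaN")] <- NA
  values <- suppressWarnings(
    matrix(as.numeric(cells), nrow = nrow(cells),
           dimnames = list(ids, colnames(cells))))
  bad <- which(is.na(values) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric cell(s) in ", path, ": ",
         paste(sprintf("[%s, %s] = '%s'", ids[bad[, 1]],
                       colnames(values)[bad[, 2]],
                       cells[bad][seq_len(nrow(bad))])[
                         seq_len(min(5, nrow(bad)))],
               collapse = ", "), call. = FALSE)
  }
  samples <- if (is.character(sample_sheet)) {
    utils::read.table(sample_sheet, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, comment.char = "#")
  } else sample_sheet
  intensity_matrix(values, samples, scale = scale)
}

#' Write an intensity matrix to TSV
#'
#' Writes the values with feature ids in a `feature_id` first column, and
#' (optionally) the sample sheet alongside. Round-trips with
#' [read_intensity_matrix()].
#'
#' @param im an [intensity_matrix()].
#' @param path output TSV path.
#' @param sample_sheet_path optional path for the sample sheet TSV.
#' @param header optional named character vector written as `# key: value`
#'   comment lines.
#' @return `path`, invisibly.
#' @export
write_intensity_matrix <- function(im, path, sample_sheet_path = NULL,
                                   header = NULL) {
  df <- data.frame(feature_id = rownames(im$values), im$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, header)
  if (!is.null(sample_sheet_path)) {
    write_tsv_with_header(im$samples, sample_sheet_path, header)
  }
  invisible(path)
}

# comment header + TSV body; deterministic (no timestamps)
write_tsv_with_header <- function(df, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  meta <- c(package = paste0("meltshift ",
                             as.character(utils::packageVersion("meltshift"))),
            header)
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated as
#' `set_id <tab> description <tab> member ...`. Duplicate members within a
#' set are collapsed with a warning; a line with fewer than three fields
#' is an error naming the line number.
#'
#' @param path GMT file.
#' @return Named list of unique member vectors with a `descriptions`
#'   attribute (named character vector), class `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); descriptions <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, " in ", path,
           ": fewer than 3 fields", call. = FALSE)
    }
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning("set '", fields[1], "' (line ", i,
              ") has duplicated members; collapsed", call. = FALSE)
      members <- unique(members)
    }
    sets[[fields[1]]] <- members
    descriptions[fields[1]] <- fields[2]
  }
  attr(sets, "descriptions") <- descriptions
  class(sets) <- "gene_set_collection"
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of member vectors (optionally with a
#'   `descriptions` attribute).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(id) {
    d <- if (!is.null(desc) && !is.na(desc[id])) desc[id] else "NA"
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a long-format TPP table
#'
#' Columns `protein_id`, `condition`, `replicate`, `temperature`
#' (degrees C; `temperature_c` accepted), `rel_abundance`.
#'
#' @param path TSV path.
#' @return Data frame in the layout of [simulate_melting_dataset()].
#' @export
read_tpp_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if ("temperature_c" %in% names(df) && !"temperature" %in% names(df)) {
    names(df)[names(df) == "temperature_c"] <- "temperature"
  }
  need <- c("protein_id", "condition", "replicate", "temperature",
            "rel_abundance")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("TPP table ", path, " missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a long-format TPP table
#'
#' @param tpp long-format TPP data frame.
#' @param path output TSV path.
#' @param header optional named character vector of comment metadata.
#' @return `path`, invisibly.
#' @export
write_tpp_table <- function(tpp, path, header = NULL) {
  write_tsv_with_header(tpp, path, header)
}
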