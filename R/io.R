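#' Read and write BED interval files
#'
#' Three-or-more-column BED, 0-based half-open, tab-separated, no header.
#' Records with fewer than 3 fields, non-numeric coordinates, negative
#' starts or `start >= end` are rejected with their line number.
#'
#' @param path File path.
#' @return `read_bed()` returns a tibble `chrom`, `start`, `end` (plus
#'   `name` if a fourth column is present).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such BED file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3) {
      stop("malformed BED line ", i, ": fewer than 3 fields", call. = FALSE)
    }
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s < 0 || s >= e) {
      stop("malformed BED line ", i,
           ": need numeric 0-based half-open coordinates with start < end",
           call. = FALSE)
    }
  }
  out <- tibble::tibble(
    chrom = vapply(fields, `[`, character(1), 1),
    start = vapply(fields, function(f) as.numeric(f[2]), numeric(1)),
    end = vapply(fields, function(f) as.numeric(f[3]), numeric(1))
  )
  if (all(lengths(fields) >= 4)) {
    out$name <- vapply(fields, `[`, character(1), 4)
  }
  out
}

#' @param bed Tibble/data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `name`.
#' @rdname read_bed
#' @export
write_bed <- function(bed, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bed)),
            all(bed$start >= 0), all(bed$start < bed$end))
  cols <- intersect(c("chrom", "start", "end", "name"), names(bed))
  df <- as.data.frame(bed)[, cols, drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write tabular data (TSV/CSV)
#'
#' Thin wrappers preserving column order and round-tripping doubles at full
#' precision. The delimiter follows the file extension (`.csv` vs anything
#' else = tab).
#'
#' @param path File path.
#' @return `read_table_auto()` returns a tibble.
#' @export
read_table_auto <- function(path) {
  if (!file.exists(path)) stop("no such table: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = delim, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  tibble::as_tibble(df)
}

#' @param table Data frame to write.
#' @rdname read_table_auto
#' @export
write_table_auto <- function(table, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- as.data.frame(table)
  for (j in seq_along(out)) {
    # 17 significant digits round-trips every double exactly
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}
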