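# Column names of the GenePix-results-like tab-delimited spot dialect.
GPR_COLUMNS <- c("Block", "Row", "Column", "ID",
                 "F635 Median", "B635 Median",
                 "F532 Median", "B532 Median", "Flags")

new_two_channel_array <- function(array_id, spots) {
  stopifnot(is.data.frame(spots))
  need <- c("block", "row", "column", "probe_id",
            "f_red", "b_red", "f_green", "b_green", "flag")
  missing <- setdiff(need, names(spots))
  if (length(missing))
    stop("spot table missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(spots[, c("block", "row", "column")]))
    stop("duplicated (block, row, column) coordinates in array '",
         array_id, "'", call. = FALSE)
  num <- c("f_red", "b_red", "f_green", "b_green")
  if (any(vapply(spots[num], function(v) any(v < 0, na.rm = TRUE), logical(1))))
    stop("negative intensities in array '", array_id, "'", call. = FALSE)
  structure(list(array_id = array_id, spots = spots),
            class = "two_channel_array")
}

#' @export
print.two_channel_array <- function(x, ...) {
  cat("Two-channel array '", x$array_id, "': ", nrow(x$spots), " spots, ",
      length(unique(x$spots$block)), " print-tip blocks, ",
      sum(x$spots$flag < 0), " flagged\n", sep = "")
  invisible(x)
}

#' Read a spot table in the GenePix-results-like dialect
#'
#' Parses a tab-delimited spot file with a header row carrying the columns
#' `Block`, `Row`, `Column`, `ID`, `F635 Median`, `B635 Median`,
#' `F532 Median`, `B532 Median`, `Flags` (635 nm = Cy5/red = patient
#' channel, 532 nm = Cy3/green = reference channel). Leading metadata lines
#' starting with a double quote are skipped. Rows whose numeric fields do
#' not parse are dropped with a warning naming their file line numbers.
#' Flagged spots (negative `Flags`) are retained in the structure and only
#' excluded later by [compute_ma()].
#'
#' @param path Path to the spot file.
#' @param array_id Array identifier; defaults to the file name without
#'   extension.
#' @return A `two_channel_array` object.
#' @export
read_spot_table <- function(path, array_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines))))
    stop("empty spot file: ", path, call. = FALSE)
  is_comment <- startsWith(lines, "\"")
  header_line <- which(!is_comment & nzchar(trimws(lines)))[1]
  if (is.na(header_line)) stop("empty spot file: ", path, call. = FALSE)

  tab <- read.delim(text = lines[header_line:length(lines)],
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  missing <- setdiff(GPR_COLUMNS, names(tab))
  if (length(missing))
    stop("spot file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab <- tab[, GPR_COLUMNS]

  num_cols <- setdiff(GPR_COLUMNS, "ID")
  parsed <- lapply(tab[num_cols], function(v) suppressWarnings(as.numeric(v)))
  bad <- Reduce(`|`, lapply(parsed, is.na))
  if (any(bad)) {
    warning("dropping ", sum(bad), " malformed row(s) in '", path,
            "' at line(s) ", paste(header_line + which(bad), collapse = ", "),
            call. = FALSE)
  }
  keep <- !bad
  spots <- data.frame(
    block = as.integer(parsed[["Block"]][keep]),
    row = as.integer(parsed[["Row"]][keep]),
    column = as.integer(parsed[["Column"]][keep]),
    probe_id = tab$ID[keep],
    f_red = parsed[["F635 Median"]][keep],
    b_red = parsed[["B635 Median"]][keep],
    f_green = parsed[["F532 Median"]][keep],
    b_green = parsed[["B532 Median"]][keep],
    flag = as.integer(parsed[["Flags"]][keep]),
    stringsAsFactors = FALSE
  )
  if (!nrow(spots)) stop("no parseable spots in ", path, call. = FALSE)
  if (is.null(array_id))
    array_id <- sub("\\.[^.]*$", "", basename(path))
  new_two_channel_array(array_id, spots)
}

#' Write a spot table in the GenePix-results-like dialect
#'
#' Inverse of [read_spot_table()]: writes the tab-delimited spot file with
#' the standard header row.
#'
#' @param array A `two_channel_array` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spot_table <- function(array, path) {
  stopifnot(inherits(array, "two_channel_array"))
  s <- array$spots
  out <- data.frame(s$block, s$row, s$column, s$probe_id,
                    s$f_red, s$b_red, s$f_green, s$b_green, s$flag)
  names(out) <- GPR_COLUMNS
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
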