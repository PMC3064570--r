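## Internal helpers: numeric parsing tolerant of comma decimal separators,
## angle wrapping, and provenance headers for all file writers.

## Parse numbers accepting both "." and "," as decimal separator.
## Published tables in this domain frequently print "-108,36".
parse_num <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  x <- gsub("−", "-", x)          # unicode minus
  has_comma <- grepl(",", x, fixed = TRUE)
  x[has_comma] <- gsub(",", ".", x[has_comma], fixed = TRUE)
  out <- suppressWarnings(as.numeric(x))
  out
}

## Wrap angles (degrees) onto (-180, 180].
wrap_angle <- function(theta) {
  out <- theta - 360 * floor((theta + 180) / 360)
  out[out <= -180] <- out[out <= -180] + 360
  out
}

## Format a number with a configurable decimal separator for reports.
fmt_num <- function(x, digits = 2, dec = ".") {
  s <- formatC(x, format = "f", digits = digits)
  if (dec != ".") s <- gsub(".", dec, s, fixed = TRUE)
  s
}

## Provenance comment block prepended to every TSV the package writes.
provenance_header <- function(seed = NULL, extra = character()) {
  ver <- tryCatch(as.character(utils::packageVersion("endstate")),
                  error = function(e) "dev")
  lines <- c(sprintf("# endstate %s", ver))
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %d", as.integer(seed)))
  if (length(extra)) lines <- c(lines, paste0("# ", extra))
  lines
}

## Write a data.frame as TSV with a "#" provenance block.
write_tsv_report <- function(df, path, seed = NULL, extra = character(),
                             dec = ".") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, extra), con)
  if (dec != ".") {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) gsub(".", dec, format(x, trim = TRUE),
                                                fixed = TRUE))
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Read a TSV written with a leading "#" comment block.
read_tsv_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
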