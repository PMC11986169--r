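# Shared internal helpers: error signalling, seeded RNG scopes, TSV dialect.

# Input/usage errors get a dedicated condition class so the CLI can map them
# to exit code 1 (internal errors exit 2).
pp_stop_input <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("proteopick_input_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write a table in the package's TSV dialect
#'
#' UTF-8, tab-delimited, header row, `.` decimal separator. Optional `#`
#' comment lines (e.g. seed provenance) precede the header and are skipped by
#' [read_tsv()].
#'
#' @param x A data.frame.
#' @param path Output file path.
#' @param comments Character vector written as leading `# ` lines.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, comments = character()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con, sep = "\n")
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a table written by [write_tsv()]
#'
#' @param path File path.
#' @return A `data.table`.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) pp_stop_input(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) pp_stop_input(sprintf("empty table: %s", path))
  data.table::fread(text = lines, sep = "\t", header = TRUE,
                    na.strings = "", colClasses = NULL)
}

# Deterministic column check with a readable error.
require_columns <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing))
    pp_stop_input(sprintf("%s is missing column(s): %s", what,
                          paste(missing, collapse = ", ")))
  invisible(TRUE)
}
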