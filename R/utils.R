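# Small shared helpers: seeded evaluation, JSONL/TSV io.

# Evaluates expr under a temporary RNG state so callers' streams are not
# disturbed; all generator determinism flows through this.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Write records as JSON Lines
#'
#' @param records A list of records (each serialized as one JSON object) or
#'   a data.frame (one object per row).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeJsonl <- function(records, path) {
  if (is.data.frame(records)) {
    records <- lapply(seq_len(nrow(records)), function(i) as.list(records[i, ]))
  }
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read JSON Lines
#'
#' @param path Input file path.
#' @return List of records.
#' @export
readJsonl <- function(path) {
  lapply(readLines(path, warn = FALSE), jsonlite::fromJSON,
         simplifyVector = TRUE)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

.readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "", fileEncoding = "UTF-8")
}
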