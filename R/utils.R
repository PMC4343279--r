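# Internal helpers shared across modules.

## Deterministic C-locale ordering for data frames; radix sorting keeps the
## row order independent of the session locale.
.orderBy <- function(df, cols) {
  stopifnot(all(cols %in% names(df)))
  do.call(order, c(unname(df[cols]), list(method = "radix")))
}

## Run `expr` under a fixed RNG seed and restore the caller's RNG state,
## so generators are pure functions of their seed.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.splitBar <- function(x) {
  out <- strsplit(ifelse(is.na(x) | x == "", NA_character_, x), "|", fixed = TRUE)
  lapply(out, function(v) if (length(v) == 1L && is.na(v)) character(0) else v)
}

.joinBar <- function(x) {
  vapply(x, function(v) paste(v, collapse = "|"), character(1))
}

## %.17g survives a write/parse/write cycle byte-identically for doubles.
.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.writeTsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  cells <- lapply(df, function(col) {
    if (is.double(col)) .fmtNum(col) else as.character(col)
  })
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(cells, sep = "\t")))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

.readTsv <- function(path, colClasses = NA) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, colClasses = colClasses,
                    check.names = FALSE, na.strings = "NA")
}
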