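# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    .stopf("'%s' must be a non-empty string", name)
}

# read a TSV (plain or gzip; read.table autodetects compression from the
# connection) preserving row order and exact header names
.read_tsv <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "", na.strings = c("NA", ""))
}

.write_tsv <- function(x, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

# run code with a temporarily seeded RNG, restoring the caller's stream
.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    .stopf("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.size_group <- function(n) {
  stopifnot(all(n >= 2))
  ifelse(n >= 5, "5plus", as.character(n))
}

.size_group_levels <- c("2", "3", "4", "5plus")
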