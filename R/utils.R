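# Shared internal helpers: classed conditions, delimited I/O, seeded evaluation.

stop_rorscan <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("rorscan_", class), "rorscan_error")))
}

warn_rorscan <- function(msg, class = "warning") {
  warning(warningCondition(msg, class = c(paste0("rorscan_", class), "rorscan_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Delimiter auto-detection between tab and comma: a header containing a tab is
# taken as TSV, otherwise CSV.
detect_delim <- function(path) {
  if (!file.exists(path)) {
    stop_rorscan(sprintf("input file not found: %s", path), "config_error")
  }
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

read_delim_auto <- function(path) {
  sep <- detect_delim(path)
  utils::read.table(path,
    sep = sep, header = TRUE, stringsAsFactors = FALSE,
    check.names = FALSE, quote = "\"", comment.char = "",
    na.strings = c("NA", "")
  )
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_rorscan(
      sprintf(
        "%s is missing required column%s: %s", what,
        if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
      ),
      "config_error"
    )
  }
  invisible(df)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
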