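## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Classed validation error so callers (and the CLI wrapper) can distinguish
## bad input from runtime failure.
stop_validation <- function(fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(errorCondition(msg,
                      class = c("enamelmap_validation_error", "validationError")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

## Deterministic sub-stream seeds: one shared global seed, per-entity streams
## derived so that adding entities never reshuffles existing ones.  Kept below
## 2^31 - 1 because R seeds are 32-bit integers.
derive_seed <- function(seed, index, salt = 0) {
  ((seed %% 1e6) * 1009 + index * 131 + salt * 7919) %% 2147483647
}

## Evaluate `code` under `seed` and restore the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

tool_header <- function(seed = NULL) {
  v <- as.character(utils::packageVersion("enamelmap"))
  if (is.null(seed)) sprintf("# enamelmap %s", v)
  else sprintf("# enamelmap %s; seed=%s", v, format(seed, scientific = FALSE))
}

## TSV writer used for every tabular artifact: leading '#' header comment
## (tool version + seed), full-precision doubles so round-trips are lossless.
write_tsv <- function(df, path, seed = NULL, extra_header = character(0)) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(df[[j]]), NA, sprintf("%.17g", df[[j]]))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(tool_header(seed), extra_header), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop_validation("input file not found: %s", path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
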