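#' @keywords internal
"_PACKAGE"

#' @useDynLib txpod, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aggregate density dnbinom lm.fit median nlminb optimize
#'   pchisq qchisq quantile rlnorm rnbinom runif rnorm sd setNames uniroot var
#' @importFrom utils read.delim write.table
NULL

# fail-loud condition helpers: every user-facing error carries a class so
# callers (and tests) can distinguish schema, design and data problems
txpod_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "txpod_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

schema_error <- function(msg, ...) txpod_error("txpod_schema_error", msg, ...)
design_error <- function(msg, ...) txpod_error("txpod_design_error", msg, ...)
data_error   <- function(msg, ...) txpod_error("txpod_data_error", msg, ...)
config_error <- function(msg, ...) txpod_error("txpod_config_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# tab vs comma auto-detection on the header line; headers are mandatory and
# contain neither delimiter inside a field, so a straight count is safe
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) schema_error(sprintf("'%s' is empty", path))
  if (lengths(regmatches(header, gregexpr("\t", header))) >=
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

read_table_auto <- function(path, ...) {
  read.delim(path, sep = detect_delim(path), check.names = FALSE,
             stringsAsFactors = FALSE, ...)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    schema_error(sprintf("%s is missing required column(s): %s",
                         what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# derive a per-stream child seed from a scalar seed and a label, kept below
# 2^31 so it is a valid R integer seed
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * (31L ^ (seq_along(
    utf8ToInt(as.character(label))) %% 8L)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629) + 1L
}
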