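# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

ps_abort <- function(msg, class = "pansynt_error", ...) {
  stop(structure(
    class = c(class, "pansynt_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

ps_validation_error <- function(msg, ...) {
  ps_abort(msg, class = "pansynt_validation_error", ...)
}

ps_log <- function(..., level = "info") {
  message(sprintf("[pansynt %s] %s", level, paste0(...)))
}

# Semicolon-joined set columns used by the gene table serialization.
join_set <- function(x) {
  if (length(x) == 0L) return("")
  paste(sort(unique(as.character(x))), collapse = ";")
}

split_set <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

stopifnot_scalar_string <- function(x, what) {
  if (!(is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)))
    ps_validation_error(sprintf("%s must be a non-empty string", what))
}
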