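`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic per-repetition seed from a root seed
#'
#' Monte-Carlo routines in this package consume one root seed and hash a
#' substream seed for each repetition (or each simulated unit). Repetition
#' `i` therefore always sees the same random draws regardless of the total
#' number of repetitions requested, so extending a run does not reshuffle
#' earlier draws.
#'
#' @param root integer root seed (any value representable below 2^31).
#' @param i repetition index (non-negative integer).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(root, i) {
  p <- 2147483647 # 2^31 - 1, all arithmetic exact in doubles
  s <- as.double(root) %% p
  s <- (s * 48271 + as.double(i)) %% p
  s <- (s * 48271 + 1) %% p
  s <- (s * 69621 + 12345) %% p
  as.integer(s)
}

# stop() with a message that cites the offending input rows
abort_rows <- function(msg, rows) {
  rows <- unique(rows)
  shown <- paste(utils::head(rows, 10), collapse = ", ")
  if (length(rows) > 10) shown <- paste0(shown, ", ...")
  stop(sprintf("%s (row%s %s)", msg, if (length(rows) > 1) "s" else "", shown),
       call. = FALSE)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
}

# FNV-1a hash of a string, returned as 8 hex digits; used to fingerprint
# run configurations in output manifests without a hashing dependency.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
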