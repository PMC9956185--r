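#' Derive a reproducible integer seed from a key
#'
#' Hashes a global seed together with any number of string components
#' (for example a pair of sample ids) into a positive 32-bit integer.
#' Used to give every independent unit of work (a sample pair, a
#' simulation substream, an NMDS restart) its own RNG stream, so results
#' do not depend on execution order.
#'
#' @param ... seed components; coerced to character and concatenated.
#' @return A positive integer below 2^31 - 1.
#' @export
derive_seed <- function(...) {
  key <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                      character(1)), collapse = "\x1f")
  h <- 17
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483629
  as.integer(max(h, 1))
}

# Evaluate code with a temporary RNG seed, restoring prior RNG state.
local_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Largest-remainder rounding of proportions p to integer counts summing
# to `total`.  Used to reconstitute counts from a relative table.
largest_remainder <- function(p, total) {
  stopifnot(all(p >= 0), sum(p) > 0, total >= 0)
  raw <- p / sum(p) * total
  fl <- floor(raw)
  rem <- as.integer(round(total - sum(fl)))
  if (rem > 0) {
    idx <- order(raw - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}

# Full-precision numeric formatting for lossless TSV round trips.
format_full <- function(x) {
  if (is.integer(x) || all(x == round(x) & abs(x) < 2^53, na.rm = TRUE)) {
    format(x, scientific = FALSE, trim = TRUE)
  } else {
    sprintf("%.17g", x)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
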