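# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one integer master seed. Each
#' generated table (counts, miRNA records, hit tables, bootstrap draws, ...)
#' seeds its own stream from the master seed plus a stream label, so that a
#' table can be regenerated on its own without replaying every earlier draw.
#'
#' @param seed integer master seed.
#' @param label character stream label.
#' @return An integer seed in `[0, 2^31 - 2]`, deterministic in `(seed, label)`.
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, keeps derived seeds valid 32-bit integers
  h <- as.double(seed) %% m
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% m
  as.integer(h)
}

# Stable 32-bit content hash (polynomial, hex-encoded) used to stamp outputs
# with the configuration they came from.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  m <- 2147483647
  h <- 17
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% m
  sprintf("%08x", as.integer(h))
}

# Validate a counts matrix: non-negative integers, unique dimnames.
check_counts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry feature and sample identifiers")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("duplicate feature or sample identifiers")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  invisible(counts)
}

# Column sums as library sizes, refusing all-zero libraries.
library_sizes <- function(counts, allow_zero = FALSE) {
  ls <- colSums(counts)
  if (!allow_zero && any(ls <= 0)) stop("all-zero library encountered")
  ls
}
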