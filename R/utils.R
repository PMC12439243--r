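# Internal helpers shared across modules.

#' @noRd
abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# A NULL seed leaves the RNG stream untouched.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  abort_if(!is.numeric(seed) || length(seed) != 1 || !is.finite(seed),
           "`seed` must be a single finite number")
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize a RNG state so we can restore it
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Frequency-domain index shuffles. After fftshift the zero-frequency bin sits
# at index floor(n/2) + 1 for both parities of n.
#' @noRd
fftshift_vec <- function(x) {
  n <- length(x)
  x[c((ceiling(n / 2) + 1):n, 1:ceiling(n / 2))]
}

#' @noRd
ifftshift_vec <- function(x) {
  n <- length(x)
  x[c((floor(n / 2) + 1):n, 1:floor(n / 2))]
}

# Derive a per-record 31-bit seed from a master seed and a record index, so
# outputs are independent of batching. Splitmix-style integer mix done in
# double precision (exact below 2^53).
#' @noRd
derive_seed <- function(master, index) {
  x <- (as.numeric(master) * 2654435761 + as.numeric(index) * 40503 + 12345)
  x <- x %% 2147483647
  as.integer(x)
}

# Tiny FNV-1a hash of a character scalar, for config fingerprints in manifests.
#' @noRd
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648 - (h %% 2147483648 > 2147483647)),
                 b)
    h <- (as.numeric(h %% 4294967296) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

# Lossless text encoding of numeric/complex vectors: raw IEEE-754 doubles,
# base64. Complex vectors are interleaved (re, im, re, im, ...).
#' @noRd
encode_doubles <- function(x) {
  x <- as.vector(x)
  if (is.complex(x)) x <- as.vector(rbind(Re(x), Im(x)))
  jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8,
                                endian = "little"))
}

#' @noRd
decode_doubles <- function(s, complex = FALSE) {
  x <- readBin(jsonlite::base64_dec(s), what = "double",
               n = length(jsonlite::base64_dec(s)) / 8, size = 8,
               endian = "little")
  if (complex) {
    idx <- seq(1, length(x), by = 2)
    x <- complex(real = x[idx], imaginary = x[idx + 1])
  }
  x
}
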