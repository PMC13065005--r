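#' @keywords internal
"_PACKAGE"

stop_aspectrx <- function(msg, class) {
  stop(structure(
    class = c(class, "aspectrx_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' FNV-1a 32-bit hash of a character string
#'
#' Pure-R Fowler/Noll/Vo hash used for config fingerprints and lexicon
#' hashes. Returns an 8-character lowercase hex string. Not cryptographic;
#' collisions are acceptable for fingerprinting run configurations.
#'
#' @param x a character scalar (vectors are collapsed with `"\n"`)
#' @return character scalar, 8 hex digits
#' @export
#' @examples
#' fnv1a32("abc")
fnv1a32 <- function(x) {
  x <- paste(x, collapse = "\n")
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    # h * 16777619 mod 2^32, in double arithmetic split to stay exact
    lo <- (h %% 65536) * 16777619
    hi <- ((h %/% 65536) * 16777619) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# XOR for a double holding a 32-bit unsigned value against a byte (b < 256):
# only the low 8 bits change, so XOR them as integers and reassemble.
bitwXor_dbl <- function(h, b) {
  low8 <- h %% 256
  h - low8 + bitwXor(as.integer(low8), as.integer(b))
}

# Evaluate fn with a temporary RNG state derived from `seed`, restoring the
# caller's .Random.seed afterwards (so fixture embedders are side-effect free).
with_local_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

# Deterministic 31-bit integer hash of a string (for seeding per-token RNG)
string_seed <- function(x, salt = 0L) {
  bytes <- utf8ToInt(enc2utf8(tolower(x)))
  h <- (as.double(salt) %% 2147483647) + 7
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ext_file <- function(...) {
  system.file("extdata", ..., package = "aspectrx", mustWork = TRUE)
}
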