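#' @keywords internal
"_PACKAGE"

#' @importFrom stats dnorm pt rnorm rpois sd var coef resid
#' @importFrom utils read.csv write.csv
NULL

# --- validation helpers -----------------------------------------------------

stop_if <- function(cond, ..., call. = FALSE) {
  if (cond) stop(..., call. = call.)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
          sprintf("'%s' must be a single finite number", name))
  stop_if(x < lower || x > upper,
          sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x))
  if (integer) stop_if(x != round(x), sprintf("'%s' must be an integer", name))
  invisible(x)
}

check_image <- function(x, name = "image") {
  stop_if(!is.matrix(x) || !is.numeric(x),
          sprintf("'%s' must be a numeric matrix", name))
  stop_if(any(!is.finite(x)), sprintf("'%s' contains non-finite values", name))
  invisible(x)
}

match_condition <- function(condition) {
  match.arg(condition, c("minusRAP", "plusRAP"))
}

# --- deterministic seeding --------------------------------------------------

#' Derive a reproducible 32-bit seed from a master seed and labels
#'
#' Mixes a master seed with an arbitrary set of labels (strain, condition,
#' field index, ...) through a polynomial rolling hash modulo 2^31 - 1, so
#' that each simulated field draws from its own reproducible RNG stream and
#' any subset of a screen can be regenerated without regenerating the rest.
#'
#' @param master_seed integer master seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "Sec5", "plusRAP", 3)
derive_seed <- function(master_seed, ...) {
  check_scalar(master_seed, "master_seed", integer = TRUE)
  m <- 2147483647 # 2^31 - 1, prime; products stay exact in doubles
  h <- (abs(master_seed) + 1) %% m
  key <- paste(vapply(list(...), as.character, ""), collapse = "\r")
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% m
  as.integer(h %% (m - 2L) + 1L)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# --- padding and small image helpers ---------------------------------------

# Reflective (mirror, without repeating the edge pixel when possible) index
# vector for padding a dimension of size n by r on both sides.
reflect_index <- function(n, r) {
  idx <- seq.int(1L - r, n + r)
  # reflect around the edges until all indices are in range
  while (any(idx < 1L | idx > n)) {
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    if (n == 1L) idx[] <- 1L
  }
  idx
}

pad_reflect <- function(x, r) {
  x[reflect_index(nrow(x), r), reflect_index(ncol(x), r), drop = FALSE]
}

pad_const <- function(x, r, value) {
  out <- matrix(value, nrow(x) + 2L * r, ncol(x) + 2L * r)
  out[(r + 1L):(r + nrow(x)), (r + 1L):(r + ncol(x))] <- x
  out
}

# Offsets (dr, dc) of a disk of the given radius (squared Euclidean metric).
disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

#' @importFrom Rcpp sourceCpp
#' @useDynLib pictscreen, .registration = TRUE
NULL
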