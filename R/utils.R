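#' @keywords internal
"_PACKAGE"

# Numerical helpers shared across modules. All randomness in the package
# flows through withr::with_seed() so that a (config, seed) pair fully
# determines every output.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Row-wise softmax with max-subtraction overflow guard
#' @param x numeric matrix
#' @return matrix of the same shape; every row sums to 1
#' @keywords internal
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

softmax_vec <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

log_softmax_vec <- function(x) {
  x <- x - max(x)
  x - log(sum(exp(x)))
}

#' Xavier (Glorot) uniform initialization
#' @param nrow,ncol matrix dimensions
#' @return nrow x ncol matrix with entries uniform on +/- sqrt(6/(nrow+ncol))
#' @keywords internal
xavier_init <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow = nrow, ncol = ncol)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop_invalid("`%s` must be an integer >= %d (got %s)", name, min,
                 paste(format(x), collapse = ","))
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_invalid("`%s` must be a real number in [0, 1]", name)
  }
  as.numeric(x)
}

# Derive a stream-specific 32-bit seed from a base seed; keeps derived seeds
# well below 2^31 and decorrelated across named streams.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 17) %% 2147483629)
}

# Flatten a nested list of numeric arrays into one numeric vector (and back).
flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

param_sizes <- function(params) {
  vapply(params, length, integer(1))
}

zero_like <- function(params) {
  lapply(params, function(p) {
    z <- p
    z[] <- 0
    z
  })
}

add_grads <- function(a, b, scale = 1) {
  for (nm in names(b)) {
    if (is.null(a[[nm]])) a[[nm]] <- b[[nm]] * scale else a[[nm]] <- a[[nm]] + b[[nm]] * scale
  }
  a
}
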