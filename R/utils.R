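# internal helpers shared across modules

# Structured error so tests can match on condition class.
cf_stop <- function(class, ..., call. = FALSE) {
  msg <- paste0(...)
  cond <- structure(
    class = c(class, "confens_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

# Evaluate `code` under a fixed RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    cf_stop("confens_validation_error", "seed must be a single number")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap angles (degrees) into (-180, 180].
wrap180 <- function(x) x - 360 * ceiling((x - 180) / 360)

# Smallest absolute circular distance between two angles in degrees.
circ_dist <- function(a, b) abs(wrap180(a - b))

# Uniform random proper rotation (QR of a Gaussian matrix, det fixed to +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  # make decomposition unique / uniform, then enforce det +1
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

vnorm <- function(v) sqrt(sum(v * v))

# FNV-1a 32-bit hash of a string; used to stamp outputs with a config hash.
# Arithmetic kept in doubles split into 16-bit halves so every intermediate
# stays exactly representable.
fnv1a32 <- function(s) {
  h <- 2166136261
  m <- 16777619
  for (b in utf8ToInt(s)) {
    lo <- h %% 65536
    hi <- h %/% 65536
    lo <- bitwXor(as.integer(lo), as.integer(b))
    h <- (lo * m + ((hi * m) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
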