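# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "alaradose")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}

# Log-log interpolation inside the table range; errors outside.
# x must be strictly ascending and positive; y positive.
loglog_interp <- function(x, y, xout, what = "table") {
  if (any(xout < x[1] - 1e-12) || any(xout > x[length(x)] + 1e-12)) {
    bad <- xout[xout < x[1] - 1e-12 | xout > x[length(x)] + 1e-12]
    stop(sprintf("energy %.6g MeV outside %s range [%.4g, %.4g]",
                 bad[1], what, x[1], x[length(x)]))
  }
  xout <- pmin(pmax(xout, x[1]), x[length(x)])
  exp(stats::approx(log(x), log(y), xout = log(xout), ties = "ordered")$y)
}

# Linear interpolation in log(energy), clamped at the table ends. Used for
# build-up coefficients where extrapolation should saturate, not explode.
loglin_interp_clamped <- function(x, y, xout) {
  xout <- pmin(pmax(xout, x[1]), x[length(x)])
  stats::approx(log(x), y, xout = log(xout), rule = 2, ties = "ordered")$y
}

# FNV-1a 32-bit hash over a character scalar, in double arithmetic
# (all intermediates < 2^53, so exact). Used for fixture checksums and
# position-keyed per-node seeds.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                      # xor only touches the low byte
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  h
}

# Evaluate code with a private, restorable RNG stream seeded from `seed`.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2^31))
  force(code)
}

# 2-significant-figure display used in dose tables; full precision is kept
# internally everywhere.
signif2 <- function(x) signif(x, 2)

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a finite numeric scalar")
  if (positive && x <= 0) stop(name, " must be > 0")
  if (nonneg && x < 0) stop(name, " must be >= 0")
  invisible(x)
}
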