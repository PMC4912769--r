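# Small internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed, staying inside the 32-bit range.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 9973) %% 2147483563) + 1L
}

# Signed shoelace area of a polygon given as a two-column matrix.
shoelace_area <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Convex hull area of a 2-column point matrix (0 for degenerate sets).
convex_hull_area <- function(xy) {
  xy <- xy[complete.cases(xy), , drop = FALSE]
  if (nrow(xy) < 3) return(0)
  h <- grDevices::chull(xy)
  if (length(h) < 3) return(0)
  shoelace_area(xy[h, , drop = FALSE])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
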