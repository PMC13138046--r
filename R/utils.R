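# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Shifted copy of a matrix: out[r, c] = m[r + dr, c + dc], zero outside.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0, nr, nc)
  r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
  if (r1 <= r2 && c1 <= c2) {
    out[r1:r2, c1:c2] <- m[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
  }
  out
}

# Discrete Fourier frequencies in cycles per sample for length n.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

stop_fk <- function(stage, ...) {
  msg <- paste0(...)
  cond <- structure(
    class = c("fibrilkit_error", "error", "condition"),
    list(message = sprintf("[%s] %s", stage, msg), call = sys.call(-1),
         stage = stage)
  )
  stop(cond)
}

check_that <- function(ok, stage, ...) {
  if (!isTRUE(ok)) stop_fk(stage, ...)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
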