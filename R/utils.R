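#' @keywords internal
"_PACKAGE"

# Input validation helpers. All user-facing errors name the offending
# argument so configuration mistakes are traceable.

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

assert_scalar_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_config(field, "must be a single positive finite number")
  invisible(x)
}

assert_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_config(field, "must be TRUE or FALSE")
  invisible(x)
}

# Shift a matrix by (di, dj), zero-filling vacated cells. Used by the
# image-morphology code (neighbor counts, boundary detection, thinning).
shift_mat <- function(m, di, dj, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- seq_len(nr); rj <- seq_len(nc)
  si <- ri - di; sj <- rj - dj
  ok_i <- si >= 1L & si <= nr
  ok_j <- sj >= 1L & sj <= nc
  out[ri[ok_i], rj[ok_j]] <- m[si[ok_i], sj[ok_j]]
  out
}

# The 8-neighborhood offsets (row, col), row-major order.
offsets8 <- cbind(
  di = c(-1, -1, -1, 0, 0, 1, 1, 1),
  dj = c(-1, 0, 1, -1, 1, -1, 0, 1)
)
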