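# internal helpers shared across modules

# run `expr` under a fixed seed without clobbering the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_dim3 <- function(x, name) {
  if (is.null(dim(x)) || length(dim(x)) != 3L)
    stopf("'%s' must be a 3D array", name)
}

# trilinear interpolation of a 3D field at 0-based voxel coordinates p (n x 3)
interp_trilinear <- function(field, p) {
  d <- dim(field)
  if (nrow(p) == 0L) return(numeric(0))
  f0 <- floor(p)
  w <- p - f0
  # clamp upper corner for points exactly on the last voxel plane
  f1 <- sweep(f0 + 1, 2, d - 1, pmin)
  f0 <- sweep(f0, 2, d - 1, pmin)
  gather <- function(ix, iy, iz) {
    field[cbind(ix + 1, iy + 1, iz + 1)]
  }
  (1 - w[, 1]) * (1 - w[, 2]) * (1 - w[, 3]) * gather(f0[, 1], f0[, 2], f0[, 3]) +
    w[, 1] * (1 - w[, 2]) * (1 - w[, 3]) * gather(f1[, 1], f0[, 2], f0[, 3]) +
    (1 - w[, 1]) * w[, 2] * (1 - w[, 3]) * gather(f0[, 1], f1[, 2], f0[, 3]) +
    (1 - w[, 1]) * (1 - w[, 2]) * w[, 3] * gather(f0[, 1], f0[, 2], f1[, 3]) +
    w[, 1] * w[, 2] * (1 - w[, 3]) * gather(f1[, 1], f1[, 2], f0[, 3]) +
    w[, 1] * (1 - w[, 2]) * w[, 3] * gather(f1[, 1], f0[, 2], f1[, 3]) +
    (1 - w[, 1]) * w[, 2] * w[, 3] * gather(f0[, 1], f1[, 2], f1[, 3]) +
    w[, 1] * w[, 2] * w[, 3] * gather(f1[, 1], f1[, 2], f1[, 3])
}
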