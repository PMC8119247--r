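# round half away from zero is not wanted here: display levels are always
# non-negative, so floor(x + 0.5) is exactly round-half-up
round_half_up <- function(x) floor(x + 0.5)

# Shift a logical 3D array by one voxel along `axis` in direction `dir`
# (+1 or -1), padding with FALSE. Used by the vectorised flood fill.
shift3 <- function(a, axis, dir) {
  d <- dim(a)
  out <- array(FALSE, d)
  n <- d[axis]
  src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  dst <- src
  if (dir > 0) {
    src[[axis]] <- seq_len(n - 1L)
    dst[[axis]] <- 2:n
  } else {
    src[[axis]] <- 2:n
    dst[[axis]] <- seq_len(n - 1L)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Union of the 6 face neighbours of all TRUE voxels.
neighbours_face <- function(a) {
  shift3(a, 1, 1) | shift3(a, 1, -1) |
    shift3(a, 2, 1) | shift3(a, 2, -1) |
    shift3(a, 3, 1) | shift3(a, 3, -1)
}

# Union of the 26 box neighbours: sequential dilation along each axis
# (including the zero offset) yields the full 3x3x3 neighbourhood.
neighbours_box <- function(a) {
  d1 <- a | shift3(a, 1, 1) | shift3(a, 1, -1)
  d2 <- d1 | shift3(d1, 2, 1) | shift3(d1, 2, -1)
  d2 | shift3(d2, 3, 1) | shift3(d2, 3, -1)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_fixed_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
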