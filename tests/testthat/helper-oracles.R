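# Independent brute-force oracles. These deliberately share no code with
# the package: the flood fill is an explicit stack-based search over voxel
# triples, the projections are per-ray loops, and the windowing is scalar
# arithmetic.

oracle_flood_fill <- function(vox, seeds, threshold, connectivity = "face") {
  d <- dim(vox)
  offs <- if (connectivity == "face") {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
          c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    o[rowSums(abs(o)) > 0, , drop = FALSE]
  }
  mask <- array(FALSE, d)
  stack <- vector("list", 0)
  for (r in seq_len(nrow(seeds))) {
    s <- as.integer(seeds[r, ])
    if (vox[s[1], s[2], s[3]] <= threshold && !mask[s[1], s[2], s[3]]) {
      mask[s[1], s[2], s[3]] <- TRUE
      stack[[length(stack) + 1L]] <- s
    }
  }
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (o in seq_len(nrow(offs))) {
      p <- cur + offs[o, ]
      if (all(p >= 1L) && all(p <= d) &&
          !mask[p[1], p[2], p[3]] && vox[p[1], p[2], p[3]] <= threshold) {
        mask[p[1], p[2], p[3]] <- TRUE
        stack[[length(stack) + 1L]] <- p
      }
    }
  }
  mask
}

# per-ray loop projection; fun is max/min/mean; masked voxels are dropped
# for the minIP and empty rays get the +3071 sentinel
oracle_project <- function(vox, view, fun, mask = NULL) {
  d <- dim(vox)
  nz <- d[3]
  ncols <- if (view == "anterior_posterior") d[1] else d[2]
  out <- matrix(NA_real_, nz, ncols)
  for (r in seq_len(nz)) {
    k <- nz - r + 1L
    for (cc in seq_len(ncols)) {
      ray <- if (view == "anterior_posterior") vox[cc, , k] else vox[, cc, k]
      if (!is.null(mask)) {
        keep <- if (view == "anterior_posterior") !mask[cc, , k] else !mask[, cc, k]
        ray <- ray[keep]
      }
      out[r, cc] <- if (!length(ray)) 3071 else fun(ray)
    }
  }
  out
}

oracle_window <- function(hu, center = 500, width = 1000) {
  vapply(hu, function(v) {
    lo <- center - width / 2
    hi <- center + width / 2
    if (v <= lo) return(0)
    if (v >= hi) return(255)
    floor((v - lo) / width * 255 + 0.5)
  }, numeric(1))
}

# 2D footprint of a 3D mask in image coordinates (rows z top-down)
oracle_footprint <- function(mask, view) {
  d <- dim(mask)
  ncols <- if (view == "anterior_posterior") d[1] else d[2]
  out <- matrix(FALSE, d[3], ncols)
  for (r in seq_len(d[3])) {
    k <- d[3] - r + 1L
    for (cc in seq_len(ncols)) {
      ray <- if (view == "anterior_posterior") mask[cc, , k] else mask[, cc, k]
      out[r, cc] <- any(ray)
    }
  }
  out
}

random_hu_volume <- function(dims, seed) {
  set.seed(seed)
  # mixture spanning air to metal so thresholds fall inside the range
  vals <- sample(c(-1000, -800, -300, -200, -150, 0, 40, 1200, 3000),
                 prod(dims), replace = TRUE) +
    round(runif(prod(dims), -20, 20))
  ct_volume(array(vals, dims))
}

is_pure_red <- function(px) px[, , 1] == 255L & px[, , 2] == 0L & px[, , 3] == 0L
is_pure_blue <- function(px) px[, , 1] == 0L & px[, , 2] == 0L & px[, , 3] == 255L
is_gray <- function(px) px[, , 1] == px[, , 2] & px[, , 2] == px[, , 3]
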