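# Brute-force reference implementations, written independently of the
# package's compiled kernels. All use the same boundary convention
# (symmetric reflection, edge sample repeated) and the same watershed
# tie-break so agreement can be exact.

# fold a 1-based index into [1, n] by symmetric reflection
reflect1 <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  k <- (i - 1L) %% (2L * n)
  k[k < 0L] <- k[k < 0L] + 2L * n
  ifelse(k < n, k + 1L, 2L * n - k)
}

oracle_median3d <- function(arr, range = 3) {
  h <- as.integer(floor(range / 2))
  d <- dim(arr)
  out <- arr
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    vals <- numeric(0)
    for (dz in -h:h) for (dy in -h:h) for (dx in -h:h) {
      vals <- c(vals, arr[reflect1(z + dz, d[1]),
                          reflect1(y + dy, d[2]),
                          reflect1(x + dx, d[3])])
    }
    out[z, y, x] <- sort(vals)[(length(vals) + 1) / 2]
  }
  out
}

oracle_local_threshold <- function(arr, range = 10) {
  r <- as.integer(range)
  d <- dim(arr)
  out <- array(FALSE, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    s <- 0
    for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
      s <- s + arr[reflect1(z + dz, d[1]),
                   reflect1(y + dy, d[2]),
                   reflect1(x + dx, d[3])]
    }
    out[z, y, x] <- arr[z, y, x] > s / (2 * r + 1)^3
  }
  out
}

# priority-flood watershed: min-heap on (value, insertion sequence), markers
# enqueued in increasing linear-index order, neighbours visited in
# expand.grid(dz, dy, dx) order (dz varying fastest)
oracle_watershed <- function(x, markers, mask) {
  d <- dim(x)
  labels <- array(0L, d)
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(off != 0) > 0, , drop = FALSE]
  qv <- numeric(0); qs <- integer(0); qi <- integer(0)
  nseq <- 0L
  for (i in which(markers > 0)) {
    stopifnot(mask[i])
    labels[i] <- markers[i]
    qv <- c(qv, x[i]); qs <- c(qs, nseq); qi <- c(qi, i)
    nseq <- nseq + 1L
  }
  while (length(qv) > 0L) {
    k <- order(qv, qs)[1]
    i <- qi[k]
    lab <- labels[i]
    qv <- qv[-k]; qs <- qs[-k]; qi <- qi[-k]
    iz <- ((i - 1L) %% d[1]) + 1L
    iy <- (((i - 1L) %/% d[1]) %% d[2]) + 1L
    ix <- ((i - 1L) %/% (d[1] * d[2])) + 1L
    for (r in seq_len(nrow(off))) {
      jz <- iz + off[r, 1]; jy <- iy + off[r, 2]; jx <- ix + off[r, 3]
      if (jz < 1 || jz > d[1] || jy < 1 || jy > d[2] || jx < 1 || jx > d[3])
        next
      j <- jz + d[1] * ((jy - 1L) + d[2] * (jx - 1L))
      if (mask[j] && labels[j] == 0L) {
        labels[j] <- lab
        qv <- c(qv, x[j]); qs <- c(qs, nseq); qi <- c(qi, j)
        nseq <- nseq + 1L
      }
    }
  }
  labels
}

# grayscale opening of a 2D slice with the non-flat ball element,
# out-of-image samples ignored
oracle_ball_opening2d <- function(slice, radius) {
  ny <- nrow(slice); nx <- ncol(slice)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  offs$b <- sqrt(radius^2 - offs$dy^2 - offs$dx^2)
  ero <- matrix(Inf, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    jy <- y + offs$dy; jx <- x + offs$dx
    ok <- jy >= 1 & jy <= ny & jx >= 1 & jx <= nx
    ero[y, x] <- min(slice[cbind(jy[ok], jx[ok])] - offs$b[ok])
  }
  out <- matrix(-Inf, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    jy <- y + offs$dy; jx <- x + offs$dx
    ok <- jy >= 1 & jy <= ny & jx >= 1 & jx <= nx
    out[y, x] <- max(ero[cbind(jy[ok], jx[ok])] + offs$b[ok])
  }
  out
}

# a random small stack plus markers/mask for watershed oracle runs
random_watershed_case <- function(dims = c(8, 8, 8), n_markers = 2) {
  x <- array(sample(0:9, prod(dims), replace = TRUE), dims)
  mask <- array(runif(prod(dims)) < 0.7, dims)
  free <- which(mask)
  mk <- array(0L, dims)
  picks <- sample(free, min(n_markers, length(free)))
  mk[picks] <- seq_along(picks)
  list(x = x, markers = mk, mask = mask)
}

# construct a label map containing axis-aligned cuboid regions of the
# requested voxel counts (plus a remainder voxel glued 26-adjacent)
label_map_with_volumes <- function(volumes) {
  boxes <- lapply(volumes, function(v) {
    a <- max(1L, as.integer(round(v^(1 / 3))))
    while (v %% a != 0L && a > 1L) a <- a - 1L
    rest <- v %/% a
    b <- max(1L, as.integer(floor(sqrt(rest))))
    while (rest %% b != 0L && b > 1L) b <- b - 1L
    as.integer(c(a, b, rest %/% b, v - a * b * (rest %/% b)))
  })
  nzmax <- max(vapply(boxes, `[`, integer(1), 1)) + 2L
  nymax <- max(vapply(boxes, `[`, integer(1), 2)) + 2L
  widths <- vapply(boxes, `[`, integer(1), 3)
  lab <- array(0L, c(nzmax, nymax, sum(widths) + 2L * length(volumes) + 2L))
  x0 <- 2L
  for (i in seq_along(boxes)) {
    b <- boxes[[i]]
    lab[1:b[1], 1:b[2], x0:(x0 + b[3] - 1L)] <- i
    stopifnot(b[4] == 0L)
    x0 <- x0 + b[3] + 2L
  }
  lab
}
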