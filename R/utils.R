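# Internal 3-D array helpers: separable Gaussian convolution, shift-and-add
# kernel convolution, connected-component labelling.  All operate on plain
# numeric 3-D arrays; geometry is handled by the callers.

#' @keywords internal
#' @noRd
stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Discrete Gaussian taps, normalised to unit sum so that convolution
# conserves total activity exactly.  sigma in voxel units.
gauss_taps <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  w <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  w / sum(w)
}

# Shift-and-add 1-D convolution along one axis of a 3-D array.
# `taps` must have odd length; zero padding (mass leaves the grid at the
# border) or periodic wrap.
convolve_axis <- function(a, taps, axis, periodic = FALSE) {
  nt <- length(taps)
  if (nt == 1L) return(a * taps)
  stopifnot(nt %% 2L == 1L)
  d <- dim(a)
  ord <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, ord)
  n <- d[axis]
  m <- matrix(ap, nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  r <- (nt - 1L) %/% 2L
  for (j in seq_len(nt)) {
    k <- j - r - 1L   # out[i] += taps[j] * m[i - k]
    if (periodic) {
      src <- ((seq_len(n) - k - 1L) %% n) + 1L
      out <- out + taps[j] * m[src, , drop = FALSE]
    } else {
      i1 <- max(1L, 1L + k); i2 <- min(n, n + k)
      if (i1 > i2) next
      out[i1:i2, ] <- out[i1:i2, ] + taps[j] * m[(i1:i2) - k, , drop = FALSE]
    }
  }
  out <- array(out, dim = d[ord])
  aperm(out, order(ord))
}

# Separable 3-D Gaussian blur; sigma per axis in voxel units.
gauss_blur3d <- function(a, sigma_vox, periodic = FALSE) {
  stopifnot(length(sigma_vox) %in% c(1L, 3L))
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (ax in 1:3) a <- convolve_axis(a, gauss_taps(sigma_vox[ax]), ax, periodic)
  a
}

# Full 3-D convolution with an odd-sized kernel by shift-and-add over
# kernel offsets.  Suitable for compact dose kernels.
convolve3d <- function(a, kern, periodic = FALSE) {
  kd <- dim(kern)
  if (is.null(kd) || length(kd) != 3L || any(kd %% 2L == 0L))
    stop("kernel must be a 3-D array with odd extents", call. = FALSE)
  d <- dim(a)
  out <- array(0, dim = d)
  ctr <- (kd + 1L) %/% 2L
  nz <- which(kern != 0)
  if (length(nz) == 0L) return(out)
  offs <- arrayInd(nz, kd) - rep(ctr, each = length(nz))
  idx <- function(n, k) {
    if (periodic) ((seq_len(n) - k - 1L) %% n) + 1L else seq_len(n) - k
  }
  for (q in seq_along(nz)) {
    o <- offs[q, ]
    w <- kern[nz[q]]
    if (periodic) {
      out <- out + w * a[idx(d[1], o[1]), idx(d[2], o[2]), idx(d[3], o[3])]
    } else {
      # destination range for which the source index is in bounds
      dst <- lapply(1:3, function(ax) {
        i1 <- max(1L, 1L + o[ax]); i2 <- min(d[ax], d[ax] + o[ax])
        if (i1 > i2) integer(0) else i1:i2
      })
      if (any(lengths(dst) == 0L)) next
      src <- lapply(1:3, function(ax) dst[[ax]] - o[ax])
      out[dst[[1]], dst[[2]], dst[[3]]] <-
        out[dst[[1]], dst[[2]], dst[[3]]] +
        w * a[src[[1]], src[[2]], src[[3]]]
    }
  }
  out
}

neighbour_offsets <- function(connectivity = 26L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L))
    stop("connectivity must be 6 or 26", call. = FALSE)
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  g
}

# Label connected components of a logical 3-D mask.  Breadth-first flood
# fill with vectorised frontier expansion; returns an integer array with
# 0 = background and components numbered in first-voxel (column-major) order.
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  if (is.null(d) || length(d) != 3L)
    stop("mask must be a 3-D array", call. = FALSE)
  offs <- neighbour_offsets(connectivity)
  lab <- array(0L, dim = d)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  inmask <- array(FALSE, dim = d); inmask[fg] <- TRUE
  strides <- c(1L, d[1], d[1] * d[2])
  next_lab <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    next_lab <- next_lab + 1L
    lab[s] <- next_lab
    frontier <- s
    while (length(frontier) > 0L) {
      co <- arrayInd(frontier, d)
      cand <- integer(0)
      for (q in seq_len(nrow(offs))) {
        nb <- co + rep(offs[q, ], each = nrow(co))
        ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
              nb[, 2] >= 1L & nb[, 2] <= d[2] &
              nb[, 3] >= 1L & nb[, 3] <= d[3]
        if (!any(ok)) next
        nb <- nb[ok, , drop = FALSE]
        lin <- 1L + (nb[, 1] - 1L) + (nb[, 2] - 1L) * strides[2] +
          (nb[, 3] - 1L) * strides[3]
        cand <- c(cand, lin[inmask[lin] & lab[lin] == 0L])
      }
      cand <- unique(cand)
      if (length(cand) > 0L) lab[cand] <- next_lab
      frontier <- cand
    }
  }
  lab
}

# Evaluate a deterministic expression under a local RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
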