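# Shared fixture builders.  Small grids keep the default run fast; the
# full 64^3 clinical matrix is exercised in the acceptance tests.

# single centred sphere on a small grid
sphere_spec <- function(radius_mm = 10, A0 = 1000, lambda = log(2) / 24,
                        grid = c(32L, 32L, 32L), voxel = 1.95,
                        fwhm = 0, noise = "none", sigma = 0.05, seed = 1L,
                        kind = "lesion") {
  centre <- grid * voxel / 2
  phantom_spec(
    list(region_spec("s", kind, center_mm = centre, radii_mm = radius_mm,
                     A0_Bq_per_ml = A0, lambda_per_h = lambda)),
    grid_shape = grid, voxel_size_mm = voxel, psf_fwhm_mm = fwhm,
    noise = noise, sigma_fraction = sigma, seed = seed)
}

# centre-in-sphere voxel mask built independently of the package's
# voxelisation code (the volume oracle)
oracle_sphere_mask <- function(grid, voxel, centre, radius) {
  ax <- lapply(1:3, function(i) (seq_len(grid[i]) - 0.5) * voxel - centre[i])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  r2 <= radius^2
}

# independent connected-components oracle built on igraph
igraph_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  fg <- which(mask)
  if (length(fg) == 0L) return(list(n = 0L, sizes = integer(0)))
  co <- arrayInd(fg, d)
  id_of <- integer(prod(d)); id_of[fg] <- seq_along(fg)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1L, , drop = FALSE]
  edges <- NULL
  for (q in seq_len(nrow(offs))) {
    nb <- co + rep(offs[q, ], each = nrow(co))
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- 1L + (nb[ok, 1] - 1L) + (nb[ok, 2] - 1L) * d[1] +
      (nb[ok, 3] - 1L) * d[1] * d[2]
    tgt <- id_of[lin]
    src <- which(ok)[tgt > 0L]
    if (length(src) > 0L)
      edges <- rbind(edges, cbind(src, tgt[tgt > 0L]))
  }
  g <- igraph::graph_from_edgelist(unique(t(apply(edges, 1, sort))),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)
  list(n = comp$no, sizes = sort(as.integer(comp$csize), decreasing = TRUE))
}
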