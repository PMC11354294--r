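# Shared fixtures, built in code at test time.

# small field for fast segmentation tests: 30 x 30 um, 160 px
smallGeom <- function() FieldGeometry(30, 160L)

noiseFree <- function(background = 0.05) {
  list(background = background, gaussianSD = 0, poisson = FALSE)
}

# two equal disks (area = 4*pi um^2 each) whose centres are `gap` um apart
touchingDisks <- function(gap = 3.5, geom = smallGeom(), noise = noiseFree()) {
  mid <- sideLength(geom) / 2
  cells <- data.frame(cellId = 1:2, x = c(mid - gap / 2, mid + gap / 2),
                      y = c(mid, mid), trueArea = pi * 4, inflamed = FALSE)
  renderMosaic(cells, geom, noise = noise, seed = 1)
}

# jitter-free triangular lattice rendered noise-free at spacing D (um)
latticeImage <- function(D = 5, geom = FieldGeometry(), area = 10,
                         jitter = 0, seed = 1, noise = noiseFree()) {
  density <- 2 / (sqrt(3) * D^2) * 1e6
  pts <- generateHexCenters(density, geom, jitter = jitter, seed = seed)
  cells <- data.frame(cellId = seq_len(nrow(pts)), x = pts[, 1],
                      y = pts[, 2], trueArea = area, inflamed = FALSE)
  renderMosaic(cells, geom, noise = noise, seed = seed)
}

# disjoint sparse mosaic with known per-cell areas (no touching cells)
sparseMosaic <- function(geom = smallGeom(), seed = 1, noise = noiseFree()) {
  side <- sideLength(geom)
  gx <- seq(4, side - 4, by = 6)
  pts <- expand.grid(x = gx, y = gx)
  set.seed(seed)
  areas <- stats::runif(nrow(pts), 7, 13)
  cells <- data.frame(cellId = seq_len(nrow(pts)), x = pts$x, y = pts$y,
                      trueArea = areas, inflamed = FALSE)
  renderMosaic(cells, geom, noise = noise, seed = seed)
}

# nearest-neighbour distances of a point set
nnDistances <- function(pts) {
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  apply(d, 1, min)
}
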