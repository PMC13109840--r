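# Session-cached fixtures: everything is generated in code, deterministic
# under fixed seeds, and shared across test files to keep the suite fast.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtureCache[[name]]))
    assign(name, expr, envir = .fixtureCache)
  .fixtureCache[[name]]
}

fixtureSurface <- function() {
  fixture("surface_lh", makeToySurface(3, seed = 11, hemisphere = "lh"))
}

fixtureParcellation <- function() {
  fixture("parc_lh", makeParcellation(fixtureSurface(), 10, seed = 11))
}

fixtureCortex <- function() {
  fixture("cortex", {
    lh <- makeToySurface(3, seed = 11, "lh")
    rh <- makeToySurface(3, seed = 11, "rh")
    list(surface = mergeHemispheres(lh, rh),
         parcellation = mergeParcellations(
           makeParcellation(lh, 10, seed = 11),
           makeParcellation(rh, 10, seed = 11)))
  })
}

# small aligned phantom scene (48^3 at 4 mm) for preprocessing tests
fixtureScene <- function() {
  fixture("scene_small", simulateVolumeScene(
    simulationConfig(seed = 5, mesh_subdivisions = 2),
    misalign_translation = c(0, 0, 0), grid_dim = 48L, voxel_mm = 4))
}

# independent oracle: Cohen's kappa from expanded label vectors, using
# explicit observed/chance agreement over the 2x2 table
kappaOracle <- function(tp, fp, fn, tn) {
  truth <- rep(c(1, 0, 1, 0), c(tp, fp, fn, tn))
  pred <- rep(c(1, 1, 0, 0), c(tp, fp, fn, tn))
  n <- length(truth)
  po <- mean(truth == pred)
  pe <- 0
  for (v in c(0, 1)) pe <- pe + mean(truth == v) * mean(pred == v)
  if (abs(1 - pe) < 1e-15) return(NA_real_)
  (po - pe) / (1 - pe)
}

# independent oracle: point-in-cylinder test over every voxel centre of a
# grid (no bounding-box shortcut)
cylinderFootprintOracle <- function(contact, volume) {
  d <- dim(volData(volume))
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  world <- cbind(idx, 1) %*% t(volAffine(volume))
  ctr <- c(contact$x, contact$y, contact$z)
  ax <- c(contact$axis_x, contact$axis_y, contact$axis_z)
  ax <- ax / sqrt(sum(ax^2))
  rel <- sweep(world[, 1:3, drop = FALSE], 2, ctr)
  t <- as.numeric(rel %*% ax)
  rad2 <- rowSums(rel^2) - t^2
  inside <- abs(t) <= contact$length / 2 &
    rad2 <= (contact$diameter / 2)^2
  sort((1 + idx[, 1] + d[1] * (idx[, 2] + d[2] * idx[, 3]))[inside])
}
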