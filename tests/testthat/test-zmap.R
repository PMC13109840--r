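test_that("global mean normalization is scale-invariant with unit mask mean", {
  set.seed(2)
  m <- VertexMap(runif(200, 0.5, 1.5))
  n1 <- globalMeanNormalize(m)
  expect_equal(mean(mapValues(n1)), 1.0, tolerance = 1e-12)
  n2 <- globalMeanNormalize(VertexMap(17.3 * mapValues(m)))
  expect_equal(mapValues(n2), mapValues(n1), tolerance = 1e-12)
  msk <- rep(c(TRUE, FALSE), 100)
  nm <- globalMeanNormalize(m, msk)
  expect_equal(mean(mapValues(nm)[msk]), 1.0, tolerance = 1e-12)
  expect_error(globalMeanNormalize(m, rep(FALSE, 200)), "empty")
})

test_that("control templates use the n-1 sample SD and flag degeneracy", {
  controls <- list(rep(1.0, 3), rep(1.1, 3), rep(0.9, 3),
                   rep(1.05, 3), rep(0.95, 3))
  # make vertex 3 identical across controls (degenerate SD)
  controls <- lapply(controls, function(x) { x[3] <- 1; x })
  tmpl <- buildTemplate(controls)
  expect_equal(templateMean(tmpl), c(1.0, 1.0, 1.0))
  expect_equal(templateSD(tmpl)[1], 0.0790569, tolerance = 1e-6)
  expect_true(is.na(templateSD(tmpl)[3]))
  expect_equal(nControls(tmpl), 5L)
  # template mean is the exact vertex-wise average of the inputs
  X <- do.call(cbind, controls)
  expect_equal(templateMean(tmpl), rowMeans(X))
  expect_error(buildTemplate(controls[1]), "at least 2")
})

test_that("Z-scores follow their definition and are equivariant", {
  controls <- lapply(1:10, function(i) c(1, 1.1, 0.9, 1.05, 0.95) + i / 100)
  tmpl <- buildTemplate(controls)
  z0 <- computeZMap(templateMean(tmpl), tmpl)
  expect_equal(mapValues(z0), rep(0, 5))
  # patient at mean - 3 sd scores exactly -3.00
  pat <- templateMean(tmpl) - 3 * templateSD(tmpl)
  expect_equal(mapValues(computeZMap(pat, tmpl)), rep(-3, 5))
  # hand example: controls {1.0,1.1,0.9,1.05,0.95}, patient 0.8
  tmpl2 <- buildTemplate(list(rep(1, 2), rep(1.1, 2), rep(0.9, 2),
                              rep(1.05, 2), rep(0.95, 2)))
  expect_equal(mapValues(computeZMap(rep(0.8, 2), tmpl2)),
               rep(-2.5298, 2), tolerance = 1e-4)
  # adding delta*sd at one vertex raises that z by exactly delta
  pat2 <- pat; pat2[2] <- pat2[2] + 1.75 * templateSD(tmpl)[2]
  expect_equal(mapValues(computeZMap(pat2, tmpl))[2], -3 + 1.75,
               tolerance = 1e-12)
  expect_error(computeZMap(rep(1, 4), tmpl), "does not match")
})

test_that("bottom-fraction selection counts, ties and missing handling are exact", {
  z <- new("ZMap", z = runif(200), nControls = 10L, patientId = "t")
  expect_length(selectHypometabolic(z, 0.005)@vertexIds, 1)
  # all-equal: the k lowest-indexed vertices win
  zt <- new("ZMap", z = rep(1, 400), nControls = 10L, patientId = "t")
  expect_identical(selectHypometabolic(zt, 0.01)@vertexIds, 1:4)
  # fsaverage-sized input: floor(0.005 * 163842) = 819
  set.seed(3)
  zf <- new("ZMap", z = rnorm(163842), nControls = 10L, patientId = "t")
  expect_length(selectHypometabolic(zf, 0.005)@vertexIds, 819)
  # missing vertices excluded from numerator and denominator
  zm <- new("ZMap", z = c(rep(NA_real_, 100), runif(300)),
            nControls = 10L, patientId = "t")
  sel <- selectHypometabolic(zm, 0.01)
  expect_length(sel@vertexIds, 3)          # floor(0.01 * 300)
  expect_true(all(sel@vertexIds > 100))
  expect_error(selectHypometabolic(
    new("ZMap", z = rep(NA_real_, 5), nControls = 10L, patientId = "t")),
    "usable")
})

test_that("selected vertices map to hemisphere-distinct regions", {
  cx <- fixtureCortex()
  p <- cx$parcellation
  lab <- vertexRegions(p)
  # all selected vertices in one region -> singleton set
  vs <- which(lab == lab[1] & vertexHemispheres(p) == "lh")[1:5]
  r <- verticesToRegions(vs, p)
  expect_equal(nrow(r), 1)
  expect_equal(r$hemisphere, "lh")
  # homologous left/right regions give two distinct entries
  vl <- which(lab == "region_03" & vertexHemispheres(p) == "lh")[1]
  vr <- which(lab == "region_03" & vertexHemispheres(p) == "rh")[1]
  r2 <- verticesToRegions(c(vl, vr), p)
  expect_equal(nrow(r2), 2)
  expect_setequal(r2$hemisphere, c("lh", "rh"))
  expect_equal(nrow(verticesToRegions(integer(0), p)), 0)
})

test_that("threshold overlays are monotone in the threshold", {
  set.seed(9)
  z <- new("ZMap", z = rnorm(500, 0, 1), nControls = 10L, patientId = "t")
  expect_length(thresholdOverlay(z, min(z@z) - 0.1), 0)
  expect_length(thresholdOverlay(z, Inf), 500)
  thr <- seq(-3, 3, by = 0.5)
  sets <- lapply(thr, function(t) thresholdOverlay(z, t))
  for (i in seq_len(length(thr) - 1))
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("held-out control Z-scores are approximately standard normal", {
  s <- makeToySurface(4, seed = 7)          # 2562 vertices
  p <- makeParcellation(s, 10, seed = 7)
  cfg <- simulationConfig(n_controls = 101, seed = 17)
  maps <- simulateControlCohort(s, p, cfg)
  tmpl <- buildTemplate(maps[1:100])
  z <- mapValues(computeZMap(maps[[101]], tmpl))
  expect_lt(abs(mean(z)), 0.05)
  expect_gt(sd(z), 0.9)
  expect_lt(sd(z), 1.1)
})

test_that("planted lesions are recovered through the surface statistics", {
  s <- fixtureSurface()
  p <- fixtureParcellation()
  hits <- 0
  for (seed in 1:20) {
    cfg <- simulationConfig(n_controls = 23, seed = 3000 + seed)
    soz <- data.frame(hemisphere = "lh",
                      region = sprintf("region_%02d", 1 + seed %% 10))
    tmpl <- buildTemplate(lapply(simulateControlCohort(s, p, cfg),
                                 globalMeanNormalize))
    pat <- simulatePatient(s, p, soz, -3, cfg)
    zm <- computeZMap(globalMeanNormalize(pat$map), tmpl)
    sel <- selectHypometabolic(zm, 0.005, p)
    if (soz$region %in% sel@regions$region) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.95)
})
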