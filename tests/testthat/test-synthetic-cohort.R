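test_that("control cohort noise model matches its configuration", {
  s <- makeToySurface(2, seed = 3)            # 162 vertices
  p <- makeParcellation(s, 5, seed = 3)
  # zero noise: every control map equals the baseline profile
  cfg0 <- simulationConfig(n_controls = 3, control_noise_sd = 0, seed = 9)
  maps <- simulateControlCohort(s, p, cfg0)
  expect_equal(mapValues(maps[[1]]), mapValues(maps[[2]]))
  expect_equal(mapValues(maps[[2]]), mapValues(maps[[3]]))
  # Monte-Carlo: per-vertex sample SD of a large cohort matches the
  # configured SD within 3%
  cfg <- simulationConfig(n_controls = 10000, control_noise_sd = 0.08,
                          seed = 9)
  X <- vapply(simulateControlCohort(s, p, cfg), mapValues,
              numeric(nVertices(s)))
  sdHat <- apply(X, 1, sd)
  expected <- zmapsoz:::controlNoiseSD(s, p, cfg)
  expect_lt(max(abs(sdHat / expected - 1)), 0.03)
  expect_true(all(X > 0))
})

test_that("cohort and patient generation are seed-deterministic", {
  s <- makeToySurface(2, seed = 3)
  p <- makeParcellation(s, 5, seed = 3)
  cfg <- simulationConfig(n_controls = 4, seed = 21)
  a <- simulateControlCohort(s, p, cfg)
  b <- simulateControlCohort(s, p, cfg)
  expect_identical(lapply(a, mapValues), lapply(b, mapValues))
  soz <- data.frame(hemisphere = "lh", region = "region_01")
  pa <- simulatePatient(s, p, soz, -3, cfg)
  pb <- simulatePatient(s, p, soz, -3, cfg)
  expect_identical(mapValues(pa$map), mapValues(pb$map))
})

test_that("planted lesions shift exactly the requested parcels", {
  s <- makeToySurface(2, seed = 3)
  p <- makeParcellation(s, 5, seed = 3)
  cfg <- simulationConfig(n_controls = 5, seed = 13)
  soz <- data.frame(hemisphere = "lh", region = "region_02")
  null <- simulatePatient(s, p, soz, 0, cfg)
  les <- simulatePatient(s, p, soz, -3, cfg)
  inLesion <- vertexRegions(p) == "region_02"
  expect_equal(mapValues(null$map)[!inLesion],
               mapValues(les$map)[!inLesion])
  expect_true(all(mapValues(les$map)[inLesion] <
                    mapValues(null$map)[inLesion]))
  expect_equal(les$truth@sozRegions$region, "region_02")
  expect_error(simulatePatient(s, p,
                               data.frame(hemisphere = "lh",
                                          region = "no_such"),
                               -3, cfg),
               "unknown region")
})

test_that("empirical Z inside a -3 SD lesion converges to -3", {
  s <- makeToySurface(2, seed = 3)
  p <- makeParcellation(s, 5, seed = 3)
  soz <- data.frame(hemisphere = "lh", region = "region_03")
  inLesion <- vertexRegions(p) == "region_03"
  zs <- numeric(0)
  for (seed in 1:30) {
    cfg <- simulationConfig(n_controls = 23, seed = 1000 + seed)
    tmpl <- buildTemplate(simulateControlCohort(s, p, cfg))
    pat <- simulatePatient(s, p, soz, -3, cfg)
    z <- mapValues(computeZMap(pat$map, tmpl))
    zs <- c(zs, z[inLesion])
  }
  # small negative bias relative to -3 is expected: Z uses the sample SD
  # of 23 controls, and E[sigma/s] at 22 df is about 1.035
  expect_equal(mean(zs), -3, tolerance = 0.15)
})

test_that("the bundled lobe lookup has the expected structure", {
  tab <- destrieuxLobeTable(include_unclassified = TRUE)
  expect_setequal(unique(tab$hemisphere), c("lh", "rh"))
  expect_equal(sum(tab$lobe == "unclassified"), 2)   # one medial wall/hemi
  expect_false(anyDuplicated(paste(tab$hemisphere, tab$region)) > 0)
  # default excludes the unclassified medial wall
  expect_false("unclassified" %in% destrieuxLobeTable()$lobe)
})
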