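# A fine-grid label volume around the origin: 0.2 mm isotropic voxels.
fineGrid <- function(n = 31, labels = NULL) {
  aff <- diag(c(0.2, 0.2, 0.2, 1))
  aff[1:3, 4] <- -0.2 * (n - 1) / 2
  data <- if (is.null(labels)) array(1, c(n, n, n)) else labels
  VolumeImage(data, aff, units = "label")
}

mkContact <- function(x = 0, y = 0, z = 0, axis = c(0, 0, 1)) {
  data.frame(x = x, y = y, z = z, axis_x = axis[1], axis_y = axis[2],
             axis_z = axis[3], diameter = 0.8, length = 2.0)
}

test_that("contact voxelization equals the point-in-cylinder oracle", {
  vol <- fineGrid()
  for (axis in list(c(0, 0, 1), c(1, 0, 0),
                    c(1, 1, 1) / sqrt(3), c(0.6, -0.8, 0))) {
    ct <- mkContact(axis = axis)
    fp <- voxelizeContact(ct, vol)
    expect_false(fp$supersampled)
    expect_identical(sort(fp$indices), cylinderFootprintOracle(ct, vol))
  }
  # discretization symmetry: rotating 90 degrees changes counts < 10%
  n1 <- length(voxelizeContact(mkContact(axis = c(0, 0, 1)), vol)$indices)
  n2 <- length(voxelizeContact(mkContact(axis = c(1, 0, 0)), vol)$indices)
  expect_lt(abs(n1 - n2) / n1, 0.10)
  expect_error(voxelizeContact(mkContact(x = 100), vol), "outside")
})

test_that("coarse grids fall back to supersampled fractional occupancy", {
  aff <- diag(c(1, 1, 1, 1)); aff[1:3, 4] <- -10
  vol <- VolumeImage(array(1, c(21, 21, 21)), aff, units = "label")
  fp <- voxelizeContact(mkContact(x = 0.3, y = 0.2, z = 0.1), vol)
  expect_true(fp$supersampled)
  expect_true(all(fp$weights > 0 & fp$weights <= 1))
  # total occupancy approximates cylinder volume / voxel volume
  cylVol <- pi * 0.4^2 * 2
  expect_equal(sum(fp$weights), cylVol, tolerance = 0.15)
})

test_that("the strict majority rule verifies 60/40 but rejects 50/50", {
  tab <- data.frame(code = c(1, 2, 3),
                    hemisphere = c("lh", "lh", NA),
                    region = c("A", "B", "white_matter"),
                    gray = c(TRUE, TRUE, FALSE))
  vol <- fineGrid()
  mkFootprint <- function(labels) {
    # synthetic footprint over the first length(labels) voxels
    list(indices = seq_along(labels), weights = rep(1, length(labels)))
  }
  labArr <- array(1, dim(volData(vol)))
  v <- VolumeImage(labArr, volAffine(vol), units = "label")
  a <- assignContactRegion(mkFootprint(rep(1, 10)), v, tab)
  expect_true(a@verified)
  expect_equal(a@region, "A")
  expect_equal(a@majorityFraction, 1.0)
  # 60/40 straddling contact: verified for the 60% region
  labArr[1:10] <- c(rep(1, 6), rep(2, 4))
  v <- VolumeImage(labArr, volAffine(vol), units = "label")
  a2 <- assignContactRegion(mkFootprint(rep(0, 10)), v, tab)
  expect_true(a2@verified)
  expect_equal(a2@region, "A")
  expect_equal(a2@majorityFraction, 0.6)
  # exact 50/50: strict inequality fails
  labArr[1:10] <- c(rep(1, 5), rep(2, 5))
  v <- VolumeImage(labArr, volAffine(vol), units = "label")
  a3 <- assignContactRegion(mkFootprint(rep(0, 10)), v, tab)
  expect_false(a3@verified)
  expect_true(is.na(a3@region))
  # majority in white matter: fraction > 0.5 but not gray, not verified
  labArr[1:10] <- c(rep(3, 6), rep(1, 4))
  v <- VolumeImage(labArr, volAffine(vol), units = "label")
  a4 <- assignContactRegion(mkFootprint(rep(0, 10)), v, tab)
  expect_false(a4@verified)
  expect_equal(a4@majorityFraction, 0.6)
})

test_that("label permutation changes assignments but never verification", {
  set.seed(12)
  n <- 21
  labels <- array(sample(1:3, n^3, replace = TRUE,
                         prob = c(0.6, 0.3, 0.1)), c(n, n, n))
  tab <- data.frame(code = 1:3, hemisphere = "lh",
                    region = c("A", "B", "C"), gray = TRUE)
  vol <- fineGrid(n, labels)
  perm <- c(2, 3, 1)
  volP <- fineGrid(n, array(perm[labels], c(n, n, n)))
  for (off in list(c(0, 0, 0), c(0.3, -0.2, 0.1), c(-0.5, 0.5, 0))) {
    ct <- mkContact(off[1], off[2], off[3], axis = c(0, 0, 1))
    a <- assignContactRegion(voxelizeContact(ct, vol), vol, tab)
    b <- assignContactRegion(voxelizeContact(ct, volP), volP, tab)
    expect_identical(a@verified, b@verified)
    expect_equal(a@majorityFraction, b@majorityFraction)
  }
})

test_that("gray-matter filtering matches the synthetic ground truth", {
  sc <- fixtureScene()
  soz <- sc$soz_regions
  sim <- simulateContacts(sc$label, sc$label_table, n_electrodes = 5,
                          contacts_per_electrode = 6, soz_regions = soz,
                          seed = 31)
  flt <- filterGrayMatterContacts(sim$contacts, sc$label, sc$label_table)
  expect_equal(nrow(flt$report), nrow(contacts(sim$contacts)))
  # verified assignments agree with the recorded ground truth
  gt <- sim$truth@contactRegions
  merged <- merge(flt$report, gt, by = "contact_id",
                  suffixes = c("", "_true"))
  ver <- merged[merged$verified, ]
  expect_gt(nrow(ver), 0)
  expect_equal(ver$region, ver$region_true)
  expect_equal(ver$hemisphere, ver$hemisphere_true)
  # empty table round-trips to empty output
  empty <- new("ContactTable",
               contacts = contacts(sim$contacts)[0, , drop = FALSE])
  fe <- filterGrayMatterContacts(empty, sc$label, sc$label_table)
  expect_equal(nrow(fe$report), 0)
  expect_equal(nrow(contacts(fe$verified)), 0)
})

test_that("simulated electrodes respect geometry, spacing and determinism", {
  sc <- fixtureScene()
  sim <- simulateContacts(sc$label, sc$label_table, n_electrodes = 3,
                          contacts_per_electrode = 5,
                          soz_regions = sc$soz_regions, seed = 8)
  df <- contacts(sim$contacts)
  expect_equal(nrow(df), 15)
  # centre-to-centre pitch = contact length + 1.5 mm insulation gap
  for (el in unique(df$electrode)) {
    sub <- df[df$electrode == el, ]
    gaps <- sqrt(diff(sub$x)^2 + diff(sub$y)^2 + diff(sub$z)^2)
    expect_equal(gaps, rep(2.0 + 1.5, nrow(sub) - 1), tolerance = 1e-9)
  }
  # deepest contact sits at its target region's centroid: ground truth
  # assigns it to that region
  first <- sim$truth@contactRegions[
    sim$truth@contactRegions$contact_id == "E01C01", ]
  expect_equal(paste(first$hemisphere, first$region),
               paste(sc$soz_regions$hemisphere, sc$soz_regions$region))
  sim2 <- simulateContacts(sc$label, sc$label_table, n_electrodes = 3,
                           contacts_per_electrode = 5,
                           soz_regions = sc$soz_regions, seed = 8)
  expect_identical(contacts(sim2$contacts), df)
  expect_error(simulateContacts(sc$label, sc$label_table,
                                contacts_per_electrode = 4,
                                soz_regions = sc$soz_regions, seed = 8))
  expect_error(simulateContacts(sc$label, sc$label_table,
                                n_electrodes = 2,
                                contacts_per_electrode = 18,
                                soz_regions = sc$soz_regions, seed = 8),
               "exits the volume")
})
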