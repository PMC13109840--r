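mkReport <- function(ids, regions, hemis, verified = TRUE) {
  data.frame(contact_id = ids, region = regions, hemisphere = hemis,
             majority_fraction = 0.9,
             verified = rep_len(verified, length(ids)),
             stringsAsFactors = FALSE)
}

mkContactTable <- function(ids, soz) {
  new("ContactTable", contacts = data.frame(
    contact_id = ids, electrode = "E1",
    x = seq_along(ids), y = 0, z = 0,
    axis_x = 1, axis_y = 0, axis_z = 0,
    diameter = 0.8, length = 2, soz_flag = soz,
    stringsAsFactors = FALSE))
}

lobeTab <- data.frame(
  hemisphere = rep(c("lh", "rh"), each = 2),
  region = rep(c("A", "B"), 2),
  lobe = rep(c("frontal", "temporal"), 2),
  stringsAsFactors = FALSE)

test_that("region instances collapse contacts with the any-contact SOZ rule", {
  ct <- mkContactTable(c("c1", "c2", "c3"), c(TRUE, FALSE, FALSE))
  rep1 <- mkReport(c("c1", "c2", "c3"), c("A", "A", "B"),
                   c("lh", "lh", "lh"))
  inst <- buildRegionInstances(ct, rep1, lobeTab)
  expect_equal(nrow(inst), 2)
  expect_equal(inst$is_soz[inst$region == "A"], TRUE)  # one of two flagged
  expect_equal(inst$is_soz[inst$region == "B"], FALSE)
  expect_equal(inst$lobe[inst$region == "A"], "frontal")
  # left and right homologues are distinct instances
  rep2 <- mkReport(c("c1", "c2"), c("A", "A"), c("lh", "rh"))
  inst2 <- buildRegionInstances(mkContactTable(c("c1", "c2"),
                                               c(TRUE, FALSE)), rep2,
                                lobeTab)
  expect_equal(nrow(inst2), 2)
  # unverified contacts contribute nothing
  rep3 <- mkReport("c1", "A", "lh", verified = FALSE)
  expect_equal(nrow(buildRegionInstances(mkContactTable("c1", TRUE),
                                         rep3, lobeTab)), 0)
  # unknown region is an error
  rep4 <- mkReport("c1", "Z", "lh")
  expect_error(buildRegionInstances(mkContactTable("c1", TRUE), rep4,
                                    lobeTab), "unknown")
})

test_that("cross-classification counts match brute-force enumeration", {
  set.seed(14)
  inst <- data.frame(
    patient = "p1",
    hemisphere = sample(c("lh", "rh"), 100, replace = TRUE),
    region = sprintf("R%02d", sample(1:25, 100, replace = TRUE)),
    lobe = "frontal",
    is_soz = sample(c(TRUE, FALSE), 100, replace = TRUE),
    stringsAsFactors = FALSE)
  inst <- inst[!duplicated(paste(inst$hemisphere, inst$region)), ]
  hypo <- unique(inst[sample(nrow(inst), 10), c("hemisphere", "region")])
  cc <- crossClassify(inst, hypo)
  # brute force, row by row
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(nrow(inst))) {
    h <- any(hypo$hemisphere == inst$hemisphere[i] &
               hypo$region == inst$region[i])
    s <- inst$is_soz[i]
    if (s && h) tp <- tp + 1 else if (!s && h) fp <- fp + 1
    else if (s) fn <- fn + 1 else tn <- tn + 1
  }
  expect_equal(cc$counts, c(TP = tp, FP = fp, FN = fn, TN = tn))
  expect_equal(sum(cc$counts), nrow(inst))
  # degenerate cases
  allPos <- crossClassify(
    data.frame(patient = "p", hemisphere = "lh", region = "A",
               lobe = "frontal", is_soz = TRUE),
    data.frame(hemisphere = "lh", region = "A"))
  expect_equal(unname(allPos$counts), c(1, 0, 0, 0))
  noHypo <- crossClassify(inst, hypo[0, ])
  expect_equal(unname(noHypo$counts[c("TP", "FP")]), c(0, 0))
})

test_that("the six metrics match their definitions and flag undefined values", {
  perfect <- computeMetrics(c(TP = 10, FP = 0, FN = 0, TN = 90))
  expect_equal(unlist(perfect[c("TPR", "TNR", "PPV", "NPV", "ACC",
                                "Kappa")]),
               c(TPR = 1, TNR = 1, PPV = 1, NPV = 1, ACC = 1, Kappa = 1))
  allNeg <- computeMetrics(c(TP = 0, FP = 0, FN = 10, TN = 90))
  expect_equal(allNeg$TPR, 0)
  expect_equal(allNeg$TNR, 1)
  expect_equal(allNeg$ACC, 0.9)
  expect_equal(allNeg$Kappa, 0)           # chance-level agreement
  expect_true(is.na(allNeg$PPV))          # zero denominator flagged
  big <- computeMetrics(c(TP = 170, FP = 59, FN = 106, TN = 925))
  expect_equal(big$ACC, 0.869, tolerance = 5e-4)
  expect_equal(big$Kappa, 0.592, tolerance = 5e-4)
  expect_equal(big$Kappa, kappaOracle(170, 59, 106, 925),
               tolerance = 1e-12)
  expect_error(computeMetrics(c(TP = 0, FP = 0, FN = 0, TN = 0)), "zero")
})

test_that("kappa is near zero for independent labels", {
  set.seed(20)
  truth <- runif(10000) < 0.3
  pred <- runif(10000) < 0.2
  counts <- c(TP = sum(truth & pred), FP = sum(!truth & pred),
              FN = sum(truth & !pred), TN = sum(!truth & !pred))
  expect_lt(abs(computeMetrics(counts)$Kappa), 0.05)
})

test_that("stratified reporting follows Table-2 layout with an exclusion floor", {
  set.seed(21)
  inst <- data.frame(
    patient = "p1",
    hemisphere = rep(c("lh", "rh"), 50),
    region = sprintf("R%03d", 1:100),
    lobe = rep(c("frontal", "temporal", "parietal", "insular"), 25),
    is_soz = runif(100) < 0.3,
    stringsAsFactors = FALSE)
  hypo <- inst[inst$is_soz | runif(100) < 0.1, c("hemisphere", "region")]
  res <- stratifyAndReport(inst, hypo, floor = 30)
  m <- concordanceMetrics(res)
  expect_equal(m$Category,
               c("Total", "Frontal lobe", "Parietal lobe",
                 "Temporal lobe", "Occipital lobe", "Insular lobe",
                 "Left hemisphere", "Right hemisphere"))
  # lobe Ns partition the total
  lobeRows <- grepl("lobe$", m$Category)
  expect_equal(sum(m$N[lobeRows]), m$N[m$Category == "Total"])
  hemiRows <- grepl("hemisphere$", m$Category)
  expect_equal(sum(m$N[hemiRows]), m$N[m$Category == "Total"])
  # 25-instance lobes are under the floor: flagged, not numeric
  expect_true(all(!m$reported[lobeRows]))
  expect_true(all(is.na(m$TPR[lobeRows])))
  expect_true(all(m$reported[hemiRows]))  # 50 >= 30
  # instance ordering does not change the table
  res2 <- stratifyAndReport(inst[sample(nrow(inst)), ], hypo, floor = 30)
  expect_equal(concordanceMetrics(res2), m)
  # a single-lobe cohort: that lobe's row equals the total row
  fr <- inst[inst$lobe == "frontal", ]
  resF <- stratifyAndReport(fr, hypo, floor = 10)
  mF <- concordanceMetrics(resF)
  tot <- mF[mF$Category == "Total", -1]
  fro <- mF[mF$Category == "Frontal lobe", -1]
  rownames(tot) <- rownames(fro) <- NULL
  expect_equal(fro, tot)
})
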