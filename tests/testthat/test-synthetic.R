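test_that("phantoms contain the labeled anatomy plus other structures", {
  ph <- generatePhantom("prostate", "sp01", seed = 6, nOther = 3)
  labels <- vapply(records(ph$sset), trueLabel, character(1))
  expect_setequal(setdiff(labels, "other"),
                  setdiff(classNames(prostateLabels()), "other"))
  expect_equal(sum(labels == "other"), 3)
  expect_gte(sum(labels == "other"), 1)
  # every structure has closed-polygon contours on at least one slice
  expect_true(all(vapply(records(ph$sset), function(r)
    length(contours(r)) > 0, logical(1))))

  lg <- generatePhantom("lung", "sp02", seed = 6, nOther = 2)
  expect_setequal(setdiff(vapply(records(lg$sset), trueLabel,
                                 character(1)), "other"),
                  setdiff(classNames(lungLabels()), "other"))

  # bony anatomy exceeds the HU threshold by construction
  box <- computeBoundingBox(ph$series)
  expect_gt(sum(bits(extractBonyAnatomy(ph$series, box))), 0)

  # seeded determinism
  ph2 <- generatePhantom("prostate", "sp01", seed = 6, nOther = 3)
  expect_identical(voxels(ph2$series), voxels(ph$series))
  expect_identical(contours(records(ph2$sset)[[1]]),
                   contours(records(ph$sset)[[1]]))
})

test_that("center profiles implement the bowel naming convention", {
  at <- aliasTable("prostate")
  expect_true(all(lengths(at) >= 1))
  expect_true("bowel" %in% at$Bowel_Small && "bowel" %in% at$Bowel_Large)

  withr::with_seed(8, {
    amb <- makeCenterProfile("prostate", ambiguityRate = 1)
    expect_true(amb$ambiguous)
    expect_identical(amb$alias[[amb$convention]], "bowel")
    otherBowel <- setdiff(c("Bowel_Small", "Bowel_Large"), amb$convention)
    expect_false(identical(amb$alias[[otherBowel]], "bowel"))

    clean <- makeCenterProfile("prostate", ambiguityRate = 0)
    expect_false(clean$ambiguous)
    expect_false("bowel" %in% unlist(clean$alias))

    # noise off: the sampled name is the center's fixed alias
    nm1 <- sampleName("Bladder", clean)
    nm2 <- sampleName("Bladder", clean)
    expect_identical(nm1, clean$alias$Bladder)
    expect_identical(nm1, nm2)
    expect_error(sampleName("Colon", clean), "unknown class")
  })
})

test_that("cohort manifests are reproducible and dominated by 'other'", {
  cfg <- cohortConfig(nCenters = 8, patientsPerCenter = 2,
                      otherRange = c(8, 12), seed = 12)
  c1 <- generateCohort(cfg, geometry = FALSE)
  c2 <- generateCohort(cfg, geometry = FALSE)
  expect_identical(manifest(c1), manifest(c2))

  man <- manifest(c1)
  counts <- table(man$true_label)
  expect_identical(names(which.max(counts)), "other")
  # labeled classes appear once per patient
  nPat <- length(unique(man$patient_id))
  for (cl in setdiff(classNames(prostateLabels()), "other"))
    expect_equal(unname(counts[cl]), nPat)
  # structure counts = patients x (7 labeled + nOther in configured range)
  perPat <- table(man$patient_id)
  expect_true(all(perPat >= 7 + 8 & perPat <= 7 + 12))

  # the naming stream is independent of geometry generation
  c3 <- generateCohort(cfg, geometry = TRUE)
  expect_identical(manifest(c3), man)
  expect_equal(nrow(c3@boneRows), nPat)
  expect_gt(Matrix::nnzero(c3@boneRows), 0)
})

test_that("generated DICOM cohorts round-trip through the readers", {
  cfg <- cohortConfig(nCenters = 2, patientsPerCenter = 1,
                      otherRange = c(1, 2), seed = 44)
  dir <- withr::local_tempdir()
  cohort <- generateCohort(cfg, dicomPath = dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  man <- manifest(cohort)
  for (pid in unique(man$patient_id)) {
    s <- readCTSeries(file.path(dir, pid))
    ss <- readStructureSet(file.path(dir, pid, "rs.dcm"), s)
    expect_identical(vapply(records(ss), givenName, character(1)),
                     man$given_name[man$patient_id == pid])
  }
  loaded <- loadCohortFromDicom(dir)
  expect_identical(manifest(loaded)$given_name, man$given_name)
  expect_identical(manifest(loaded)$true_label, man$true_label)
  # geometry survives: same rasterization either way
  X1 <- featurizeGeometry(cohort)
  X2 <- featurizeGeometry(loaded)
  expect_lt(max(abs(X1 - X2)), 1e-12)
})

test_that("ambiguous centers give conflicting meanings to 'bowel'", {
  cfg <- cohortConfig(nCenters = 20, patientsPerCenter = 1,
                      otherRange = c(1, 2), ambiguityRate = 1,
                      nameNoise = list(case = 0, abbrev = 0, suffix = 0),
                      seed = 77)
  man <- manifest(generateCohort(cfg, geometry = FALSE))
  bowelRows <- man[man$given_name == "bowel", ]
  expect_gt(nrow(bowelRows), 0)
  meanings <- unique(bowelRows$true_label)
  expect_setequal(meanings, c("Bowel_Small", "Bowel_Large"))
  # within a center the convention is fixed
  perCenter <- tapply(bowelRows$true_label, bowelRows$center_id,
                      function(x) length(unique(x)))
  expect_true(all(perCenter == 1))
})
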