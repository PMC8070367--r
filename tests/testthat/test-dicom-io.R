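test_that("synthetic DICOM round-trips series and structure set", {
  ph <- generatePhantom("prostate", "RTpat01", seed = 11, nOther = 2)
  dir <- withr::local_tempdir()
  man <- writeSyntheticDicom(ph$series, ph$sset, dir)

  expect_length(man$ct_files, dim(voxels(ph$series))[3])
  expect_identical(man$rtstruct_file, "rs.dcm")
  expect_true(file.exists(file.path(dir, "manifest.json")))

  s2 <- readCTSeries(dir)
  expect_identical(voxels(s2), voxels(ph$series))
  expect_equal(origin(s2), c(-190, -190, -117.5))
  expect_equal(spacing(s2), c(4, 4, 5))
  expect_equal(s2@slicePositions, ph$series@slicePositions)

  ss2 <- readStructureSet(file.path(dir, "rs.dcm"), s2)
  r1 <- records(ph$sset)
  r2 <- records(ss2)
  expect_length(r2, length(r1))
  for (i in seq_along(r1)) {
    expect_identical(givenName(r2[[i]]), givenName(r1[[i]]))
    expect_length(contours(r2[[i]]), length(contours(r1[[i]])))
    for (k in seq_along(contours(r1[[i]]))) {
      expect_lt(max(abs(contours(r2[[i]])[[k]]$points -
                        contours(r1[[i]])[[k]]$points)), 1e-3)
      expect_equal(contours(r2[[i]])[[k]]$z, contours(r1[[i]])[[k]]$z,
                   tolerance = 1e-6)
    }
  }
})

test_that("double round-trip is byte-stable on contour coordinates", {
  ph <- generatePhantom("lung", "RTpat02", seed = 3, nOther = 1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeSyntheticDicom(ph$series, ph$sset, d1)
  s1 <- readCTSeries(d1)
  ss1 <- readStructureSet(file.path(d1, "rs.dcm"), s1)
  writeSyntheticDicom(s1, ss1, d2)
  expect_identical(readBin(file.path(d1, "rs.dcm"), "raw", 1e7),
                   readBin(file.path(d2, "rs.dcm"), "raw", 1e7))
})

test_that("reader preserves physician-given names verbatim", {
  # naming-variability corpus: case, whitespace and symbols must survive
  names <- c("Fem hdneck Lt", "LtFemoral Head", "bldr", "bladder-KS",
             "BLADDER", "Dose 107.1[%]", "PROS+SV'S", "SM_bowel", "out")
  series <- makeSeries(c(6, 6, 3), patientId = "names01")
  recs <- lapply(names, function(nm)
    makeRecord(cbind(c(1, 4, 4, 1), c(1, 1, 4, 4)), z = 0.5, name = nm,
               patientId = "names01"))
  dir <- withr::local_tempdir()
  writeSyntheticDicom(series, StructureSet(recs, "names01"), dir)
  ss <- readStructureSet(file.path(dir, "rs.dcm"), readCTSeries(dir))
  expect_identical(vapply(records(ss), givenName, character(1)), names)
})

test_that("degenerate and invalid inputs raise the documented errors", {
  empty <- withr::local_tempdir()
  expect_error(readCTSeries(empty), "no series found")

  # two files with different series UIDs
  dir <- withr::local_tempdir()
  writeSyntheticDicom(makeSeries(c(4, 4, 2), patientId = "pA"),
                      StructureSet(list(), "pA"), dir)
  mixed <- withr::local_tempdir()
  writeSyntheticDicom(makeSeries(c(4, 4, 2), patientId = "pB"),
                      StructureSet(list(), "pB"), mixed)
  file.copy(file.path(mixed, "ct_001.dcm"), file.path(dir, "ct_zzz.dcm"))
  expect_error(readCTSeries(dir), "inconsistent series")

  # RT-STRUCT with an empty ROI sequence is valid and yields 0 records
  d2 <- withr::local_tempdir()
  writeSyntheticDicom(makeSeries(c(4, 4, 2), patientId = "pC"),
                      StructureSet(list(), "pC"), d2)
  s <- readCTSeries(d2)
  expect_length(records(readStructureSet(file.path(d2, "rs.dcm"), s)), 0)

  # ROI with zero contour items keeps an empty contour list
  rec <- StructureRecord("empty_roi", list(), patientId = "pC")
  d3 <- withr::local_tempdir()
  writeSyntheticDicom(makeSeries(c(4, 4, 2), patientId = "pC"),
                      StructureSet(list(rec), "pC"), d3)
  ss <- readStructureSet(file.path(d3, "rs.dcm"), readCTSeries(d3))
  expect_length(records(ss), 1)
  expect_length(contours(records(ss)[[1]]), 0)

  expect_error(readStructureSet(file.path(d3, "ct_001.dcm"),
                                readCTSeries(d3)), "not an RT structure set")
})

test_that("frame-of-reference mismatch warns by default, errors in strict mode", {
  dir <- withr::local_tempdir()
  series <- makeSeries(c(4, 4, 2), patientId = "pD")
  rec <- makeRecord(cbind(c(1, 3, 3), c(1, 1, 3)), 0.5, patientId = "pD")
  writeSyntheticDicom(series, StructureSet(list(rec), "pD"), dir)
  s <- readCTSeries(dir)
  s@frameOfReferenceUID <- "1.2.3.4"
  expect_warning(ss <- readStructureSet(file.path(dir, "rs.dcm"), s),
                 "frame-of-reference mismatch")
  expect_length(records(ss), 1)  # record retained
  expect_error(readStructureSet(file.path(dir, "rs.dcm"), s, strict = TRUE),
               "frame-of-reference mismatch")
})

test_that("pydicom independently reads the writer's output", {
  ph <- generatePhantom("prostate", "RTpy01", seed = 5, nOther = 1)
  dir <- withr::local_tempdir()
  writeSyntheticDicom(ph$series, ph$sset, dir)
  script <- file.path(dir, "check.py")
  writeLines(c(
    "import pydicom, json, sys",
    sprintf("d = r'%s'", dir),
    "ct = pydicom.dcmread(d + '/ct_001.dcm')",
    "rs = pydicom.dcmread(d + '/rs.dcm')",
    "print(json.dumps({",
    "  'rows': int(ct.Rows), 'cols': int(ct.Columns),",
    "  'hu_min': int(ct.pixel_array.min()),",
    "  'names': [r.ROIName for r in rs.StructureSetROISequence],",
    "  'first_z': float(rs.ROIContourSequence[0].ContourSequence[0].ContourData[2])",
    "}))"), script)
  out <- system2("python", script, stdout = TRUE)
  res <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_equal(res$rows, 96)
  expect_equal(res$cols, 96)
  expect_equal(res$hu_min, -1000)
  expect_identical(res$names,
                   vapply(records(ph$sset), givenName, character(1)))
  expect_equal(res$first_z, contours(records(ph$sset)[[1]])[[1]]$z,
               tolerance = 1e-4)
})
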