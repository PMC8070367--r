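.dcmUID <- function(patientId, kind, idx = NULL) {
  u <- paste0(.dcmUIDroot, kind, ".", .strHash(patientId, 99999989))
  if (!is.null(idx)) u <- paste0(u, ".", idx)
  u
}

#' Write an image series and structure set as DICOM CT + RT-STRUCT
#'
#' Emits one explicit-VR little-endian CT file per slice plus a single RT
#' structure set file, readable by [readCTSeries()] and [readStructureSet()]
#' (and by standard DICOM tools). Names round-trip byte-for-byte (see the
#' vignette for the one padding caveat) and contour coordinates round-trip
#' within 1e-4 mm (decimal-string encoding at 4 decimals).
#'
#' @param series an [ImageSeries-class].
#' @param sset a [StructureSet-class] (may contain zero records).
#' @param path output directory (created if needed).
#' @return Invisibly, the manifest: list of written files with their SOP
#'   instance UIDs; also serialized to `manifest.json` in `path`.
#' @export
writeSyntheticDicom <- function(series, sset, path) {
  validObject(series)
  validObject(sset)
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", path)
  pid <- series@patientId
  studyUID <- .dcmUID(pid, 1)
  seriesUID <- .dcmUID(pid, 2)
  frameUID <- if (nzchar(series@frameOfReferenceUID))
    series@frameOfReferenceUID else .dcmUID(pid, 3)
  d <- dim(series@voxels)
  files <- character(0)
  sopUIDs <- character(0)
  for (k in seq_len(d[3])) {
    sop <- .dcmUID(pid, 4, k)
    dsel <- c(
      .dcmElem(0x0008, 0x0016, "UI", .dcmStr(.uidCT, ui = TRUE)),
      .dcmElem(0x0008, 0x0018, "UI", .dcmStr(sop, ui = TRUE)),
      .dcmElem(0x0008, 0x0060, "CS", .dcmStr("CT")),
      .dcmElem(0x0010, 0x0010, "PN", .dcmStr(pid)),
      .dcmElem(0x0010, 0x0020, "LO", .dcmStr(pid)),
      .dcmElem(0x0018, 0x0050, "DS", .dcmDS(series@spacing[3])),
      .dcmElem(0x0020, 0x000D, "UI", .dcmStr(studyUID, ui = TRUE)),
      .dcmElem(0x0020, 0x000E, "UI", .dcmStr(seriesUID, ui = TRUE)),
      .dcmElem(0x0020, 0x0013, "IS", .dcmIS(k)),
      .dcmElem(0x0020, 0x0032, "DS", .dcmDS(c(series@origin[1:2],
                                              series@slicePositions[k]))),
      .dcmElem(0x0020, 0x0037, "DS", .dcmDS(series@orientation)),
      .dcmElem(0x0020, 0x0052, "UI", .dcmStr(frameUID, ui = TRUE)),
      .dcmElem(0x0028, 0x0002, "US", .dcmU16(1)),
      .dcmElem(0x0028, 0x0004, "CS", .dcmStr("MONOCHROME2")),
      .dcmElem(0x0028, 0x0010, "US", .dcmU16(d[2])),  # Rows = y
      .dcmElem(0x0028, 0x0011, "US", .dcmU16(d[1])),  # Columns = x
      .dcmElem(0x0028, 0x0030, "DS", .dcmDS(series@spacing[c(2, 1)])),
      .dcmElem(0x0028, 0x0100, "US", .dcmU16(16)),
      .dcmElem(0x0028, 0x0101, "US", .dcmU16(16)),
      .dcmElem(0x0028, 0x0102, "US", .dcmU16(15)),
      .dcmElem(0x0028, 0x0103, "US", .dcmU16(1)),
      .dcmElem(0x0028, 0x1052, "DS", .dcmDS(0)),
      .dcmElem(0x0028, 0x1053, "DS", .dcmDS(1)),
      .dcmElem(0x7FE0, 0x0010, "OW", .dcmInt16Raw(series@voxels[, , k]))
    )
    f <- file.path(path, sprintf("ct_%03d.dcm", k))
    .dcmWriteFile(f, .uidCT, sop, dsel)
    files <- c(files, f)
    sopUIDs <- c(sopUIDs, sop)
  }

  rtSop <- .dcmUID(pid, 5)
  recs <- sset@records
  roiItems <- raw(0)
  contourItems <- raw(0)
  for (i in seq_along(recs)) {
    roiItems <- c(roiItems, .dcmItem(c(
      .dcmElem(0x3006, 0x0022, "IS", .dcmIS(i)),
      .dcmElem(0x3006, 0x0024, "UI", .dcmStr(frameUID, ui = TRUE)),
      .dcmElem(0x3006, 0x0026, "LO", .dcmStr(recs[[i]]@givenName))
    )))
    cts <- raw(0)
    for (ct in recs[[i]]@contours) {
      xyz <- cbind(ct$points, ct$z)
      cts <- c(cts, .dcmItem(c(
        .dcmElem(0x3006, 0x0042, "CS", .dcmStr("CLOSED_PLANAR")),
        .dcmElem(0x3006, 0x0046, "IS", .dcmIS(nrow(ct$points))),
        .dcmElem(0x3006, 0x0050, "DS", .dcmDS(as.vector(t(xyz))))
      )))
    }
    contourItems <- c(contourItems, .dcmItem(c(
      .dcmElem(0x3006, 0x0040, "SQ", cts),
      .dcmElem(0x3006, 0x0084, "IS", .dcmIS(i))
    )))
  }
  rtds <- c(
    .dcmElem(0x0008, 0x0016, "UI", .dcmStr(.uidRTSTRUCT, ui = TRUE)),
    .dcmElem(0x0008, 0x0018, "UI", .dcmStr(rtSop, ui = TRUE)),
    .dcmElem(0x0008, 0x0060, "CS", .dcmStr("RTSTRUCT")),
    .dcmElem(0x0010, 0x0010, "PN", .dcmStr(pid)),
    .dcmElem(0x0010, 0x0020, "LO", .dcmStr(pid)),
    .dcmElem(0x0020, 0x000D, "UI", .dcmStr(studyUID, ui = TRUE)),
    .dcmElem(0x0020, 0x000E, "UI", .dcmStr(.dcmUID(pid, 6), ui = TRUE)),
    .dcmElem(0x3006, 0x0002, "SH", .dcmStr("structviews")),
    .dcmElem(0x3006, 0x0020, "SQ", roiItems),
    .dcmElem(0x3006, 0x0039, "SQ", contourItems)
  )
  rtFile <- file.path(path, "rs.dcm")
  .dcmWriteFile(rtFile, .uidRTSTRUCT, rtSop, rtds)

  man <- list(patient_id = pid, frame_of_reference = frameUID,
              ct_files = basename(files), ct_sop_uids = sopUIDs,
              rtstruct_file = basename(rtFile), rtstruct_sop_uid = rtSop,
              n_structures = length(recs))
  jsonlite::write_json(man, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

#' Read a DICOM CT series from a directory
#'
#' Reads all CT image files of a single axial series, sorts slices by
#' z-position (ties broken by instance number) and applies the rescale
#' slope/intercept so voxels are in Hounsfield Units.
#'
#' @param path directory containing one CT series (one file per slice).
#' @return An [ImageSeries-class].
#' @export
readCTSeries <- function(path) {
  files <- list.files(path, pattern = "\\.dcm$", ignore.case = TRUE,
                      full.names = TRUE)
  parsed <- list()
  for (f in files) {
    ds <- tryCatch(.dcmParseFile(f), error = function(e) NULL)
    if (is.null(ds)) next
    if (identical(.dcmGet(ds, "00080060"), "CT"))
      parsed[[length(parsed) + 1L]] <- ds
  }
  if (length(parsed) == 0) stop("no series found in ", path)

  seriesUIDs <- unique(vapply(parsed, function(d) .dcmGet(d, "0020000E", ""),
                              character(1)))
  if (length(seriesUIDs) != 1) stop("inconsistent series: multiple series UIDs")
  orients <- vapply(parsed, function(d)
    paste(.dcmGet(d, "00200037", NA), collapse = ","), character(1))
  if (length(unique(orients)) != 1)
    stop("inconsistent series: mixed orientations")
  orient <- .dcmGet(parsed[[1]], "00200037")
  if (max(abs(orient - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    stop("non-axial series unsupported")

  z <- vapply(parsed, function(d) .dcmGet(d, "00200032")[3], numeric(1))
  inst <- vapply(parsed, function(d) .dcmGet(d, "00200013", 0L)[1], integer(1))
  ord <- order(z, inst)
  parsed <- parsed[ord]
  z <- z[ord]
  if (length(z) > 1 && any(diff(z) <= 0))
    stop("inconsistent series: duplicate slice positions")

  first <- parsed[[1]]
  nx <- .dcmGet(first, "00280011")  # Columns
  ny <- .dcmGet(first, "00280010")  # Rows
  ps <- .dcmGet(first, "00280030")  # [row (y), col (x)] spacing
  dz <- if (length(z) > 1) stats::median(diff(z)) else
    .dcmGet(first, "00180050", 1)
  vox <- array(0L, dim = c(nx, ny, length(parsed)))
  for (k in seq_along(parsed)) {
    ds <- parsed[[k]]
    pix <- readBin(ds[["7FE00010"]], "integer", n = nx * ny, size = 2,
                   signed = .dcmGet(ds, "00280103", 0L) == 1L,
                   endian = "little")
    slope <- .dcmGet(ds, "00281053", 1)
    icpt <- .dcmGet(ds, "00281052", 0)
    vox[, , k] <- as.integer(round(slope * pix + icpt))
  }
  ImageSeries(vox,
    origin = c(.dcmGet(first, "00200032")[1:2], z[1]),
    spacing = c(ps[2], ps[1], dz),
    slicePositions = z,
    patientId = .dcmGet(first, "00100020", "anon"),
    orientation = orient,
    frameOfReferenceUID = .dcmGet(first, "00200052", ""))
}

#' Read a DICOM RT structure set
#'
#' Produces one [StructureRecord-class] per ROI, with the physician-given
#' name preserved verbatim and contour points grouped per slice. A
#' frame-of-reference mismatch against `series` raises a warning and keeps
#' the record (multi-vendor exports are inconsistent); set `strict = TRUE`
#' to make it an error instead.
#'
#' @param path RT-STRUCT file.
#' @param series the [ImageSeries-class] the structures reference.
#' @param strict error (instead of warn) on frame-of-reference mismatch.
#' @return A [StructureSet-class].
#' @export
readStructureSet <- function(path, series, strict = FALSE) {
  ds <- .dcmParseFile(path)
  if (!identical(.dcmGet(ds, "00080016"), .uidRTSTRUCT))
    stop("not an RT structure set: ", path)
  rois <- ds[["30060020"]]
  cseq <- ds[["30060039"]]
  if (is.null(cseq)) stop("no contours in ", path)
  if (is.null(rois)) rois <- list()

  contourByROI <- list()
  for (it in cseq) {
    num <- as.character(.dcmGet(it, "30060084"))
    cts <- list()
    for (ci in .dcmGet(it, "30060040", list())) {
      dat <- .dcmGet(ci, "30060050")
      if (is.null(dat) || length(dat) < 3) next
      m <- matrix(dat, ncol = 3, byrow = TRUE)
      cts[[length(cts) + 1L]] <- list(z = m[1, 3], points = m[, 1:2,
                                                              drop = FALSE])
    }
    contourByROI[[num]] <- cts
  }

  recs <- list()
  for (roi in rois) {
    num <- as.character(.dcmGet(roi, "30060022"))
    refFrame <- .dcmGet(roi, "30060024", "")
    if (nzchar(series@frameOfReferenceUID) && nzchar(refFrame) &&
        !identical(refFrame, series@frameOfReferenceUID)) {
      msg <- sprintf("frame-of-reference mismatch for ROI %s", num)
      if (strict) stop(msg) else warning(msg)
    }
    recs[[length(recs) + 1L]] <- StructureRecord(
      givenName = .dcmGet(roi, "30060026", ""),
      contours = if (!is.null(contourByROI[[num]]))
        contourByROI[[num]] else list(),
      patientId = series@patientId)
  }
  StructureSet(recs, series@patientId)
}
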