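## Synthetic multi-center cohorts: anatomically plausible phantom geometry
## (ellipsoidal organs, bony landmarks in HU) plus a center-level naming
## model with aliasing, abbreviation noise and the cross-center "bowel"
## ambiguity. Everything flows from named seed substreams so the naming
## stream, geometry stream and split stream can be regenerated independently.

#' Alias table for physician-given structure names
#'
#' Canonical alias spellings per standard class. The prostate aliases are
#' real-world naming variants (including the ambiguous bare "bowel" used for
#' small bowel at some centers and large bowel at others); the lung aliases
#' are synthetic variants in the same style, since no published corpus was
#' available for that site. "other" holds planning/QA structure name
#' templates.
#'
#' @param disease `"prostate"` or `"lung"`.
#' @return Named list: class -> character vector of aliases.
#' @export
aliasTable <- function(disease = c("prostate", "lung")) {
  disease <- match.arg(disease)
  if (disease == "prostate") {
    list(
      Femur_L = c("LtFemoral Head", "Left Fem", "Fem hdneck Lt"),
      Femur_R = c("Fem Rt", "Rt_Fem", "Femoral_Rt"),
      Bowel_Large = c("bowel_lg", "colon", "bowel"),
      Bowel_Small = c("bowel", "SM_bowel"),
      Bladder = c("bldr", "bladder-KS", "BLADDER"),
      Rectum = c("Rectum", "Rect", "rectum"),
      PTV = c("PTV_Prost", "PTV", "CTV"),
      other = c("Rectum subptv", "Dose 107.1[%]", "RFH", "Prostate",
        "PTV79.2", "Balloon", "PTV45", "CTV45_OPT", "CouchSurface",
        "CTV45", "ProxSV",
        "Pelvic Nodes", "Rec50", "CTV vessels", "Marker1", "POST",
        "BLDSPARE", "PROS+SV'S", "out", "70opti", "Blad_NO_ptv", "External",
        "ROI_1", "dosavoid2", "calcification", "ROI_3", "Marker3",
        "FIDUCIALS", "bulb", "CouchInterior", "Seeds"))
  } else {
    list(
      Esophagus = c("Esophagus", "esoph", "ESOPHAGUS", "Esophag"),
      SpinalCord = c("SpinalCord", "Cord", "spinal cord", "SC"),
      Brachial_Plexus = c("Brachial_Plexus", "Brach Plexus", "BrPlexus"),
      Heart = c("Heart", "HEART", "Hrt"),
      PTV = c("PTV", "PTV_Lung", "PTV60"),
      other = c("External", "CouchSurface", "ROI_1", "Marker1",
        "Dose 107.1[%]", "GTV", "ITV", "carina", "opt_ring", "ds_cord",
        "Lung minus GTV", "A_Aorta", "block", "avoid", "ROI_2", "skin",
        "CouchInterior", "iso", "dose 95%", "wires"))
  }
}

# ellipsoid priors: organ centres (mm, relative to volume centre) and
# semi-axes; distinct locations are what lets the geometric view separate
# classes the text view cannot (the two bowels)
.organPriors <- function(disease) {
  if (disease == "prostate") {
    list(
      Femur_L = list(center = c(82, 5, -60), radii = c(16, 16, 35)),
      Femur_R = list(center = c(-82, 5, -60), radii = c(16, 16, 35)),
      Bowel_Large = list(center = c(0, 18, 20), radii = c(50, 42, 22)),
      Bowel_Small = list(center = c(0, -30, 45), radii = c(48, 38, 30)),
      Bladder = list(center = c(0, -25, -35), radii = c(35, 28, 22)),
      Rectum = list(center = c(0, 38, -40), radii = c(14, 14, 45)),
      PTV = list(center = c(0, 8, -42), radii = c(24, 24, 22)))
  } else {
    list(
      Esophagus = list(center = c(0, 28, 0), radii = c(9, 9, 95)),
      SpinalCord = list(center = c(0, 55, 0), radii = c(6, 6, 110)),
      Brachial_Plexus = list(center = c(35, 30, 85), radii = c(28, 12, 14)),
      Heart = list(center = c(-25, 5, -15), radii = c(48, 42, 40)),
      PTV = list(center = c(55, -8, 15), radii = c(30, 26, 24)))
  }
}

# trace ellipsoid cross-sections as 24-gon contours at the given slice z's
.ellipsoidContours <- function(center, radii, slicePositions) {
  theta <- seq(0, 2 * pi, length.out = 25)[-25]
  out <- list()
  for (z in slicePositions) {
    t <- (z - center[3]) / radii[3]
    if (abs(t) >= 0.999) next
    f <- sqrt(1 - t^2)
    a <- radii[1] * f
    b <- radii[2] * f
    if (min(a, b) < 1.5) next  # skip degenerate polar slivers
    out[[length(out) + 1L]] <- list(z = z,
      points = cbind(center[1] + a * cos(theta), center[2] + b * sin(theta)))
  }
  out
}

#' Generate one synthetic patient phantom
#'
#' Builds an HU volume (air background -1000, soft-tissue body ellipsoid at
#' 0 HU, bony structures above 1400 HU: a vertebral cylinder, plus femoral
#' head spheres and a sternum bar depending on site) and a structure set
#' with one jittered ellipsoidal structure per OAR/PTV class and `nOther`
#' random "other" structures. Contours are traced per slice as closed
#' 24-gon polygons. Deterministic given `seed`.
#'
#' @param disease `"prostate"` or `"lung"`.
#' @param patientId opaque id.
#' @param seed integer seed for this patient's geometry stream.
#' @param nOther number of extra "other" structures (default 3).
#' @param gridShape phantom voxel grid (default `c(96, 96, 48)`).
#' @param spacing voxel size in mm (default `c(4, 4, 5)`, body-scale).
#' @param jitterSd positional jitter sd in mm (default 6).
#' @return list with `series` ([ImageSeries-class]) and `sset`
#'   ([StructureSet-class]); record names default to the class names.
#' @export
generatePhantom <- function(disease = c("prostate", "lung"),
                            patientId = "anon", seed = 1L, nOther = 3L,
                            gridShape = c(96L, 96L, 48L),
                            spacing = c(4, 4, 5), jitterSd = 6) {
  disease <- match.arg(disease)
  gridShape <- as.integer(gridShape)
  origin <- -(gridShape - 1) * spacing / 2
  xs <- origin[1] + (seq_len(gridShape[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(gridShape[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(gridShape[3]) - 1) * spacing[3]

  withr::with_seed(seed, {
    hu <- array(-1000L, dim = gridShape)
    body <- outer(outer((xs / 175)^2, (ys / 115)^2, `+`), (zs / 200)^2,
                  `+`) < 1
    hu[body] <- 0L
    skelShift <- rnorm(2, 0, 3)
    vert <- outer(((xs - skelShift[1]) / 14)^2,
                  ((ys - 55 - skelShift[2]) / 14)^2, `+`) < 1
    hu[array(vert, gridShape)] <- 1500L
    if (disease == "prostate") {
      for (sx in c(-82, 82)) {
        sph <- outer(outer(((xs - sx - skelShift[1]) / 22)^2,
                           ((ys - 5 - skelShift[2]) / 22)^2, `+`),
                     ((zs + 25) / 22)^2, `+`) < 1
        hu[sph] <- 1500L
      }
    } else {
      stern <- outer(((xs - skelShift[1]) / 10)^2,
                     ((ys + 95 - skelShift[2]) / 10)^2, `+`) < 1
      hu[array(stern, gridShape)] <- 1400L
    }

    priors <- .organPriors(disease)
    recs <- list()
    for (cl in names(priors)) {
      ctr <- priors[[cl]]$center + rnorm(3, 0, jitterSd)
      rad <- priors[[cl]]$radii * runif(1, 0.85, 1.15)
      recs[[length(recs) + 1L]] <- StructureRecord(
        givenName = cl, contours = .ellipsoidContours(ctr, rad, zs),
        trueLabel = cl, patientId = patientId)
    }
    for (i in seq_len(nOther)) {
      ctr <- c(runif(1, -120, 120), runif(1, -90, 90), runif(1, -100, 100))
      rad <- runif(3, 8, 35)
      recs[[length(recs) + 1L]] <- StructureRecord(
        givenName = sprintf("ROI_%d", i),
        contours = .ellipsoidContours(ctr, rad, zs),
        trueLabel = "other", patientId = patientId)
    }

    series <- ImageSeries(hu, origin = origin, spacing = spacing,
      patientId = patientId, frameOfReferenceUID = .dcmUID(patientId, 3))
    list(series = series, sset = StructureSet(recs, patientId))
  })
}

#' Build a center naming profile
#'
#' Each center fixes one preferred alias per class (physician preference is
#' consistent at center level). In an ambiguous center, one of the two bowel
#' classes -- the center's convention -- is labeled with the bare alias
#' "bowel", while the other bowel class (and both bowels at non-ambiguous
#' centers) draws from the unambiguous aliases. Draws from the current RNG
#' state.
#'
#' @param disease `"prostate"` or `"lung"`.
#' @param ambiguityRate probability this center is "bowel"-ambiguous
#'   (prostate only).
#' @return list with `alias` (class -> preferred alias), `ambiguous`,
#'   `convention` (the bowel class meant by "bowel", or NA).
#' @export
makeCenterProfile <- function(disease, ambiguityRate = 0.5) {
  at <- aliasTable(disease)
  ambiguous <- disease == "prostate" && runif(1) < ambiguityRate
  convention <- if (ambiguous) sample(c("Bowel_Small", "Bowel_Large"), 1)
                else NA_character_
  alias <- list()
  for (cl in setdiff(names(at), "other")) {
    pool <- at[[cl]]
    if (cl %in% c("Bowel_Small", "Bowel_Large")) {
      pool <- if (ambiguous && cl == convention) "bowel"
              else setdiff(pool, "bowel")
    }
    alias[[cl]] <- if (length(pool) == 1) pool else sample(pool, 1)
  }
  list(disease = disease, alias = alias, ambiguous = ambiguous,
       convention = convention, otherPool = at$other)
}

#' Sample a physician-given name for a class
#'
#' Applies the center's preferred alias and per-patient noise:
#' whole-string case flips, substitution by another alias of the same class
#' (abbreviation variability), and appended suffix tokens. For "other",
#' draws from the planning-structure template pool or generates an indexed
#' name. Draws from the current RNG state; with all noise probabilities 0
#' the name is the center's fixed alias.
#'
#' @param class standard class name (must exist in the profile).
#' @param profile a [makeCenterProfile()] result.
#' @param nameNoise list with `case`, `abbrev`, `suffix` probabilities.
#' @return A single name string.
#' @export
sampleName <- function(class, profile,
                       nameNoise = list(case = 0, abbrev = 0, suffix = 0)) {
  if (class == "other") {
    if (runif(1) < 0.5) return(sample(profile$otherPool, 1))
    return(paste0(sample(c("roi_", "ptv", "ctv", "marker", "opt", "ring",
                           "dose"), 1), sample.int(99, 1)))
  }
  if (is.null(profile$alias[[class]])) stop("unknown class: ", class)
  nm <- profile$alias[[class]]
  bowelFixed <- identical(nm, "bowel")  # the ambiguity is the convention
  if (!bowelFixed && runif(1) < nameNoise$abbrev) {
    pool <- aliasTable(profile$disease)[[class]]
    if (class %in% c("Bowel_Small", "Bowel_Large"))
      pool <- setdiff(pool, "bowel")
    nm <- if (length(pool) == 1) pool else sample(pool, 1)
  }
  if (runif(1) < nameNoise$case)
    nm <- if (runif(1) < 0.5) toupper(nm) else tolower(nm)
  if (runif(1) < nameNoise$suffix)
    nm <- paste0(nm, sample(c(" 1", " 2", "_1", "_2", "-KS", " copy",
                              "_old"), 1))
  nm
}

#' Cohort generation config
#'
#' Bundles and validates the knobs of [generateCohort()]. Defaults emulate a
#' multi-center program: 40 centers of 5 patients, 8-12 planning/"other"
#' structures per patient (so "other" dominates the class distribution),
#' moderate naming noise, 6 mm geometric jitter, and half of the centers
#' using the ambiguous bare "bowel" label.
#'
#' @param disease `"prostate"` or `"lung"`.
#' @param nCenters,patientsPerCenter cohort size.
#' @param otherRange integer range (min, max) of "other" structures per
#'   patient.
#' @param ambiguityRate fraction of centers with the "bowel" ambiguity.
#' @param nameNoise list of probabilities: `case`, `abbrev`, `suffix`.
#' @param geometryJitter positional jitter sd (mm).
#' @param seed master seed; all substreams derive from it.
#' @return Validated config list of class `cohortConfig`.
#' @export
cohortConfig <- function(disease = "prostate", nCenters = 40L,
                         patientsPerCenter = 5L, otherRange = c(8L, 12L),
                         ambiguityRate = 0.5,
                         nameNoise = list(case = 0.15, abbrev = 0.10,
                                          suffix = 0.10),
                         geometryJitter = 6, seed = 1L) {
  stopifnot(disease %in% c("prostate", "lung"), nCenters >= 1,
            patientsPerCenter >= 1, length(otherRange) == 2,
            otherRange[1] >= 1, otherRange[2] >= otherRange[1],
            ambiguityRate >= 0, ambiguityRate <= 1,
            all(unlist(nameNoise) >= 0), all(unlist(nameNoise) <= 1))
  structure(list(disease = disease, nCenters = as.integer(nCenters),
    patientsPerCenter = as.integer(patientsPerCenter),
    otherRange = as.integer(otherRange), ambiguityRate = ambiguityRate,
    nameNoise = nameNoise, geometryJitter = geometryJitter,
    gridShape = c(96L, 96L, 48L), spacing = c(4, 4, 5),
    seed = as.integer(seed)), class = "cohortConfig")
}

#' Generate a multi-center synthetic cohort
#'
#' Draws a center naming profile per center, then per patient a phantom
#' (geometry stream) and physician-given names (naming stream). The two
#' streams are independent substreams of `config$seed`, so the manifest is
#' reproducible whether or not geometry is generated. Optionally writes
#' every patient to DICOM and the labels manifest to CSV.
#'
#' @param config a [cohortConfig()] list.
#' @param geometry generate phantom geometry and bone features (TRUE) or
#'   only names/labels (FALSE; much faster, for text-only work).
#' @param dicomPath if non-NULL, write DICOM CT + RT-STRUCT per patient
#'   under this directory plus `labels.csv` and `config.json`.
#' @return A [StructCohort-class].
#' @export
generateCohort <- function(config, geometry = TRUE, dicomPath = NULL) {
  stopifnot(inherits(config, "cohortConfig"))
  labelSet <- diseaseLabels(config$disease)
  labeled <- setdiff(classNames(labelSet), "other")
  man <- list()
  structures <- list()
  patientIds <- character(0)
  boneI <- list()
  box <- NULL
  d <- prod(config$gridShape)

  if (!is.null(dicomPath) &&
      !dir.exists(dicomPath) &&
      !dir.create(dicomPath, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dicomPath)

  for (i in seq_len(config$nCenters)) {
    centerId <- sprintf("VC%02d", i)
    profile <- withr::with_seed(
      .deriveSeed(config$seed, paste0("center_", i)),
      makeCenterProfile(config$disease, config$ambiguityRate))
    for (j in seq_len(config$patientsPerCenter)) {
      pid <- sprintf("%sP%02d", centerId, j)
      nameSeed <- .deriveSeed(config$seed, paste0("name_", i, "_", j))
      drawn <- withr::with_seed(nameSeed, {
        nOther <- sample(seq(config$otherRange[1], config$otherRange[2]), 1)
        nms <- vapply(labeled, sampleName, character(1), profile = profile,
                      nameNoise = config$nameNoise)
        oth <- vapply(seq_len(nOther), function(o)
          sampleName("other", profile, config$nameNoise), character(1))
        list(names = unname(c(nms, oth)), nOther = nOther)
      })
      ph <- generatePhantom(config$disease, pid,
        seed = .deriveSeed(config$seed, paste0("geom_", i, "_", j)),
        nOther = drawn$nOther, gridShape = config$gridShape,
        spacing = config$spacing, jitterSd = config$geometryJitter)
      recs <- records(ph$sset)
      stopifnot(length(recs) == length(drawn$names))
      for (r in seq_along(recs)) {
        rec <- recs[[r]]
        rec@givenName <- drawn$names[r]
        rec@centerId <- centerId
        recs[[r]] <- rec
        sid <- sprintf("%s_S%02d", pid, r)
        man[[length(man) + 1L]] <- data.frame(structure_id = sid,
          patient_id = pid, center_id = centerId,
          given_name = drawn$names[r], true_label = rec@trueLabel,
          stringsAsFactors = FALSE)
        structures[[length(structures) + 1L]] <- rec
      }
      if (geometry) {
        if (is.null(box)) box <- computeBoundingBox(ph$series)
        bone <- extractBonyAnatomy(ph$series, box, config$gridShape)
        boneI[[length(boneI) + 1L]] <- which(flattenVolume(bone) == 1L)
        patientIds <- c(patientIds, pid)
        if (!is.null(dicomPath))
          writeSyntheticDicom(ph$series,
                              StructureSet(recs, pid),
                              file.path(dicomPath, pid))
      } else {
        patientIds <- c(patientIds, pid)
      }
    }
  }
  manifest <- do.call(rbind, man)
  boneRows <- if (geometry && length(boneI)) {
    Matrix::sparseMatrix(
      i = rep(seq_along(boneI), lengths(boneI)),
      j = unlist(boneI), x = 1, dims = c(length(boneI), d))
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(0, d))
  }
  if (is.null(box)) {
    # nominal phantom box (geometry off): same for every patient by design
    origin <- -(config$gridShape - 1) * config$spacing / 2
    box <- BoundingBox(origin - config$spacing / 2,
                       origin + (config$gridShape - 0.5) * config$spacing)
  }
  if (!is.null(dicomPath)) {
    write.csv(manifest, file.path(dicomPath, "labels.csv"),
              row.names = FALSE)
    jsonlite::write_json(unclass(config), file.path(dicomPath,
      "config.json"), auto_unbox = TRUE, digits = NA)
  }
  new("StructCohort", manifest = manifest, structures = structures,
      boneRows = boneRows, patientIds = patientIds, box = box,
      gridShape = config$gridShape, labelSet = labelSet,
      disease = config$disease, config = unclass(config))
}

#' Sparse geometric feature matrix for a cohort
#'
#' Rasterizes every structure (rows follow the manifest) onto the cohort
#' grid and flattens; optionally concatenates the patient's bony-anatomy
#' block (doubling the width).
#'
#' @param cohort a [StructCohort-class] generated with geometry.
#' @param includeBone concatenate the bone block (default FALSE).
#' @return Sparse `Matrix` of 0/1, rows = structures.
#' @export
featurizeGeometry <- function(cohort, includeBone = FALSE) {
  d <- prod(cohort@gridShape)
  n <- length(cohort@structures)
  ii <- vector("list", n)
  for (r in seq_len(n)) {
    vol <- rasterizeStructure(cohort@structures[[r]], cohort@box,
                              cohort@gridShape)
    ii[[r]] <- which(flattenVolume(vol) == 1L)
  }
  X <- Matrix::sparseMatrix(i = rep(seq_len(n), lengths(ii)), j = unlist(ii),
                            x = 1, dims = c(n, d))
  if (includeBone) {
    if (nrow(cohort@boneRows) == 0)
      stop("cohort was generated without geometry: no bone features")
    pidx <- match(cohort@manifest$patient_id, cohort@patientIds)
    X <- cbind(X, cohort@boneRows[pidx, , drop = FALSE])
  }
  X
}
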