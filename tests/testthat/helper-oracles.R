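## Independent oracles and small fixture builders used across the suite.
## Each oracle re-derives the quantity with a different algorithm from the
## implementation it checks.

# brute-force even-odd point-in-polygon with true distance-to-segment
# boundary handling (boundary counts as inside)
oraclePointInPoly <- function(px, py, P) {
  n <- nrow(P)
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    xi <- P[i, 1]; yi <- P[i, 2]; xj <- P[j, 1]; yj <- P[j, 2]
    dx <- xj - xi; dy <- yj - yi
    L2 <- dx^2 + dy^2
    t <- if (L2 > 0) max(0, min(1, ((px - xi) * dx + (py - yi) * dy) / L2))
         else 0
    if (sqrt((px - (xi + t * dx))^2 + (py - (yi + t * dy))^2) <= 1e-9)
      return(TRUE)
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) * dx / dy
      if (px < xint) inside <- !inside
    }
  }
  inside
}

# rasterize by brute force: test every voxel centre of the grid in mm space
oracleRasterize <- function(polys, box, gridShape) {
  sz <- (box@maxCorner - box@minCorner) / gridShape
  centers <- lapply(1:3, function(a)
    box@minCorner[a] + (seq_len(gridShape[a]) - 0.5) * sz[a])
  out <- array(0L, gridShape)
  for (pg in polys) {
    k <- floor((pg$z - box@minCorner[3]) / sz[3]) + 1
    if (k < 1 || k > gridShape[3]) next
    for (i in seq_len(gridShape[1]))
      for (j in seq_len(gridShape[2]))
        if (!out[i, j, k] &&
            oraclePointInPoly(centers[[1]][i], centers[[2]][j], pg$points))
          out[i, j, k] <- 1L
  }
  out
}

# random simple (star-shaped) polygon around a centre
randomStarPolygon <- function(cx, cy, rMin, rMax, nVert = NULL) {
  if (is.null(nVert)) nVert <- sample(3:12, 1)
  th <- sort(runif(nVert, 0, 2 * pi))
  r <- runif(nVert, rMin, rMax)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# independent per-class TP/FP/FN tally + macro averaging over union labels
oracleMetrics <- function(truth, pred, classes) {
  present <- classes[classes %in% union(truth, pred)]
  pr <- re <- f1 <- numeric(length(present))
  for (i in seq_along(present)) {
    cl <- present[i]
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    pr[i] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    re[i] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[i] <- if (pr[i] + re[i] == 0) 0 else
      2 * pr[i] * re[i] / (pr[i] + re[i])
  }
  c(precision = mean(pr), recall = mean(re), f1 = mean(f1),
    accuracy = mean(truth == pred))
}

# random point on the probability simplex
randomSimplex <- function(k) {
  g <- rgamma(k, 1)
  g / sum(g)
}

# small uniform-HU image series fixture
makeSeries <- function(dims = c(8, 8, 4), spacing = c(1, 1, 1),
                       origin = c(0, 0, 0), hu = -1000L,
                       patientId = "fix01") {
  ImageSeries(array(as.integer(hu), dim = dims), origin = origin,
              spacing = spacing, patientId = patientId)
}

# single-polygon structure record
makeRecord <- function(points, z, name = "roi", label = NA_character_,
                       patientId = "fix01") {
  StructureRecord(name, list(list(z = z, points = points)),
                  trueLabel = label, patientId = patientId)
}

# absolute-difference expectation (printed-precision agreement)
expectWithin <- function(actual, want, tol = 0.005) {
  expect_lte(abs(actual - want), tol + 1e-12)
}

# MLB metrics computed through the real pipeline from per-class test counts
mlbMetricsFromCounts <- function(counts, labelSet) {
  truth <- rep(names(counts), counts)
  clf <- majorityLabelBaseline(truth, labelSet)
  computeMetrics(confusionCounts(truth, predict(clf, length(truth)),
                                 labelSet))
}

# balanced synthetic test counts for a target majority fraction and
# class count (the remaining mass spread evenly over the minority classes)
mlbCountsFor <- function(majorityFraction, labelSet, nPresent,
                         total = 1000L) {
  cn <- classNames(labelSet)
  minority <- setdiff(cn, "other")[seq_len(nPresent - 1)]
  nMaj <- round(majorityFraction * total)
  base <- (total - nMaj) %/% length(minority)
  extra <- (total - nMaj) %% length(minority)
  counts <- c(stats::setNames(rep(base, length(minority)), minority),
              other = nMaj)
  counts[seq_len(extra)] <- counts[seq_len(extra)] + 1
  counts
}
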