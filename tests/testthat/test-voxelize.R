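test_that("bounding box spans outer voxel corners", {
  s <- makeSeries(c(96, 96, 48), spacing = c(1, 1, 2), origin = c(0, 0, 0))
  box <- computeBoundingBox(s)
  expect_equal(box@minCorner, c(-0.5, -0.5, -1))
  expect_equal(box@maxCorner, c(95.5, 95.5, 95))

  expect_error(computeBoundingBox(makeSeries(c(4, 4, 1))),
               "degenerate extent")

  # corner-enumeration oracle on a random series
  withr::with_seed(7, {
    sp <- runif(3, 0.5, 3)
    o <- runif(3, -50, 50)
    dims <- c(5, 7, 4)
    s2 <- makeSeries(dims, spacing = sp, origin = o)
    b2 <- computeBoundingBox(s2)
    corners <- expand.grid(x = c(-0.5, dims[1] - 0.5),
                           y = c(-0.5, dims[2] - 0.5),
                           z = c(-0.5, dims[3] - 0.5))
    mm <- t(apply(corners, 1, function(cr) o + cr * sp))
    expect_equal(b2@minCorner, unname(apply(mm, 2, min)))
    expect_equal(b2@maxCorner, unname(apply(mm, 2, max)))
  })
})

test_that("rasterizer matches hand-counted squares and handles edge cases", {
  box <- BoundingBox(c(0, 0, 0), c(4, 4, 2))
  grid <- c(4L, 4L, 2L)
  # square strictly containing 4 voxel centres (1.5 and 2.5 per axis)
  rec <- makeRecord(cbind(c(1, 3, 3, 1), c(1, 1, 3, 3)), z = 0.5)
  v <- rasterizeStructure(rec, box, grid)
  expect_equal(sum(bits(v)), 4)
  expect_equal(which(bits(v)[, , 1] == 1L, arr.ind = TRUE),
               as.matrix(expand.grid(row = 2:3, col = 2:3)),
               ignore_attr = TRUE)

  # boundary voxel centres count as inside: corners on centres -> 3x3
  recB <- makeRecord(cbind(c(0.5, 2.5, 2.5, 0.5), c(0.5, 0.5, 2.5, 2.5)),
                     z = 0.5)
  expect_equal(sum(bits(rasterizeStructure(recB, box, grid))), 9)

  # empty contour list -> all zeros; <3 points -> warning and skip
  expect_equal(sum(bits(rasterizeStructure(
    StructureRecord("none", list()), box, grid))), 0)
  expect_warning(v2 <- rasterizeStructure(
    makeRecord(cbind(c(1, 3), c(1, 1)), 0.5), box, grid),
    "fewer than 3 points")
  expect_equal(sum(bits(v2)), 0)

  # contour outside the box in z is clipped silently
  expect_silent(v3 <- rasterizeStructure(
    makeRecord(cbind(c(1, 3, 3, 1), c(1, 1, 3, 3)), z = 99), box, grid))
  expect_equal(sum(bits(v3)), 0)

  # default grid flattens to the documented feature length
  ph <- generatePhantom("prostate", "vx01", seed = 2, nOther = 1)
  bigBox <- computeBoundingBox(ph$series)
  vol <- rasterizeStructure(records(ph$sset)[[5]], bigBox)
  expect_length(flattenVolume(vol), 442368)
})

test_that("rasterizer agrees with brute-force point-in-polygon oracle", {
  box <- BoundingBox(c(0, 0, 0), c(12, 12, 3))
  grid <- c(12L, 12L, 3L)
  withr::with_seed(42, {
    for (i in 1:40) {
      polys <- lapply(seq_len(sample(1:3, 1)), function(p)
        list(z = runif(1, 0, 3),
             points = randomStarPolygon(runif(1, 3, 9), runif(1, 3, 9),
                                        0.8, 4)))
      rec <- StructureRecord("r", polys)
      got <- bits(rasterizeStructure(rec, box, grid))
      want <- oracleRasterize(polys, box, grid)
      expect_identical(got, want)
    }
  })
})

test_that("enlarging a convex contour never loses voxels (monotonicity)", {
  box <- BoundingBox(c(0, 0, 0), c(20, 20, 2))
  grid <- c(20L, 20L, 2L)
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  withr::with_seed(9, {
    for (i in 1:10) {
      cx <- runif(1, 6, 14); cy <- runif(1, 6, 14)
      a <- runif(1, 1, 4); b <- runif(1, 1, 4)
      prev <- -1L
      for (s in c(0.5, 1, 1.5, 2)) {
        pts <- cbind(cx + s * a * cos(th), cy + s * b * sin(th))
        n <- sum(bits(rasterizeStructure(makeRecord(pts, 0.5), box, grid)))
        expect_gte(n, prev)
        prev <- n
      }
    }
  })
})

test_that("on-grid translation shifts the occupancy pattern identically", {
  box <- BoundingBox(c(0, 0, 0), c(20, 20, 2))
  grid <- c(20L, 20L, 2L)  # 1 mm pitch
  withr::with_seed(13, {
    pts <- randomStarPolygon(7, 7, 1, 4)
    v1 <- bits(rasterizeStructure(makeRecord(pts, 0.5), box, grid))[, , 1]
    v2 <- bits(rasterizeStructure(
      makeRecord(cbind(pts[, 1] + 3, pts[, 2] + 2), 0.5), box, grid))[, , 1]
    expect_identical(unname(v2[4:20, 3:20]), unname(v1[1:17, 1:18]))
  })
})

test_that("bone extraction thresholds strictly above 1300 HU", {
  s <- makeSeries(c(4, 4, 4), hu = -1000L)
  box <- computeBoundingBox(s)
  expect_equal(sum(bits(extractBonyAnatomy(s, box, c(4L, 4L, 4L)))), 0)

  for (hu in c(1299L, 1300L, 1301L)) {
    sv <- makeSeries(c(4, 4, 4), hu = hu)
    n <- sum(bits(extractBonyAnatomy(sv, box, c(4L, 4L, 4L))))
    expect_equal(n, if (hu > 1300) 64 else 0)
  }

  # random phantom vs independent nearest-neighbour resampling oracle
  withr::with_seed(21, {
    sr <- makeSeries(c(6, 5, 4), spacing = c(2, 3, 4), origin = c(-5, 0, 3))
    sr@voxels[] <- as.integer(sample(c(-1000L, 0L, 1400L, 1500L),
                                     prod(dim(sr@voxels)), replace = TRUE))
    bx <- computeBoundingBox(sr)
    gs <- c(9L, 7L, 5L)
    got <- bits(extractBonyAnatomy(sr, bx, gs))
    sz <- (bx@maxCorner - bx@minCorner) / gs
    want <- array(0L, gs)
    for (i in seq_len(gs[1])) for (j in seq_len(gs[2]))
      for (k in seq_len(gs[3])) {
        p <- bx@minCorner + (c(i, j, k) - 0.5) * sz
        idx <- c(floor((p[1:2] - sr@origin[1:2]) / sr@spacing[1:2] + 0.5)
                 + 1, which.min(abs(sr@slicePositions - p[3])))
        idx <- pmin(pmax(idx, 1), dim(sr@voxels))
        want[i, j, k] <- as.integer(
          sr@voxels[idx[1], idx[2], idx[3]] > 1300)
      }
    expect_identical(got, want)
  })
})

test_that("flatten order is x-fastest and exactly invertible", {
  box <- BoundingBox(c(0, 0, 0), c(3, 2, 2))
  withr::with_seed(4, {
    b <- array(sample(0:1, 3 * 2 * 2, replace = TRUE), c(3, 2, 2))
    vol <- new("BinaryVolume", bits = b, box = box)
    flat <- flattenVolume(vol)
    # x fastest, then y, then z (slice-major)
    expect_equal(flat[1:3], b[, 1, 1])
    expect_equal(flat[4:6], b[, 2, 1])
    expect_equal(flat[7:9], b[, 1, 2])
    back <- unflattenVolume(flat, c(3L, 2L, 2L), box)
    expect_identical(bits(back), array(as.integer(b), dim(b)))
  })
  expect_error(unflattenVolume(1:5, c(2L, 2L, 2L), box), "length mismatch")
})

test_that("structure + bone concatenation keeps both halves", {
  a <- c(1L, 0L, 1L, 1L)
  b <- c(0L, 0L, 1L, 0L)
  cc <- concatStructureAndBone(a, b)
  expect_length(cc, 8)
  expect_identical(cc[1:4], a)
  expect_identical(cc[5:8], b)
  expect_identical(concatStructureAndBone(a, rep(0L, 4))[5:8], rep(0L, 4))
  expect_error(concatStructureAndBone(a, 1:3), "length mismatch")
})
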