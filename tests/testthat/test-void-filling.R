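sphereCloud <- function(d = c(48, 48, 48), ctr = c(24, 24, 24), r = 14) {
  extractSurfacePoints(ctMask(makeBallArray(d, ctr, r)))
}

test_that("voxelizePoints dilates by an L1 ball", {
  p1 <- boundaryPoints(matrix(c(10L, 10L, 10L), 1))
  m0 <- voxelizePoints(p1, c(20, 20, 20), dilation = 0)
  expect_equal(sum(imgData(m0)), 1)
  m1 <- voxelizePoints(p1, c(20, 20, 20), dilation = 1)
  expect_equal(sum(imgData(m1)), 7)   # |{v : ||v||_1 <= 1}| = 7
  m2 <- voxelizePoints(p1, c(20, 20, 20), dilation = 2)
  expect_equal(sum(imgData(m2)), 25)  # L1 ball radius 2
  ## a sphere point cloud becomes one connected shell
  shell <- voxelizePoints(sphereCloud(), c(48, 48, 48), dilation = 1)
  lab <- GaborDictSeg:::labelComponents(imgData(shell) > 0.5)
  expect_length(attr(lab, "sizes"), 1L)
})

test_that("octree refines shell leaves to max depth and partitions the box", {
  shell <- voxelizePoints(sphereCloud(), c(48, 48, 48), dilation = 1)
  oc <- octreeDecompose(shell)
  lv <- oc@leaves
  ## partition: total leaf volume equals the root cube volume
  expect_equal(sum(as.numeric(lv$size)^3), as.numeric(oc@rootSize)^3)
  expect_true(all(lv$depth <= oc@maxDepth))
  ## every leaf intersecting the shell is at max depth (size 1)
  expect_true(all(lv$size[lv$intersects] == 1L))
  ## a known shell voxel lies in an intersecting finest leaf
  v <- boundaryCoords(sphereCloud())[1, ]
  hit <- lv$intersects & lv$x0 <= v[1] & lv$x0 + lv$size > v[1] &
    lv$y0 <= v[2] & lv$y0 + lv$size > v[2] &
    lv$z0 <= v[3] & lv$z0 + lv$size > v[3]
  expect_equal(sum(hit), 1L)
  ## an empty corner region is covered by one coarse leaf
  corner <- lv$x0 == 1 & lv$y0 == 1 & lv$z0 == 1
  expect_equal(sum(corner), 1L)
  expect_gt(lv$size[corner], 1L)
  expect_error(octreeDecompose(ctMask(array(0, c(8, 8, 8)))), "empty")
  expect_error(octreeDecompose(shell, maxDepth = 0), "maxDepth")
})

test_that("parity labels of a closed shell match the flood-fill oracle", {
  d <- c(32, 32, 32)
  shell <- voxelizePoints(sphereCloud(d, c(16, 16, 16), 9), d, dilation = 1)
  oc <- octreeDecompose(shell)
  lab <- suppressMessages(parityLabel(oc, shell))
  expect_equal(attr(lab, "mode"), "closed")
  oracle <- bruteExteriorFill(imgData(shell))
  expect_true(all((lab > 0) == !oracle))
})

test_that("an open shell is detected and filled by majority parity", {
  d <- c(48, 48, 48); ctr <- c(24, 24, 24); r <- 14
  sc <- boundaryCoords(sphereCloud(d, ctr, r))
  ang <- acos(pmin(1, pmax(-1, (sc[, 3] - ctr[3]) /
                             sqrt(rowSums(sweep(sc, 2, ctr)^2)))))
  open <- boundaryPoints(sc[ang > 15 * pi / 180, , drop = FALSE])
  shell <- voxelizePoints(open, d, dilation = 1)
  oc <- octreeDecompose(shell)
  msgs <- capture_messages(lab <- parityLabel(oc, shell))
  expect_match(paste(msgs, collapse = " "), "disagree")   # conflicts logged
  expect_equal(attr(lab, "mode"), "open")
  expect_gt(attr(lab, "conflicts"), 0)
  ## majority parity still recovers most of the enclosed ball
  ball <- makeBallArray(d, ctr, r)
  inside <- lab > 0
  expect_gt(sum(inside & ball == 1) / sum(ball), 0.85)
})

test_that("dual contouring produces watertight oriented meshes", {
  ## solid cube: watertight, genus 0, volume = cube volume
  d <- c(16, 16, 16)
  cube <- makeCubeArray(d, c(5, 5, 5), c(11, 11, 11))
  oc <- octreeDecompose(ctMask(cube))
  mesh <- dualContour(oc, cube)
  expect_true(isWatertight(mesh))
  expect_equal(eulerCharacteristic(mesh), 2L)
  expect_equal(meshComponents(mesh), 1L)
  expect_equal(meshVolume(mesh), 7^3, tolerance = 0.1)
  ## sphere: enclosed volume within 10% of the analytic ball
  db <- c(40, 40, 40); r <- 12
  ball <- makeBallArray(db, c(20, 20, 20), r)
  ocb <- octreeDecompose(ctMask(ball))
  mb <- dualContour(ocb, ball)
  expect_true(isWatertight(mb))
  expect_lt(abs(meshVolume(mb) - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.1)
  ## two disjoint blobs give two components
  two <- makeBallArray(db, c(11, 11, 11), 5) +
    makeBallArray(db, c(29, 29, 29), 5)
  oct <- octreeDecompose(ctMask(two))
  m2 <- dualContour(oct, two)
  expect_equal(meshComponents(m2), 2L)
  ## nothing to contour
  expect_error(dualContour(oc, array(0L, d)), "no sign changes")
})

test_that("fillVoids reconstructs a solid ball from its surface cloud", {
  d <- c(48, 48, 48); ctr <- c(24, 24, 24); r <- 14
  cloud <- sphereCloud(d, ctr, r)
  res <- suppressMessages(fillVoids(cloud, d))
  ball <- makeBallArray(d, ctr, r)
  expect_lt(voeOf(res$mask, ball), 10)
  expect_true(isWatertight(res$mesh))
  expect_equal(eulerCharacteristic(res$mesh), 2L)
  ## no interior cavities: exterior flood fill reaches every background voxel
  solid <- imgData(res$mask) > 0.5
  reach <- GaborDictSeg:::floodFromBorder(!solid)
  expect_true(all(reach | solid))
  ## solid contains its own interior erosion
  er <- GaborDictSeg:::erode6(solid)
  expect_true(all(solid[er]))
  ## idempotence of the geometric repair: refilling from the output surface
  ## (regularization off) changes the volume < 2%; with the default
  ## regularization each pass is a mild surface smoothing, so the change
  ## stays small but nonzero
  res0 <- suppressMessages(fillVoids(cloud, d, smoothWidth = 0))
  v0 <- sum(imgData(res0$mask))
  res0b <- suppressMessages(fillVoids(extractSurfacePoints(res0$mask), d,
                                      smoothWidth = 0))
  expect_lt(abs(sum(imgData(res0b$mask)) - v0) / v0, 0.02)
  res2 <- suppressMessages(fillVoids(extractSurfacePoints(res$mask), d))
  expect_lt(abs(sum(imgData(res2$mask)) - sum(solid)) / sum(solid), 0.08)
})

test_that("fillVoids repairs a deleted-cap sphere into a closed solid", {
  d <- c(48, 48, 48); ctr <- c(24, 24, 24); r <- 14
  sc <- boundaryCoords(sphereCloud(d, ctr, r))
  ang <- acos(pmin(1, pmax(-1, (sc[, 3] - ctr[3]) /
                             sqrt(rowSums(sweep(sc, 2, ctr)^2)))))
  open <- boundaryPoints(sc[ang > 15 * pi / 180, , drop = FALSE])
  res <- suppressMessages(fillVoids(open, d))
  expect_true(isWatertight(res$mesh))
  expect_equal(eulerCharacteristic(res$mesh), 2L)
  solid <- imgData(res$mask) > 0.5
  reach <- GaborDictSeg:::floodFromBorder(!solid)
  expect_true(all(reach | solid))
  expect_lt(abs(sum(solid) - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.15)
  expect_error(fillVoids(boundaryPoints(cbind(1:5, 1:5, 3L)), d),
               "degenerate")
})

test_that("pruning keeps on-surface points and drops outliers", {
  d <- c(48, 48, 48)
  cloud <- sphereCloud(d)
  res <- suppressMessages(fillVoids(cloud, d))
  kept <- pruneRedundantPoints(cloud, res$mesh, delta = 2)
  expect_equal(nElements(kept), nElements(cloud))   # all points on surface
  ## inject a far outlier
  noisy <- boundaryPoints(rbind(boundaryCoords(cloud), c(44L, 44L, 44L)),
                          source = "predicted")
  pruned <- pruneRedundantPoints(noisy, res$mesh, delta = 2)
  expect_equal(nElements(pruned), nElements(cloud))
  expect_false(any(apply(boundaryCoords(pruned), 1, identical,
                         c(44L, 44L, 44L))))
  expect_lte(nElements(pruned), nElements(noisy))
})

test_that("meshes export to readable ASCII STL and PLY", {
  res <- suppressMessages(fillVoids(sphereCloud(), c(48, 48, 48)))
  fs <- tempfile(fileext = ".stl"); fp <- tempfile(fileext = ".ply")
  writeMeshSTL(res$mesh, fs)
  writeMeshPLY(res$mesh, fp)
  stl <- readLines(fs)
  expect_equal(sum(grepl("^facet", stl)), nrow(meshFaces(res$mesh)))
  ply <- readLines(fp)
  expect_match(ply[1], "ply")
  nv <- as.integer(sub("element vertex ", "",
                       grep("element vertex", ply, value = TRUE)))
  expect_equal(nv, nrow(meshVertices(res$mesh)))
})
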