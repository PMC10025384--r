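test_that("a minimal two-triangle patch builds and validates", {
  m <- TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                    rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_equal(nVertices(m), 4L)
  expect_equal(nFaces(m), 2L)
  expect_equal(surfaceArea(m), 1)
})

test_that("mesh files round-trip losslessly through PLY and STL", {
  tube <- makeTube("straight", length = 30, r = 8, nAxial = 8, nCirc = 12)
  ply <- withr::local_tempfile(fileext = ".ply")
  writeMesh(tube$mesh, ply)
  m <- readMesh(ply)
  expect_equal(nVertices(m), nVertices(tube$mesh))
  expect_equal(nFaces(m), nFaces(tube$mesh))
  expect_lt(max(abs(meshVertices(m) - meshVertices(tube$mesh))), 1e-6)

  stl <- withr::local_tempfile(fileext = ".stl")
  writeMesh(tube$mesh, stl)
  m2 <- quietly(readMesh(stl))  # per-facet vertices merged on read
  expect_equal(nVertices(m2), nVertices(tube$mesh))
  expect_equal(nFaces(m2), nFaces(tube$mesh))
  expect_equal(surfaceArea(m2), surfaceArea(tube$mesh), tolerance = 1e-9)
})

test_that("duplicated vertices are merged and degenerate faces dropped", {
  # square patch with 3 exact duplicates and one zero-area face
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  f <- rbind(c(1, 2, 3), c(5, 7, 4), c(5, 6, 2))  # last face has zero area
  expect_message(m <- TriangleMesh(v, f), "merged 3 duplicate")
  expect_equal(nVertices(m), 4L)
  expect_equal(nFaces(m), 2L)
})

test_that("malformed mesh input is rejected with a clear error", {
  bad <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property double x", "property double y", "property double z",
               "element face 1",
               "property list uchar int vertex_indices", "end_header",
               "0 0 0", "1 0 0", "1 1 0", "4 0 1 2 2"), bad)
  expect_error(readMesh(bad), "non-triangular face #1")
  expect_error(readMesh("does-not-exist.stl"), "cannot read")
  empty <- withr::local_tempfile(fileext = ".obj")
  writeLines("# nothing", empty)
  expect_error(readMesh(empty))
})

test_that("boundary loop census matches tube topology", {
  # closed surface: octahedron has no boundary
  oct <- TriangleMesh(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                            c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)),
                      rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
                            c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6)))
  expect_length(boundaryLoops(oct), 0L)

  tube <- makeTube("straight", length = 50, r = 15, nAxial = 10, nCirc = 64)
  loops <- boundaryLoops(tube$mesh)
  expect_length(loops, 2L)
  for (l in loops)
    expect_equal(l@perimeter, 2 * pi * 15, tolerance = 0.01)
  # loops sorted by descending perimeter
  expect_true(diff(vapply(loops, function(l) l@perimeter, numeric(1))) <= 0)

  # capping one end leaves a single loop
  capped <- local({
    V <- meshVertices(tube$mesh); Fc <- meshFaces(tube$mesh)
    ring <- boundaryLoops(tube$mesh)[[2]]@indices
    apex <- nrow(V) + 1L
    V <- rbind(V, boundaryLoops(tube$mesh)[[2]]@centroid)
    fan <- cbind(ring, c(ring[-1], ring[1]), apex)
    TriangleMesh(V, rbind(Fc, fan), clean = FALSE)
  })
  expect_length(boundaryLoops(capped), 1L)
})

test_that("boundary loops run counter-clockwise about the outward normal", {
  tube <- makeTube("straight", length = 40, r = 10, nAxial = 8, nCirc = 16)
  for (l in boundaryLoops(tube$mesh)) {
    pts <- meshVertices(tube$mesh)[l@indices, ]
    u <- pts[1, ] - l@centroid
    v <- pts[2, ] - l@centroid
    cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    expect_gt(sum(cr * l@normal), 0)
  }
})

test_that("plane cuts split cleanly and conserve surface area", {
  tube <- makeTube("straight", length = 100, r = 15, nAxial = 21, nCirc = 24)
  pl <- Plane(c(0, 0, 50.5), c(0, 0, 1))   # between vertex rings
  top <- planeCut(tube$mesh, pl, "positive")
  bot <- planeCut(tube$mesh, pl, "negative")
  expect_equal(surfaceArea(top) + surfaceArea(bot), surfaceArea(tube$mesh),
               tolerance = 1e-9)
  expect_equal(range(meshVertices(top)[, 3]), c(50.5, 100), tolerance = 1e-9)
  # kept side had one boundary loop and gains exactly one more at the cut
  expect_length(boundaryLoops(top), 2L)
  newLoop <- Filter(function(l) abs(l@centroid[3] - 50.5) < 1e-6,
                    boundaryLoops(top))
  expect_length(newLoop, 1L)
  # new boundary lies in the cut plane
  zs <- meshVertices(top)[newLoop[[1]]@indices, 3]
  expect_lt(max(abs(zs - 50.5)), 1e-6)
})

test_that("a plane missing the mesh is an empty-result error", {
  tube <- makeTube("straight", length = 20, r = 5, nAxial = 4, nCirc = 8)
  expect_error(planeCut(tube$mesh, Plane(c(0, 0, 100), c(0, 0, 1)),
                        "positive"),
               "empty result")
})

test_that("cutting a curved tube gives a contour centered on its centerline", {
  tor <- makeTube("torus", R = 40, r = 15, theta = pi, nAxial = 60,
                  nCirc = 24)
  # cut perpendicular to the centerline at phi = pi/2, keep one side
  p0 <- c(0, 40, 0)
  normal <- c(-1, 0, 0)  # tangent direction at phi = pi/2
  part <- quietly(planeCut(tor$mesh, Plane(p0, normal), "positive"))
  loops <- boundaryLoops(part)
  newLoop <- loops[[which.min(vapply(loops, function(l)
    sum((l@centroid - p0)^2), numeric(1)))]]
  expect_lt(sqrt(sum((newLoop@centroid - p0)^2)), 0.5)
})

test_that("feature tables round-trip and enforce their schema", {
  tab <- data.frame(patient_id = c("a", "b"),
                    D = c(48.123456789, 52.1), DCR = c(0.5, 0.41),
                    EILR = c(2.2, 1 / 3), T = c(1.2, 1.07))
  f <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(tab, f)
  back <- readFeatureTable(f)
  for (cn in c("D", "DCR", "EILR", "T"))
    expect_equal(back[[cn]], tab[[cn]], tolerance = 1e-12)

  empty <- tab[0, ]
  writeFeatureTable(empty, f)
  expect_equal(nrow(readFeatureTable(f)), 0L)

  noDt <- data.frame(patient_id = "a", D = 48, DCR = 0.5, EILR = 2.2,
                     T = 1.2)
  writeFeatureTable(noDt, f)
  expect_error(readGrowthTable(f), "dt_months")
})
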