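# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtureCache[[name]]))
    .fixtureCache[[name]] <- builder()
  .fixtureCache[[name]]
}

quietly <- function(expr) suppressWarnings(suppressMessages(expr))

# A cylinder fixture with extracted centerline and isolated domain.
cylinderFixture <- function() fixture("cylinder", function() {
  tube <- makeTube("straight", length = 100, r = 15, nAxial = 50, nCirc = 32)
  cl <- extractCenterline(tube$mesh)
  dom <- isolateAscending(tube$mesh, cl, ostiumArc = centerlineLength(cl))
  list(tube = tube, cl = cl, dom = dom)
})

# Half-torus tube (R = 40 mm, r = 15 mm, sweep pi) with analytic values.
torusFixture <- function() fixture("torus", function() {
  tube <- makeTube("torus", R = 40, r = 15, theta = pi,
                   nAxial = 100, nCirc = 48)
  cl <- extractCenterline(tube$mesh)
  dom <- isolateAscending(tube$mesh, cl, ostiumArc = centerlineLength(cl))
  icl <- smoothPath(dom, shortestGeodesic(dom))
  secs <- quietly(extractSections(dom, n = 100))
  ecl <- externalLine(dom, secs, icl)
  list(tube = tube, cl = cl, dom = dom, icl = icl, secs = secs, ecl = ecl)
})

# Tiny tube for brute-force graph oracles (~40 vertices).
tinyTubeDomain <- function(nAxial = 4, nCirc = 8, length = 20, r = 5) {
  tube <- makeTube("straight", length = length, r = r,
                   nAxial = nAxial, nCirc = nCirc)
  loops <- boundaryLoops(tube$mesh)
  cl <- aortamorph:::.makeCenterline(
    rbind(loops[[1]]@centroid, loops[[2]]@centroid), c(r, r))
  methods::new("AAoDomain", surface = tube$mesh, centerline = cl,
               annulus = loops[[1]], ostium = loops[[2]])
}

# Random convex polygon (3-D, in the z = 0 plane) containing the origin.
randomConvexContour <- function(nPts = 40, rMin = 8, rMax = 25) {
  ang <- sort(stats::runif(nPts, 0, 2 * pi))
  rad <- stats::runif(nPts, rMin, rMax)
  pts <- cbind(rad * cos(ang), rad * sin(ang))
  hull <- grDevices::chull(pts)
  pts <- pts[hull[length(hull):1], , drop = FALSE]  # counter-clockwise
  cbind(pts, 0)
}

rigidTransform <- function(pts, angles = c(0.4, -0.7, 1.1),
                           shift = c(12, -5, 30)) {
  rx <- matrix(c(1, 0, 0, 0, cos(angles[1]), -sin(angles[1]),
                 0, sin(angles[1]), cos(angles[1])), 3, byrow = TRUE)
  ry <- matrix(c(cos(angles[2]), 0, sin(angles[2]), 0, 1, 0,
                 -sin(angles[2]), 0, cos(angles[2])), 3, byrow = TRUE)
  rz <- matrix(c(cos(angles[3]), -sin(angles[3]), 0,
                 sin(angles[3]), cos(angles[3]), 0, 0, 0, 1), 3, byrow = TRUE)
  sweep(pts %*% t(rz %*% ry %*% rx), 2, shift, "+")
}

transformMesh <- function(mesh, ...) {
  TriangleMesh(rigidTransform(meshVertices(mesh), ...), meshFaces(mesh),
               clean = FALSE)
}
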