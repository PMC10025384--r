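#' Isolate the ascending aorta between annulus and ostium
#'
#' Cuts the full surface with two planes perpendicular to the centerline —
#' one at the annulus (arc length `annulusArc`, proximal end) and one at
#' the brachiocephalic-trunk ostium — keeps the tube segment between them,
#' and clips the centerline to the same extent. The ostium is a required
#' user landmark (a 3-D point near the surface, or an arc length along the
#' centerline); everything else is automatic. The Valsalva sinuses are
#' part of the kept segment: the annulus cut is the proximal end of the
#' analysis domain.
#'
#' Cut-plane normals are the centerline tangents estimated by central
#' differences. If a cut separates the mesh into several components, the
#' component containing the mid-segment is kept.
#'
#' @param mesh full [TriangleMesh-class] (e.g. whole thoracic aorta).
#' @param centerline full [Centerline-class] of the same vessel.
#' @param annulusArc arc length (mm) of the annulus cut; default 0
#'   (the inlet end).
#' @param ostiumPoint 3-D point marking the ostium; must lie within 2
#'   maximal tube radii of the surface. The cut is placed at the
#'   centerline point nearest to it. Alternative: give `ostiumArc`.
#' @param ostiumArc arc length (mm) of the ostium cut (overrides
#'   `ostiumPoint`).
#' @return An [AAoDomain-class] with exactly two boundary loops (annulus
#'   and ostium) and the clipped centerline.
#' @examples
#' tube <- makeTube("torus", R = 40, r = 12, theta = pi,
#'                  nAxial = 60, nCirc = 24)
#' cl <- extractCenterline(tube$mesh)
#' dom <- isolateAscending(tube$mesh, cl, annulusArc = 0,
#'                         ostiumArc = centerlineLength(cl))
#' @export
isolateAscending <- function(mesh, centerline, annulusArc = 0,
                             ostiumPoint = NULL, ostiumArc = NULL) {
  L <- centerlineLength(centerline)
  if (annulusArc < 0 || annulusArc >= L)
    stop("annulusArc must lie within the centerline range [0, ", round(L, 1), ")")
  rad <- centerline@radius
  maxR <- if (all(is.na(rad))) Inf else max(rad, na.rm = TRUE)
  if (is.null(ostiumArc)) {
    if (is.null(ostiumPoint))
      stop("supply the ostium landmark: ostiumPoint or ostiumArc")
    dSurf <- .closestPointOnMesh(mesh, matrix(ostiumPoint, 1))$dist
    if (is.finite(maxR) && dSurf > 2 * maxR)
      stop("ostiumPoint is ", round(dSurf, 1),
           " mm from the surface (limit 2 tube radii = ",
           round(2 * maxR, 1), " mm)")
    dC <- .rowNorms(sweep(centerline@points, 2, ostiumPoint))
    ostiumArc <- centerline@arcLength[which.min(dC)]
  }
  if (ostiumArc <= annulusArc)
    stop("ostium cut lies upstream of the annulus cut along the centerline")
  ostiumArc <- min(ostiumArc, L)

  tang <- .centerlineTangents(centerline)
  pA <- .centerlinePointAt(centerline, annulusArc)
  nA <- .centerlineTangentAt(centerline, tang, annulusArc)
  pO <- .centerlinePointAt(centerline, ostiumArc)
  nO <- .centerlineTangentAt(centerline, tang, ostiumArc)
  pMid <- .centerlinePointAt(centerline, (annulusArc + ostiumArc) / 2)

  cut <- mesh
  if (annulusArc > 0) {
    cut <- withCallingHandlers(
      planeCut(cut, Plane(pA, nA), "positive"),
      warning = function(w) invokeRestart("muffleWarning"))
    cut <- .selectComponent(cut, pMid)
  }
  if (ostiumArc < L) {
    cut <- withCallingHandlers(
      planeCut(cut, Plane(pO, nO), "negative"),
      warning = function(w) invokeRestart("muffleWarning"))
    cut <- .selectComponent(cut, pMid)
  }
  clClip <- .clipCenterline(centerline, annulusArc, ostiumArc)
  loops <- boundaryLoops(cut)
  if (length(loops) != 2L)
    stop("topology error: kept component has ", length(loops),
         " boundary loops (expected 2)")
  cA <- vapply(loops, function(l) sqrt(sum((l@centroid - pA)^2)), numeric(1))
  annulus <- loops[[which.min(cA)]]
  ostium <- loops[[which.max(cA)]]
  ends <- clClip@points[c(1, nrow(clClip@points)), , drop = FALSE]
  dEnds <- c(sqrt(sum((ends[1, ] - annulus@centroid)^2)),
             sqrt(sum((ends[2, ] - ostium@centroid)^2)))
  if (any(dEnds > 2 + 0.05 * max(annulus@perimeter, ostium@perimeter) / pi))
    warning("clipped centerline endpoints are ",
            paste(round(dEnds, 2), collapse = "/"),
            " mm from the cut-loop centroids; check the cuts")
  new("AAoDomain", surface = cut, centerline = clClip,
      annulus = annulus, ostium = ostium)
}

.centerlineTangents <- function(centerline) {
  p <- centerline@points
  n <- nrow(p)
  t <- rbind(p[2, ] - p[1, ],
             p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE],
             p[n, ] - p[n - 1, ])
  t / .rowNorms(t)
}

.centerlinePointAt <- function(centerline, arc) {
  s <- centerline@arcLength
  vapply(1:3, function(d)
    stats::approx(s, centerline@points[, d], xout = arc)$y, numeric(1))
}

.centerlineTangentAt <- function(centerline, tang, arc) {
  s <- centerline@arcLength
  v <- vapply(1:3, function(d) stats::approx(s, tang[, d], xout = arc)$y,
              numeric(1))
  .unit(v)
}

# Clip a centerline to the arc interval [a, b], inserting interpolated
# endpoints; arc length restarts at 0.
.clipCenterline <- function(centerline, a, b) {
  s <- centerline@arcLength
  inner <- which(s > a & s < b)
  sNew <- c(a, s[inner], b)
  sNew <- unique(sNew)
  pts <- vapply(1:3, function(d)
    stats::approx(s, centerline@points[, d], xout = sNew)$y,
    numeric(length(sNew)))
  pts <- matrix(pts, ncol = 3)
  rad <- if (all(is.na(centerline@radius))) rep(NA_real_, length(sNew)) else
    stats::approx(s, centerline@radius, xout = sNew)$y
  .makeCenterline(pts, rad)
}
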