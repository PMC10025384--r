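#' @import methods
NULL

#' Oriented plane in 3-D
#'
#' A plane given by a point on it and a unit normal. Used for mesh cuts and
#' cross-sections perpendicular to the centerline.
#'
#' @slot point numeric(3), a point on the plane (mm).
#' @slot normal numeric(3), unit normal (|n| = 1 within 1e-9).
#' @export
setClass("Plane", representation(point = "numeric", normal = "numeric"),
         validity = function(object) {
           if (length(object@point) != 3L || length(object@normal) != 3L)
             return("point and normal must be length-3 numeric")
           if (any(!is.finite(object@point)) || any(!is.finite(object@normal)))
             return("non-finite plane coordinates")
           if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
             return("plane normal must be unit length (|n| = 1 within 1e-9)")
           TRUE
         })

#' Construct a Plane
#'
#' @param point numeric(3) point on the plane (mm).
#' @param normal numeric(3) normal direction; normalized internally.
#' @return A [Plane-class] object.
#' @examples
#' Plane(c(0, 0, 50), c(0, 0, 2))
#' @export
Plane <- function(point, normal) {
  nrm <- sqrt(sum(normal^2))
  if (!is.finite(nrm) || nrm < 1e-12)
    stop("plane normal must be a non-zero vector")
  new("Plane", point = as.numeric(point), normal = as.numeric(normal) / nrm)
}

#' Triangulated surface mesh
#'
#' The segmented luminal surface: a set of 3-D vertices (mm) and triangular
#' faces indexing them. Meshes used for feature extraction are expected to be
#' edge-manifold, single-component open surfaces (cut ends give boundary
#' loops).
#'
#' @slot vertices numeric matrix, n x 3 (mm).
#' @slot faces integer matrix, m x 3, 1-based vertex indices.
#' @export
setClass("TriangleMesh",
         representation(vertices = "matrix", faces = "matrix"),
         validity = function(object) {
           v <- object@vertices; f <- object@faces
           if (ncol(v) != 3L) return("vertices must be an n x 3 matrix")
           if (ncol(f) != 3L) return("faces must be an m x 3 matrix")
           if (nrow(v) < 3L || nrow(f) < 1L) return("empty mesh")
           if (any(!is.finite(v))) return("non-finite vertex coordinates")
           if (any(f < 1L) || any(f > nrow(v)))
             return("face indices out of range")
           if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
             return("degenerate face (repeated vertex index)")
           TRUE
         })

#' Construct (and clean) a TriangleMesh
#'
#' Duplicate vertices within `mergeTol` are merged and zero-area faces
#' dropped; counts are reported via `message()` when anything was cleaned.
#' STL files store each facet's corners independently, so merging is
#' mandatory before any graph algorithm runs on the mesh.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 index matrix (1-based).
#' @param mergeTol vertex-merge tolerance in mm (default 1e-6).
#' @param clean logical; merge duplicates and drop degenerate faces.
#' @return A [TriangleMesh-class].
#' @examples
#' m <- TriangleMesh(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)),
#'                   rbind(c(1,2,3), c(1,3,4)))
#' nFaces(m)
#' @export
TriangleMesh <- function(vertices, faces, mergeTol = 1e-6, clean = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (clean) {
    n0 <- nrow(vertices); m0 <- nrow(faces)
    key <- paste(round(vertices[, 1] / mergeTol),
                 round(vertices[, 2] / mergeTol),
                 round(vertices[, 3] / mergeTol))
    first <- !duplicated(key)
    map <- match(key, key[first])
    vertices <- vertices[first, , drop = FALSE]
    faces <- matrix(map[faces], ncol = 3L)
    storage.mode(faces) <- "integer"
    bad <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    a <- .faceAreas(vertices, faces)
    bad <- bad | a <= .Machine$double.eps
    faces <- faces[!bad, , drop = FALSE]
    used <- sort(unique(as.vector(faces)))
    if (length(used) < nrow(vertices)) {
      remap <- integer(nrow(vertices)); remap[used] <- seq_along(used)
      vertices <- vertices[used, , drop = FALSE]
      faces <- matrix(remap[faces], ncol = 3L)
      storage.mode(faces) <- "integer"
    }
    merged <- n0 - nrow(vertices); dropped <- m0 - nrow(faces)
    if (merged > 0L || dropped > 0L)
      message(sprintf("mesh cleanup: merged %d duplicate vertices, dropped %d degenerate faces",
                      merged, dropped))
  }
  new("TriangleMesh", vertices = vertices, faces = faces)
}

#' Ordered boundary loop of an open mesh
#'
#' A closed sequence of vertices along edges incident to exactly one face,
#' e.g. the annulus or ostium ring of a cut ascending aorta. Loops are
#' oriented counter-clockwise about the outward best-fit-plane normal.
#'
#' @slot indices integer vertex indices, ordered, closed implicitly
#'   (last connects to first).
#' @slot centroid numeric(3) loop centroid (mm).
#' @slot normal numeric(3) outward best-fit plane normal (unit).
#' @slot perimeter numeric(1) loop perimeter (mm).
#' @export
setClass("BoundaryLoop",
         representation(indices = "integer", centroid = "numeric",
                        normal = "numeric", perimeter = "numeric"),
         validity = function(object) {
           if (length(object@indices) < 3L) return("loop needs >= 3 vertices")
           if (anyDuplicated(object@indices)) return("loop revisits a vertex")
           TRUE
         })

#' Lumen centerline
#'
#' Ordered medial polyline of a tubular mesh with cumulative arc length and
#' the maximal-inscribed-sphere radius at each point. The first point is the
#' inlet (annulus side), the last the outlet (ostium side).
#'
#' @slot points n x 3 numeric matrix (mm).
#' @slot arcLength numeric(n), cumulative arc length, strictly increasing,
#'   starting at 0 (mm).
#' @slot radius numeric(n), inscribed radius at each point (mm); may be NA
#'   for centerlines imported without a companion mesh.
#' @export
setClass("Centerline",
         representation(points = "matrix", arcLength = "numeric",
                        radius = "numeric"),
         validity = function(object) {
           p <- object@points
           if (ncol(p) != 3L || nrow(p) < 2L)
             return("centerline needs >= 2 points in 3-D")
           if (length(object@arcLength) != nrow(p))
             return("arcLength length mismatch")
           if (any(diff(object@arcLength) <= 0))
             return("arc length must be strictly increasing")
           if (abs(object@arcLength[1]) > 1e-12)
             return("arc length must start at 0")
           r <- object@radius
           if (length(r) != nrow(p)) return("radius length mismatch")
           if (!all(is.na(r)) && any(!is.na(r) & r <= 0))
             return("inscribed radius must be > 0")
           TRUE
         })

.makeCenterline <- function(points, radius = rep(NA_real_, nrow(points))) {
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  new("Centerline", points = points, arcLength = c(0, cumsum(seg)),
      radius = as.numeric(radius))
}

#' Ascending-aorta analysis domain
#'
#' The open tube between the annulus cut and the brachiocephalic-trunk
#' ostium cut: surface, clipped centerline, and the two labeled boundary
#' loops.
#'
#' @slot surface [TriangleMesh-class], open tube with exactly two boundary
#'   loops.
#' @slot centerline [Centerline-class] clipped to the same extent.
#' @slot annulus,ostium [BoundaryLoop-class] proximal / distal rings.
#' @export
setClass("AAoDomain",
         representation(surface = "TriangleMesh", centerline = "Centerline",
                        annulus = "BoundaryLoop", ostium = "BoundaryLoop"))

#' Perpendicular cross-section of the lumen
#'
#' The closed intersection contour of the surface with a plane perpendicular
#' to the centerline at station k, its center (centerline point), and the
#' rotating-sweep maximum diameter with the chord endpoints achieving it.
#'
#' @slot index integer station index k.
#' @slot center numeric(3), intersection of the section plane with the
#'   centerline (mm).
#' @slot plane [Plane-class] of the section.
#' @slot contour p x 3 matrix, ordered closed in-plane polyline (mm); the
#'   last point connects back to the first.
#' @slot maxDiameter numeric(1), the sweep maximum diameter (mm).
#' @slot chordEndpoints 2 x 3 matrix, endpoints of the maximal chord.
#' @export
setClass("PlaneSection",
         representation(index = "integer", center = "numeric",
                        plane = "Plane", contour = "matrix",
                        maxDiameter = "numeric", chordEndpoints = "matrix"))

#' Internal or external curvature line
#'
#' The internal curvature line (ICL) is the smoothed shortest discrete
#' geodesic on the surface between the annulus and ostium boundaries; the
#' external curvature line (ECL) is the spline through the ray-cast surface
#' points diametrically opposite the ICL through the centerline.
#'
#' @slot kind "internal" or "external".
#' @slot points n x 3 matrix of polyline points (mm).
#' @slot length numeric(1) polyline length (mm).
#' @slot rawPath integer mesh-vertex path before smoothing (internal only).
#' @slot anchors k x 3 matrix of per-section anchor points (external only).
#' @export
setClass("CurvatureLine",
         representation(kind = "character", points = "matrix",
                        length = "numeric", rawPath = "integer",
                        anchors = "matrix"),
         validity = function(object) {
           if (!object@kind %in% c("internal", "external"))
             return("kind must be 'internal' or 'external'")
           if (object@length <= 0) return("curve length must be > 0")
           TRUE
         })

#' Binary confusion matrix
#'
#' Counts for the two-class growth-risk problem; "fast" growth is the
#' positive class.
#'
#' @slot tp,tn,fp,fn non-negative integer counts.
#' @export
setClass("ConfusionMatrix",
         representation(tp = "integer", tn = "integer",
                        fp = "integer", fn = "integer"),
         validity = function(object) {
           k <- c(object@tp, object@tn, object@fp, object@fn)
           if (length(k) != 4L || any(is.na(k)) || any(k < 0L))
             return("counts must be non-negative integers")
           TRUE
         })

#' Construct a ConfusionMatrix
#' @param tp,tn,fp,fn non-negative integer counts (positive class = fast
#'   growth).
#' @return A [ConfusionMatrix-class].
#' @examples
#' ConfusionMatrix(tp = 5, tn = 38, fp = 3, fn = 4)
#' @export
ConfusionMatrix <- function(tp, tn, fp, fn)
  new("ConfusionMatrix", tp = as.integer(tp), tn = as.integer(tn),
      fp = as.integer(fp), fn = as.integer(fn))

#' Leave-one-out classification report
#'
#' Pooled held-out results for one classifier on one feature subset:
#' confusion matrix, accuracy/sensitivity/specificity, diagnostic
#' likelihood ratios and AUROC, plus the per-patient held-out scores.
#'
#' @slot model one of "dt", "ld", "lr", "nb", "svm", "knn".
#' @slot features character vector of feature names used.
#' @slot confusion [ConfusionMatrix-class].
#' @slot accuracy,sensitivity,specificity fractions in [0, 1].
#' @slot lhrPos,lhrNeg likelihood ratios; `Inf` allowed, `NA` = undefined.
#' @slot auroc area under the ROC of the pooled held-out scores.
#' @slot scores numeric per-patient held-out scores (higher = more likely
#'   fast growth).
#' @slot predicted factor of held-out class predictions.
#' @slot prevalence observed fraction of fast-growth patients.
#' @export
setClass("ClassifierReport",
         representation(model = "character", features = "character",
                        confusion = "ConfusionMatrix",
                        accuracy = "numeric", sensitivity = "numeric",
                        specificity = "numeric", lhrPos = "numeric",
                        lhrNeg = "numeric", auroc = "numeric",
                        scores = "numeric", predicted = "factor",
                        prevalence = "numeric"))
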