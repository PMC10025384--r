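#' @include AllClasses.R
NULL

#' Accessors for geometry objects
#'
#' `meshVertices()`/`meshFaces()` return the raw matrices of a
#' [TriangleMesh-class]; `nVertices()`/`nFaces()` their row counts;
#' `surfaceArea()` the total triangle area (mm^2);
#' `centerlinePoints()`, `arcLengths()`, `inscribedRadii()` and
#' `centerlineLength()` expose a [Centerline-class];
#' `curveLength()` the length of a [CurvatureLine-class];
#' `lineKind()` its kind.
#'
#' @param x the object.
#' @return Matrix, numeric vector or scalar as described.
#' @examples
#' tube <- makeTube("straight", length = 40, r = 10, nAxial = 10, nCirc = 16)
#' nVertices(tube$mesh)
#' surfaceArea(tube$mesh)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))
#' @rdname accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname accessors
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))
#' @rdname accessors
#' @export
setGeneric("surfaceArea", function(x) standardGeneric("surfaceArea"))
#' @rdname accessors
#' @export
setGeneric("centerlinePoints", function(x) standardGeneric("centerlinePoints"))
#' @rdname accessors
#' @export
setGeneric("arcLengths", function(x) standardGeneric("arcLengths"))
#' @rdname accessors
#' @export
setGeneric("inscribedRadii", function(x) standardGeneric("inscribedRadii"))
#' @rdname accessors
#' @export
setGeneric("centerlineLength", function(x) standardGeneric("centerlineLength"))
#' @rdname accessors
#' @export
setGeneric("curveLength", function(x) standardGeneric("curveLength"))
#' @rdname accessors
#' @export
setGeneric("lineKind", function(x) standardGeneric("lineKind"))

#' @rdname accessors
#' @export
setMethod("meshVertices", "TriangleMesh", function(x) x@vertices)
#' @rdname accessors
#' @export
setMethod("meshFaces", "TriangleMesh", function(x) x@faces)
#' @rdname accessors
#' @export
setMethod("nVertices", "TriangleMesh", function(x) nrow(x@vertices))
#' @rdname accessors
#' @export
setMethod("nFaces", "TriangleMesh", function(x) nrow(x@faces))
#' @rdname accessors
#' @export
setMethod("surfaceArea", "TriangleMesh",
          function(x) sum(.faceAreas(x@vertices, x@faces)))
#' @rdname accessors
#' @export
setMethod("centerlinePoints", "Centerline", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("arcLengths", "Centerline", function(x) x@arcLength)
#' @rdname accessors
#' @export
setMethod("inscribedRadii", "Centerline", function(x) x@radius)
#' @rdname accessors
#' @export
setMethod("centerlineLength", "Centerline",
          function(x) x@arcLength[length(x@arcLength)])
#' @rdname accessors
#' @export
setMethod("curveLength", "CurvatureLine", function(x) x@length)
#' @rdname accessors
#' @export
setMethod("lineKind", "CurvatureLine", function(x) x@kind)

#' Accessors for an AAoDomain
#'
#' @param x an [AAoDomain-class].
#' @return The surface mesh, clipped centerline, or a boundary loop.
#' @name domain-accessors
NULL

#' @rdname domain-accessors
#' @export
setGeneric("domainSurface", function(x) standardGeneric("domainSurface"))
#' @rdname domain-accessors
#' @export
setGeneric("domainCenterline", function(x) standardGeneric("domainCenterline"))
#' @rdname domain-accessors
#' @export
setGeneric("annulusLoop", function(x) standardGeneric("annulusLoop"))
#' @rdname domain-accessors
#' @export
setGeneric("ostiumLoop", function(x) standardGeneric("ostiumLoop"))
#' @rdname domain-accessors
#' @export
setMethod("domainSurface", "AAoDomain", function(x) x@surface)
#' @rdname domain-accessors
#' @export
setMethod("domainCenterline", "AAoDomain", function(x) x@centerline)
#' @rdname domain-accessors
#' @export
setMethod("annulusLoop", "AAoDomain", function(x) x@annulus)
#' @rdname domain-accessors
#' @export
setMethod("ostiumLoop", "AAoDomain", function(x) x@ostium)

#' Confusion-matrix counts
#'
#' @param x a [ConfusionMatrix-class].
#' @return Named integer vector `c(tp, tn, fp, fn)`.
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
#' @rdname confusionCounts
#' @export
setMethod("confusionCounts", "ConfusionMatrix",
          function(x) c(tp = x@tp, tn = x@tn, fp = x@fp, fn = x@fn))

setMethod("show", "TriangleMesh", function(object) {
  nb <- tryCatch(length(boundaryLoops(object)), error = function(e) NA_integer_)
  cat(sprintf("TriangleMesh: %d vertices, %d faces, %s boundary loop(s), area %.1f mm^2\n",
              nrow(object@vertices), nrow(object@faces),
              ifelse(is.na(nb), "?", nb), surfaceArea(object)))
})

setMethod("show", "Centerline", function(object) {
  r <- object@radius
  cat(sprintf("Centerline: %d points, length %.2f mm, chord %.2f mm, radius %s mm\n",
              nrow(object@points), centerlineLength(object),
              chordLength(object),
              if (all(is.na(r))) "NA" else
                sprintf("%.2f-%.2f", min(r, na.rm = TRUE), max(r, na.rm = TRUE))))
})

setMethod("show", "AAoDomain", function(object) {
  cat("AAoDomain\n")
  cat(sprintf("  surface:    %d vertices, %d faces\n",
              nVertices(object@surface), nFaces(object@surface)))
  cat(sprintf("  centerline: %.2f mm (%d points)\n",
              centerlineLength(object@centerline),
              nrow(centerlinePoints(object@centerline))))
  cat(sprintf("  annulus perimeter %.2f mm, ostium perimeter %.2f mm\n",
              object@annulus@perimeter, object@ostium@perimeter))
})

setMethod("show", "PlaneSection", function(object) {
  cat(sprintf("PlaneSection k=%d: %d contour points, Dmax %.2f mm\n",
              object@index, nrow(object@contour), object@maxDiameter))
})

setMethod("show", "CurvatureLine", function(object) {
  cat(sprintf("CurvatureLine (%s): %d points, length %.2f mm\n",
              object@kind, nrow(object@points), object@length))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              object@tp, object@tn, object@fp, object@fn,
              object@tp + object@tn + object@fp + object@fn))
})

setMethod("show", "ClassifierReport", function(object) {
  fmtLhr <- function(x) if (is.na(x)) "undefined" else
    if (is.infinite(x)) "+Inf" else sprintf("%.2f", x)
  cat(sprintf("ClassifierReport [%s] on {%s}\n", toupper(object@model),
              paste(object@features, collapse = ", ")))
  cat(sprintf("  accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              100 * object@accuracy, 100 * object@sensitivity,
              100 * object@specificity))
  cat(sprintf("  LHR+ %s, LHR- %s, AUROC %.2f, prevalence %.2f\n",
              fmtLhr(object@lhrPos), fmtLhr(object@lhrNeg),
              object@auroc, object@prevalence))
})
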