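#' Extract perpendicular cross-sections along the centerline
#'
#' Places `n` planes perpendicular to the centerline at equal arc-length
#' stations, intersects each with the surface, keeps the closed contour
#' component nearest the centerline point (grazing intersections with
#' other lumen portions are discarded), and computes each section's
#' rotating-sweep maximum diameter. Sections whose contour is open (the
#' plane exits through a boundary) or whose center falls outside the
#' contour are skipped with a warning; more than 50% skipped is an error.
#'
#' @param domain an [AAoDomain-class].
#' @param n number of sections (default 100).
#' @param alphaDeg sweep step in degrees (default 10; must divide 180).
#' @return List of [PlaneSection-class] objects (possibly fewer than `n`).
#' @examples
#' tube <- makeTube("straight", length = 60, r = 12, nAxial = 30, nCirc = 24)
#' cl <- extractCenterline(tube$mesh)
#' dom <- isolateAscending(tube$mesh, cl, ostiumArc = centerlineLength(cl))
#' secs <- extractSections(dom, n = 10)
#' maxDiameter(secs)
#' @export
extractSections <- function(domain, n = 100, alphaDeg = 10) {
  if (!is.numeric(n) || n < 2) stop("n must be >= 2 sections")
  n <- as.integer(n)
  cl <- resampleCenterline(domain@centerline, n)
  tang <- .centerlineTangents(cl)
  # near the cut ends the discrete tangent estimate wiggles; blend it into
  # the end-ring plane normal so terminal planes stay inside the tube
  s <- arcLengths(cl)
  Ltot <- s[n]
  blend <- min(0.08 * Ltot, 4 * Ltot / (n - 1))
  blendInto <- function(k, loop, sEdge) {
    w <- max(0, 1 - abs(s[k] - sEdge) / blend)
    if (w <= 0) return(tang[k, ])
    nrm <- loop@normal
    if (sum(nrm * tang[k, ]) < 0) nrm <- -nrm
    .unit((1 - w) * tang[k, ] + w * nrm)
  }
  for (k in seq_len(n)) {
    tang[k, ] <- blendInto(k, domain@annulus, 0)
    tang[k, ] <- blendInto(k, domain@ostium, Ltot)
  }
  mesh <- domain@surface
  # nudge the terminal stations off the cut planes so their contours close
  L <- centerlineLength(cl)
  eps <- min(0.5 * L / (n - 1), 1)
  cl@points[1, ] <- cl@points[1, ] + eps * tang[1, ]
  cl@points[n, ] <- cl@points[n, ] - eps * tang[n, ]
  out <- vector("list", n)
  skipped <- 0L
  grabContour <- function(center, normal) {
    pl <- Plane(center, normal)
    cont <- .planeContours(mesh, pl)
    if (length(cont) == 0L) return(NULL)
    dmin <- vapply(cont, function(cc)
      min(.rowNorms(sweep(cc$points, 2, center))), numeric(1))
    c(cont[[which.min(dmin)]], list(plane = pl, center = center))
  }
  inward <- function(k) if (k <= n / 2) 1 else -1
  for (k in seq_len(n)) {
    center <- cl@points[k, ]
    best <- grabContour(center, tang[k, ])
    # terminal planes can tilt out through the open end: retry deeper
    tries <- 0L
    while ((is.null(best) || !best$closed) && k %in% c(1L, n) &&
             tries < 4L) {
      tries <- tries + 1L
      center <- center + inward(k) * tries * eps * tang[k, ]
      best <- grabContour(center, tang[k, ])
    }
    if (is.null(best) || !best$closed) {
      warning("section ", k, if (is.null(best)) ": no intersection, skipped"
              else ": open intersection contour, skipped")
      skipped <- skipped + 1L
      next
    }
    sec <- tryCatch(
      .makeSection(k, best$center, best$plane, best$points, alphaDeg),
      error = function(e) {
        warning("section ", k, " skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(sec)) skipped <- skipped + 1L else out[[k]] <- sec
  }
  if (skipped > n / 2)
    stop("section extraction failed: ", skipped, " of ", n,
         " sections skipped")
  if (skipped > 0L)
    warning(skipped, " of ", n, " sections skipped")
  Filter(Negate(is.null), out)
}

.makeSection <- function(k, center, plane, contour, alphaDeg) {
  sw <- .sweepDiameter(contour, center, plane, alphaDeg)
  new("PlaneSection", index = as.integer(k), center = as.numeric(center),
      plane = plane, contour = contour, maxDiameter = sw$diameter,
      chordEndpoints = sw$endpoints)
}

#' Rotating-sweep maximum diameter of one section
#'
#' Sweeps a plane perpendicular to the section through its center in
#' angular steps of `alphaDeg` over \[0, 180) degrees; for each direction
#' the chord through the center is the segment between the farthest
#' contour intersections on either side. The maximum over directions is
#' the section's maximum diameter; ties break to the smallest angle.
#'
#' With `chordType = "any"`, the maximum distance between any two contour
#' points (rotating-calipers diameter, not constrained through the center)
#' is returned instead.
#'
#' @param section a [PlaneSection-class], or a closed contour matrix
#'   (p x 3) when `center` and `plane` are given.
#' @param alphaDeg angular step in degrees; must divide 180 evenly.
#' @param center,plane used when `section` is a raw contour matrix.
#' @param chordType `"through-center"` (the sweep definition) or `"any"`.
#' @return `list(diameter, endpoints, angleDeg)`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 73)[-73]
#' circle <- cbind(24 * cos(th), 24 * sin(th), 0)
#' maxDiameterSection(circle, center = c(0, 0, 0),
#'                    plane = Plane(c(0, 0, 0), c(0, 0, 1)))$diameter
#' @export
maxDiameterSection <- function(section, alphaDeg = 10, center = NULL,
                               plane = NULL,
                               chordType = c("through-center", "any")) {
  chordType <- match.arg(chordType)
  if (is(section, "PlaneSection")) {
    contour <- section@contour
    center <- section@center
    plane <- section@plane
  } else {
    contour <- section
    if (is.null(center) || is.null(plane))
      stop("center and plane are required with a raw contour")
  }
  if (chordType == "any") {
    d2 <- as.matrix(stats::dist(contour))
    ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
    return(list(diameter = max(d2),
                endpoints = contour[ij, , drop = FALSE],
                angleDeg = NA_real_))
  }
  .sweepDiameter(contour, center, plane, alphaDeg)
}

.sweepDiameter <- function(contour, center, plane, alphaDeg) {
  if (alphaDeg <= 0 || abs(180 / alphaDeg - round(180 / alphaDeg)) > 1e-9)
    stop("alphaDeg must divide 180 evenly")
  basis <- .planeBasis(plane@normal)
  xy <- cbind(as.numeric(contour %*% basis$u), as.numeric(contour %*% basis$v))
  c2 <- c(sum(center * basis$u), sum(center * basis$v))
  xy <- sweep(xy, 2, c2)
  if (!.pointInPolygon(c(0, 0), xy))
    stop("section center lies outside the contour")
  nDir <- as.integer(round(180 / alphaDeg))
  angles <- (seq_len(nDir) - 1L) * alphaDeg * pi / 180
  best <- -Inf; bestAng <- NA_real_; bestT <- c(NA_real_, NA_real_)
  x1 <- xy; x2 <- xy[c(2:nrow(xy), 1), , drop = FALSE]
  ex <- x2[, 1] - x1[, 1]; ey <- x2[, 2] - x1[, 2]
  for (a in seq_along(angles)) {
    dx <- cos(angles[a]); dy <- sin(angles[a])
    # line t*(dx,dy) meets edge x1 + u*(ex,ey), u in [0,1)
    denom <- dx * ey - dy * ex
    ok <- abs(denom) > 1e-14
    u <- (x1[, 1] * dy - x1[, 2] * dx) / denom
    t <- if (abs(dx) > abs(dy)) (x1[, 1] + u * ex) / dx else
      (x1[, 2] + u * ey) / dy
    hit <- ok & u >= 0 & u < 1
    tpos <- t[hit & t > 0]; tneg <- t[hit & t < 0]
    if (length(tpos) == 0L || length(tneg) == 0L) next
    len <- max(tpos) - min(tneg)
    if (len > best + 1e-12) {
      best <- len; bestAng <- angles[a] * 180 / pi
      bestT <- c(min(tneg), max(tpos))
    }
  }
  if (!is.finite(best)) stop("no chord through the section center found")
  dir3 <- cos(bestAng * pi / 180) * basis$u + sin(bestAng * pi / 180) * basis$v
  endpoints <- rbind(center + bestT[1] * dir3, center + bestT[2] * dir3)
  list(diameter = best, endpoints = endpoints, angleDeg = bestAng)
}

#' Maximum diameter over all sections
#'
#' The vessel maximum diameter D: the largest per-section sweep diameter,
#' with the achieving station index (ties break to the smallest index).
#'
#' @param sections list of [PlaneSection-class] from [extractSections()].
#' @return `list(D, k)` — diameter in mm and the achieving section index.
#' @export
maxDiameter <- function(sections) {
  if (length(sections) == 0L) stop("no valid sections")
  d <- vapply(sections, function(s) s@maxDiameter, numeric(1))
  k <- vapply(sections, function(s) s@index, integer(1))
  i <- which.max(d)  # which.max returns the first (smallest k: sorted)
  list(D = d[i], k = k[i])
}

#' Diameter-centerline ratio
#'
#' `DCR = D / L(C)`: the vessel maximum diameter normalized by the
#' centerline length of the analyzed segment (dimensionless).
#'
#' @param D maximum diameter (mm).
#' @param centerlineLength centerline length L(C) (mm).
#' @return DCR (dimensionless).
#' @examples
#' dcr(48, 96)  # 0.5
#' @export
dcr <- function(D, centerlineLength) {
  if (!is.finite(D) || D <= 0) stop("D must be > 0")
  if (!is.finite(centerlineLength) || centerlineLength <= 0)
    stop("centerline length must be > 0")
  D / centerlineLength
}

#' Export section contours for visual QC
#'
#' Writes all section contours as one long-format CSV
#' (`section, vertex, x, y, z`).
#'
#' @param sections list of [PlaneSection-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
exportSections <- function(sections, path) {
  rows <- lapply(sections, function(s)
    data.frame(section = s@index, vertex = seq_len(nrow(s@contour)),
               x = s@contour[, 1], y = s@contour[, 2], z = s@contour[, 3]))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
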