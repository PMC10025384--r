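#' Read a triangulated surface mesh
#'
#' Reads STL (ASCII or binary), PLY (ASCII) or OBJ surface meshes into a
#' validated [TriangleMesh-class]. Duplicate vertices are merged within
#' `mergeTol` (STL stores each facet's corners independently) and
#' zero-area faces dropped; a cleanup report is emitted via `message()`.
#' Coordinates are interpreted as millimetres.
#'
#' @param path path to the mesh file.
#' @param format one of `"auto"` (by extension), `"stl"`, `"ply"`, `"obj"`.
#' @param mergeTol vertex merge tolerance in mm.
#' @return A [TriangleMesh-class].
#' @examples
#' tube <- makeTube("straight", length = 30, r = 10, nAxial = 6, nCirc = 12)
#' f <- tempfile(fileext = ".ply")
#' writeMesh(tube$mesh, f)
#' m <- readMesh(f)
#' nFaces(m)
#' @export
readMesh <- function(path, format = c("auto", "stl", "ply", "obj"),
                     mergeTol = 1e-6) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, stl = "stl", ply = "ply", obj = "obj",
                     stop("cannot infer mesh format from extension '.", ext,
                          "'; pass format= explicitly"))
  }
  raw <- switch(format,
                stl = .readSTL(path),
                ply = .readPLY(path),
                obj = .readOBJ(path))
  if (nrow(raw$vertices) == 0L || nrow(raw$faces) == 0L)
    stop("empty mesh in ", path)
  TriangleMesh(raw$vertices, raw$faces, mergeTol = mergeTol)
}

.isBinarySTL <- function(path) {
  sz <- file.info(path)$size
  if (sz < 84) return(FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  identical(sz, 84 + 50 * as.numeric(ntri))
}

.readSTL <- function(path) {
  if (.isBinarySTL(path)) {
    con <- file(path, "rb"); on.exit(close(con))
    invisible(readBin(con, "raw", 80))
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    body <- readBin(con, "raw", 50 * ntri)
    m <- matrix(body, nrow = 50)
    vals <- readBin(as.vector(m[1:48, ]), "numeric", size = 4,
                    n = 12 * ntri, endian = "little")
    vals <- matrix(vals, nrow = 12)
    verts <- matrix(NA_real_, 3 * ntri, 3)
    verts[seq(1, 3 * ntri, 3), ] <- t(vals[4:6, ])
    verts[seq(2, 3 * ntri, 3), ] <- t(vals[7:9, ])
    verts[seq(3, 3 * ntri, 3), ] <- t(vals[10:12, ])
    faces <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
    return(list(vertices = verts, faces = faces))
  }
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0L) stop("no vertex records in ASCII STL ", path)
  nums <- lapply(strsplit(trimws(vlines), "\\s+"), function(x)
    as.numeric(x[2:4]))
  verts <- do.call(rbind, nums)
  if (any(!is.finite(verts))) stop("malformed vertex line in ", path)
  if (nrow(verts) %% 3L != 0L)
    stop("ASCII STL vertex count not a multiple of 3 in ", path)
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

.readPLY <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endHdr <- match("end_header", trimws(lines))
  if (is.na(endHdr)) stop("not a PLY file (no end_header): ", path)
  hdr <- trimws(lines[seq_len(endHdr)])
  if (!grepl("^ply", hdr[1])) stop("not a PLY file: ", path)
  if (!any(grepl("^format\\s+ascii", hdr)))
    stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub("^element\\s+vertex\\s+", "",
                       grep("^element\\s+vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element\\s+face\\s+", "",
                       grep("^element\\s+face", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("missing vertex/face elements in ", path)
  body <- trimws(lines[(endHdr + 1L):length(lines)])
  body <- body[nzchar(body)]
  vtxt <- strsplit(body[seq_len(nv)], "\\s+")
  verts <- t(vapply(vtxt, function(x) as.numeric(x[1:3]), numeric(3)))
  ftxt <- strsplit(body[nv + seq_len(nf)], "\\s+")
  faces <- t(vapply(seq_along(ftxt), function(i) {
    x <- as.integer(ftxt[[i]])
    if (x[1] != 3L)
      stop("non-triangular face #", i, " (", x[1], " vertices) in ", path)
    x[2:4] + 1L
  }, integer(3)))
  list(vertices = verts, faces = faces)
}

.readOBJ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  verts <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                    function(x) as.numeric(x[2:4]), numeric(3)))
  faces <- t(vapply(seq_along(flines), function(i) {
    tok <- strsplit(trimws(flines[i]), "\\s+")[[1]][-1]
    if (length(tok) != 3L)
      stop("non-triangular face #", i, " (", length(tok),
           " vertices) in ", path)
    as.integer(vapply(strsplit(tok, "/"), `[`, character(1), 1))
  }, integer(3)))
  list(vertices = verts, faces = faces)
}

#' Write a mesh to PLY (ASCII) or STL (ASCII)
#'
#' @param mesh a [TriangleMesh-class].
#' @param path output path.
#' @param format `"ply"` (default) or `"stl"`; `"auto"` picks by extension.
#' @return `path`, invisibly.
#' @export
writeMesh <- function(mesh, path, format = c("auto", "ply", "stl")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "stl") "stl" else "ply"
  V <- mesh@vertices; Fc <- mesh@faces
  if (format == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(V)),
             "property double x", "property double y", "property double z",
             paste("element face", nrow(Fc)),
             "property list uchar int vertex_indices", "end_header")
    vl <- sprintf("%.10g %.10g %.10g", V[, 1], V[, 2], V[, 3])
    fl <- sprintf("3 %d %d %d", Fc[, 1] - 1L, Fc[, 2] - 1L, Fc[, 3] - 1L)
    writeLines(c(hdr, vl, fl), path)
  } else {
    n <- .faceNormals(V, Fc)
    out <- character(2 + 7 * nrow(Fc))
    out[1] <- "solid mesh"
    k <- 2
    for (i in seq_len(nrow(Fc))) {
      out[k] <- sprintf("facet normal %.10g %.10g %.10g",
                        n[i, 1], n[i, 2], n[i, 3])
      out[k + 1] <- "  outer loop"
      for (j in 1:3) {
        p <- V[Fc[i, j], ]
        out[k + 1 + j] <- sprintf("    vertex %.10g %.10g %.10g",
                                  p[1], p[2], p[3])
      }
      out[k + 5] <- "  endloop"
      out[k + 6] <- "endfacet"
      k <- k + 7
    }
    out[length(out)] <- "endsolid mesh"
    writeLines(out, path)
  }
  invisible(path)
}

# Directed boundary half-edges: edges incident to exactly one face keep the
# orientation they have in that face.
.boundaryHalfEdges <- function(mesh) {
  f <- mesh@faces
  he <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  cnt <- table(key)
  he[cnt[key] == 1L, , drop = FALSE]
}

#' Boundary loops of an open mesh
#'
#' Finds every closed loop of boundary edges (edges incident to exactly one
#' face), e.g. the annulus and ostium rings of a cut aorta. Loops are
#' ordered counter-clockwise about the outward best-fit-plane normal and
#' returned sorted by descending perimeter.
#'
#' @param mesh a [TriangleMesh-class].
#' @return A list of [BoundaryLoop-class] objects (empty for closed meshes).
#' @examples
#' tube <- makeTube("straight", length = 30, r = 10, nAxial = 6, nCirc = 12)
#' length(boundaryLoops(tube$mesh))  # 2 open ends
#' @export
boundaryLoops <- function(mesh) {
  he <- .boundaryHalfEdges(mesh)
  if (nrow(he) == 0L) return(list())
  nxt <- integer(nrow(mesh@vertices))
  if (anyDuplicated(he[, 1]))
    stop("non-manifold boundary: vertex with multiple outgoing boundary edges")
  nxt[he[, 1]] <- he[, 2]
  visited <- rep(FALSE, nrow(mesh@vertices))
  loops <- list()
  for (start in he[, 1]) {
    if (visited[start]) next
    cur <- start
    idx <- integer(0)
    repeat {
      idx <- c(idx, cur)
      visited[cur] <- TRUE
      cur <- nxt[cur]
      if (cur == 0L) {
        stop("dangling boundary edge chain (does not close) starting at vertex ",
             start, "; edges: ",
             paste(idx[seq_len(min(10, length(idx)))], collapse = ","))
      }
      if (cur == start) break
      if (visited[cur] && cur != start)
        stop("boundary chain merges into an already-visited loop at vertex ",
             cur)
    }
    loops[[length(loops) + 1L]] <- idx
  }
  meshCentroid <- colMeans(mesh@vertices)
  out <- lapply(loops, function(idx) {
    pts <- mesh@vertices[idx, , drop = FALSE]
    centroid <- colMeans(pts)
    sv <- svd(sweep(pts, 2, centroid))
    n <- sv$v[, 3]
    if (sum(n * (centroid - meshCentroid)) < 0) n <- -n
    basis <- .planeBasis(n)
    xy <- cbind((pts %*% basis$u) - sum(centroid * basis$u),
                (pts %*% basis$v) - sum(centroid * basis$v))
    a2 <- sum(xy[, 1] * c(xy[-1, 2], xy[1, 2]) -
                c(xy[-1, 1], xy[1, 1]) * xy[, 2])
    if (a2 < 0) idx <- rev(idx)
    pts <- mesh@vertices[idx, , drop = FALSE]
    per <- .polylineLength(rbind(pts, pts[1, ]))
    new("BoundaryLoop", indices = as.integer(idx), centroid = centroid,
        normal = as.numeric(n), perimeter = per)
  })
  out[order(vapply(out, function(l) l@perimeter, numeric(1)),
            decreasing = TRUE)]
}

#' Cut a mesh with a plane
#'
#' Returns the sub-mesh on the requested side of the plane. Triangles
#' crossing the plane are split so the new boundary is a clean polygonal
#' loop lying in the plane; total surface area is conserved across the two
#' sides. If the kept side has more than one connected component, all are
#' returned with a warning (the caller selects, see [isolateAscending()]).
#'
#' @param mesh a [TriangleMesh-class].
#' @param plane a [Plane-class].
#' @param keep `"positive"` (side the normal points into) or `"negative"`.
#' @param tol on-plane snap tolerance (mm).
#' @return A [TriangleMesh-class].
#' @examples
#' tube <- makeTube("straight", length = 100, r = 15, nAxial = 20, nCirc = 24)
#' top <- planeCut(tube$mesh, Plane(c(0, 0, 50), c(0, 0, 1)), "positive")
#' range(meshVertices(top)[, 3])  # 50..100
#' @export
planeCut <- function(mesh, plane, keep = c("positive", "negative"),
                     tol = 1e-7) {
  keep <- match.arg(keep)
  n <- plane@normal
  if (keep == "negative") n <- -n
  V <- mesh@vertices
  d <- as.numeric((V %*% n) - sum(plane@point * n))
  d[abs(d) < tol] <- 0
  if (all(d <= 0)) stop("plane cut produced an empty result (mesh entirely on discarded side)")
  if (all(d >= 0)) return(mesh)
  Fc <- mesh@faces
  dv <- matrix(d[Fc], ncol = 3)
  keepAll <- rowSums(dv < 0) == 0L
  dropAll <- rowSums(dv > 0) == 0L
  crossing <- which(!keepAll & !dropAll)

  newV <- list()
  edgeCache <- new.env(hash = TRUE)
  nV <- nrow(V)
  interp <- function(i, j) {
    k <- paste(min(i, j), max(i, j))
    got <- edgeCache[[k]]
    if (!is.null(got)) return(got)
    t <- d[i] / (d[i] - d[j])
    p <- V[i, ] + t * (V[j, ] - V[i, ])
    nV <<- nV + 1L
    newV[[length(newV) + 1L]] <<- p
    edgeCache[[k]] <- nV
    nV
  }
  newFaces <- list()
  for (fi in crossing) {
    tri <- Fc[fi, ]
    dd <- d[tri]
    # clip triangle polygon to half-space dd >= 0 (Sutherland-Hodgman)
    poly <- integer(0)
    for (j in 1:3) {
      a <- tri[j]; b <- tri[if (j == 3L) 1L else j + 1L]
      da <- d[a]; db <- d[b]
      if (da >= 0) poly <- c(poly, a)
      if ((da > 0 && db < 0) || (da < 0 && db > 0))
        poly <- c(poly, interp(a, b))
    }
    poly <- poly[!duplicated(poly)]
    if (length(poly) >= 3L)
      for (j in 2:(length(poly) - 1L))
        newFaces[[length(newFaces) + 1L]] <- c(poly[1], poly[j], poly[j + 1])
  }
  Vout <- rbind(V, do.call(rbind, c(newV, list(NULL))))
  Fout <- rbind(Fc[keepAll, , drop = FALSE],
                do.call(rbind, c(newFaces, list(NULL))))
  if (is.null(Fout) || nrow(Fout) == 0L)
    stop("plane cut produced an empty result")
  out <- suppressMessages(TriangleMesh(Vout, Fout, clean = TRUE))
  comp <- .vertexComponents(out)
  ncomp <- length(unique(comp))
  if (ncomp > 1L)
    warning("plane cut produced ", ncomp,
            " connected components; caller must select one")
  out
}

# Keep the connected component of `mesh` nearest to `point`.
.selectComponent <- function(mesh, point) {
  comp <- .vertexComponents(mesh)
  if (length(unique(comp)) == 1L) return(mesh)
  d <- .rowNorms(sweep(mesh@vertices, 2, point))
  keepComp <- comp[which.min(d)]
  vKeep <- which(comp == keepComp)
  remap <- integer(nrow(mesh@vertices)); remap[vKeep] <- seq_along(vKeep)
  fKeep <- mesh@faces[comp[mesh@faces[, 1]] == keepComp, , drop = FALSE]
  suppressMessages(TriangleMesh(mesh@vertices[vKeep, , drop = FALSE],
                                matrix(remap[fKeep], ncol = 3), clean = FALSE))
}

# Intersection contours of a mesh with a plane; returns a list of
# list(points, closed). On-plane vertices are nudged off the plane by an
# infinitesimal epsilon so every contour crossing is a clean edge crossing.
.planeContours <- function(mesh, plane) {
  V <- mesh@vertices; Fc <- mesh@faces
  d <- as.numeric((V %*% plane@normal) - sum(plane@point * plane@normal))
  scale <- max(abs(d), 1)
  d[d == 0] <- 1e-12 * scale
  dv <- matrix(d[Fc], ncol = 3)
  crossing <- which(rowSums(dv > 0) %in% c(1L, 2L))
  if (length(crossing) == 0L) return(list())
  edgeKey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  segA <- character(0); segB <- character(0)
  ptsEnv <- new.env(hash = TRUE)
  for (fi in crossing) {
    tri <- Fc[fi, ]
    ek <- character(0)
    for (j in 1:3) {
      a <- tri[j]; b <- tri[if (j == 3L) 1L else j + 1L]
      if ((d[a] > 0) != (d[b] > 0)) {
        k <- edgeKey(a, b)
        if (is.null(ptsEnv[[k]])) {
          t <- d[a] / (d[a] - d[b])
          ptsEnv[[k]] <- V[a, ] + t * (V[b, ] - V[a, ])
        }
        ek <- c(ek, k)
      }
    }
    if (length(ek) == 2L) {
      segA <- c(segA, ek[1]); segB <- c(segB, ek[2])
    }
  }
  if (length(segA) == 0L) return(list())
  # chain segments: nodes are edge keys, links are faces
  adj <- new.env(hash = TRUE)
  addLink <- function(a, b) {
    cur <- adj[[a]]
    adj[[a]] <- c(cur, b)
  }
  for (i in seq_along(segA)) { addLink(segA[i], segB[i]); addLink(segB[i], segA[i]) }
  seen <- new.env(hash = TRUE)
  contours <- list()
  allKeys <- unique(c(segA, segB))
  for (k0 in allKeys) {
    if (!is.null(seen[[k0]])) next
    deg <- length(adj[[k0]])
    if (deg >= 2L) next  # start open chains at endpoints first
    chain <- .traceChain(k0, adj, seen)
    contours[[length(contours) + 1L]] <- list(keys = chain, closed = FALSE)
  }
  for (k0 in allKeys) {
    if (!is.null(seen[[k0]])) next
    chain <- .traceChain(k0, adj, seen)
    contours[[length(contours) + 1L]] <- list(keys = chain, closed = TRUE)
  }
  lapply(contours, function(cc) {
    pts <- t(vapply(cc$keys, function(k) ptsEnv[[k]], numeric(3)))
    rownames(pts) <- NULL
    list(points = pts, closed = cc$closed)
  })
}

.traceChain <- function(start, adj, seen) {
  chain <- start
  seen[[start]] <- TRUE
  cur <- start
  prev <- ""
  repeat {
    nb <- adj[[cur]]
    nb <- nb[nb != prev & vapply(nb, function(x) is.null(seen[[x]]), logical(1))]
    if (length(nb) == 0L) break
    prev <- cur
    cur <- nb[1]
    seen[[cur]] <- TRUE
    chain <- c(chain, cur)
  }
  chain
}

#' Write / read patient feature and growth tables
#'
#' RFC-4180 CSV with a header row, one row per patient exam. Required
#' columns for a feature table: `patient_id, D, DCR, EILR, T`. Growth
#' tables additionally require `D2, dt_months, gated`. Round trips are
#' lossless to better than 1e-9 relative.
#'
#' @param records a data.frame of feature/growth rows.
#' @param path CSV file path.
#' @param required character vector of columns that must be present.
#' @return `readFeatureTable()` returns the validated data.frame;
#'   `writeFeatureTable()` returns `path` invisibly.
#' @examples
#' tab <- data.frame(patient_id = "p1", D = 48, DCR = 0.5, EILR = 2.2,
#'                   T = 1.2)
#' f <- tempfile(fileext = ".csv")
#' writeFeatureTable(tab, f)
#' readFeatureTable(f)
#' @export
writeFeatureTable <- function(records, path,
                              required = c("patient_id", "D", "DCR",
                                           "EILR", "T")) {
  .checkSchema(records, required)
  num <- vapply(records, is.numeric, logical(1))
  out <- records
  out[num] <- lapply(records[num], function(x) format(x, digits = 17,
                                                      trim = TRUE,
                                                      scientific = NA))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path,
                             required = c("patient_id", "D", "DCR",
                                          "EILR", "T")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  .checkSchema(tab, required)
  tab
}

#' @rdname writeFeatureTable
#' @export
readGrowthTable <- function(path) {
  readFeatureTable(path, required = c("patient_id", "D", "DCR", "EILR", "T",
                                      "D2", "dt_months", "gated"))
}

.checkSchema <- function(tab, required) {
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L)
    stop("table schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
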