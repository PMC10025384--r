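# Independent oracles, deliberately naive: plain Dijkstra, dense chord
# sweeps, exhaustive pair counting. They share no code with the package
# internals they check.

# Plain O(V^2) Dijkstra over mesh edges from a single source vertex.
plainDijkstra <- function(mesh, source) {
  V <- meshVertices(mesh); Fc <- meshFaces(mesh)
  e <- rbind(Fc[, 1:2], Fc[, 2:3], Fc[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  w <- sqrt(rowSums((V[e[, 1], , drop = FALSE] -
                       V[e[, 2], , drop = FALSE])^2))
  n <- nrow(V)
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- rbind(adj[[e[k, 1]]], c(e[k, 2], w[k]))
    adj[[e[k, 2]]] <- rbind(adj[[e[k, 2]]], c(e[k, 1], w[k]))
  }
  dist <- rep(Inf, n); dist[source] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    relax <- dist[u] + nb[, 2] < dist[nb[, 1]]
    dist[nb[relax, 1]] <- dist[u] + nb[relax, 2]
  }
  dist
}

# Exhaustive all-pairs shortest boundary-to-boundary distance.
bruteForceGeodesic <- function(domain) {
  a <- annulusLoop(domain)@indices
  o <- ostiumLoop(domain)@indices
  best <- Inf
  for (s in a) {
    d <- plainDijkstra(domainSurface(domain), s)
    best <- min(best, min(d[o]))
  }
  best
}

# Dense brute-force maximum chord through the origin of a planar convex
# polygon (independent segment-by-segment ray marching).
denseChordOracle <- function(poly2, angleStepDeg = 0.1) {
  angles <- seq(0, 180 - angleStepDeg, by = angleStepDeg) * pi / 180
  n <- nrow(poly2)
  nxt <- c(2:n, 1)
  best <- 0
  for (a in angles) {
    d <- c(cos(a), sin(a))
    tHits <- c()
    for (i in seq_len(n)) {
      p <- poly2[i, ]; q <- poly2[nxt[i], ]
      ed <- q - p
      den <- d[1] * ed[2] - d[2] * ed[1]
      if (abs(den) < 1e-14) next
      u <- (p[1] * d[2] - p[2] * d[1]) / den
      if (u >= 0 && u < 1) {
        hit <- p + u * ed
        tHits <- c(tHits, sum(hit * d))
      }
    }
    if (length(tHits) >= 2)
      best <- max(best, max(tHits) - min(tHits))
  }
  best
}

# Exhaustive cross-pair AUROC (ties count one half).
pairCountAUROC <- function(scores, labels) {
  pos <- scores[labels == "fast"]
  neg <- scores[labels != "fast"]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Spearman rho via the explicit average-rank formula.
rankFormulaSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
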