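## Scattered-data linear interpolation on a Delaunay triangulation
## (Bowyer-Watson insertion; point sets here are tiny — one per labeled
## construct — so the O(n^2) insertion cost is irrelevant).

delaunay_triangulate <- function(px, py) {
  n <- length(px)
  if (n < 3L) stop("need at least 3 points to triangulate", call. = FALSE)
  ## super-triangle enclosing all points
  cx <- mean(range(px)); cy <- mean(range(py))
  d <- max(diff(range(px)), diff(range(py)), 1e-9) * 20
  Px <- c(px, cx - d, cx + d, cx)
  Py <- c(py, cy - d, cy - d, cy + d)
  tri <- matrix(c(n + 1L, n + 2L, n + 3L), nrow = 1L)

  circum_contains <- function(t, qx, qy) {
    ax <- Px[t[1L]]; ay <- Py[t[1L]]
    bx <- Px[t[2L]]; by <- Py[t[2L]]
    cx2 <- Px[t[3L]]; cy2 <- Py[t[3L]]
    d2 <- 2 * (ax * (by - cy2) + bx * (cy2 - ay) + cx2 * (ay - by))
    if (abs(d2) < 1e-14) return(FALSE)
    ux <- ((ax^2 + ay^2) * (by - cy2) + (bx^2 + by^2) * (cy2 - ay) +
             (cx2^2 + cy2^2) * (ay - by)) / d2
    uy <- ((ax^2 + ay^2) * (cx2 - bx) + (bx^2 + by^2) * (ax - cx2) +
             (cx2^2 + cy2^2) * (bx - ax)) / d2
    r2 <- (ax - ux)^2 + (ay - uy)^2
    (qx - ux)^2 + (qy - uy)^2 <= r2 * (1 + 1e-12)
  }

  for (i in seq_len(n)) {
    bad <- vapply(seq_len(nrow(tri)), function(k)
      circum_contains(tri[k, ], Px[i], Py[i]), logical(1L))
    edges <- do.call(rbind, lapply(which(bad), function(k) {
      t <- tri[k, ]
      rbind(sort(t[1:2]), sort(t[2:3]), sort(t[c(1L, 3L)]))
    }))
    key <- paste(edges[, 1L], edges[, 2L])
    boundary <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    tri <- tri[!bad, , drop = FALSE]
    tri <- rbind(tri, cbind(boundary, i))
  }
  tri <- tri[apply(tri, 1L, function(t) all(t <= n)), , drop = FALSE]
  tri
}

## evaluate the piecewise-linear interpolant at query points; NA outside hull
barycentric_interp <- function(px, py, pz, qx, qy) {
  tri <- delaunay_triangulate(px, py)
  out <- rep(NA_real_, length(qx))
  for (k in seq_len(nrow(tri))) {
    t <- tri[k, ]
    x1 <- px[t[1L]]; y1 <- py[t[1L]]
    x2 <- px[t[2L]]; y2 <- py[t[2L]]
    x3 <- px[t[3L]]; y3 <- py[t[3L]]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(det) < 1e-14) next
    w1 <- ((y2 - y3) * (qx - x3) + (x3 - x2) * (qy - y3)) / det
    w2 <- ((y3 - y1) * (qx - x3) + (x1 - x3) * (qy - y3)) / det
    w3 <- 1 - w1 - w2
    inside <- is.na(out) & w1 >= -1e-9 & w2 >= -1e-9 & w3 >= -1e-9
    out[inside] <- w1[inside] * pz[t[1L]] + w2[inside] * pz[t[2L]] +
      w3[inside] * pz[t[3L]]
  }
  out
}
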