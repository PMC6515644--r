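# Internal raster helpers shared by segmentation, CAA and morphometry.

# Shift a matrix by (dy, dx); vacated cells take `fill`.
mat_shift <- function(m, dy, dx, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  if (length(ys) && length(xs))
    out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  out
}

# Offsets (dy, dx) of a circular neighbourhood: pixel-center distance <= r.
disc_offsets <- function(r) {
  d <- floor(r)
  g <- expand.grid(dy = -d:d, dx = -d:d)
  g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

# Binary structuring element of the same disc, for EBImage morphology.
disc_kernel <- function(r) {
  d <- floor(r)
  ax <- -d:d
  k <- outer(ax, ax, function(dy, dx) as.numeric(dy^2 + dx^2 <= r^2))
  k
}

# Binary dilation by a disc of radius r (r = 0 is the identity).
dilate_disc <- function(mask, r) {
  if (r <= 0) return(mask)
  EBImage::dilate(mask * 1, disc_kernel(r)) > 0.5
}

# 8-connected component labeling. EBImage::bwlabel is 4-connected; diagonal
# label adjacencies are merged with a union-find pass.
label_components_8 <- function(mask) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  l4 <- EBImage::bwlabel(mask * 1)
  l4 <- matrix(as.integer(l4), nrow(mask), ncol(mask))
  nlab <- max(l4)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  h <- nrow(l4); w <- ncol(l4)
  # diagonal neighbour pairs: (i, j) with (i+1, j+1) and (i+1, j-1)
  a <- l4[-h, -w]; b <- l4[-1, -1]
  sel <- a > 0 & b > 0 & a != b
  if (any(sel)) apply(unique(cbind(a[sel], b[sel])), 1, function(p) union2(p[1], p[2]))
  a <- l4[-h, -1]; b <- l4[-1, -w]
  sel <- a > 0 & b > 0 & a != b
  if (any(sel)) apply(unique(cbind(a[sel], b[sel])), 1, function(p) union2(p[1], p[2]))
  roots <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- matrix(0L, h, w)
  out[l4 > 0] <- dense[l4[l4 > 0]]
  out
}

# Count of 8-neighbours that are TRUE, per pixel (border-clipped).
neighbor_count_8 <- function(mask) {
  m <- mask * 1L
  acc <- matrix(0L, nrow(m), ncol(m))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    acc <- acc + mat_shift(m, dy, dx, 0L)
  }
  acc
}

# Even-odd point-in-polygon over the whole pixel grid (0-based pixel-center
# coordinates); points exactly on the boundary count as inside.
polygon_grid_mask <- function(vertices, shape) {
  h <- shape[1]; w <- shape[2]
  xs <- 0:(w - 1); ys <- 0:(h - 1)
  n <- nrow(vertices)
  crossings <- matrix(0L, h, w)
  boundary <- matrix(FALSE, h, w)
  eps <- 1e-9
  for (i in seq_len(n)) {
    p1 <- vertices[i, ]; p2 <- vertices[if (i == n) 1 else i + 1, ]
    x1 <- p1[1]; y1 <- p1[2]; x2 <- p2[1]; y2 <- p2[2]
    # crossing-number contribution: rows whose center y is straddled
    straddle <- (y1 > ys) != (y2 > ys)
    if (any(straddle)) {
      ri <- which(straddle)
      yr <- ys[ri]
      xint <- x1 + (yr - y1) * (x2 - x1) / (y2 - y1)
      add <- outer(xint, xs, function(xi, xc) xc < xi)
      crossings[ri, ] <- crossings[ri, , drop = FALSE] + add
    }
    # boundary: pixel centers lying on the segment
    minx <- min(x1, x2) - eps; maxx <- max(x1, x2) + eps
    miny <- min(y1, y2) - eps; maxy <- max(y1, y2) + eps
    bx <- xs >= minx & xs <= maxx
    by <- ys >= miny & ys <= maxy
    if (any(bx) && any(by)) {
      cx <- xs[bx]; cy <- ys[by]
      cross <- outer(cy, cx, function(py, px)
        abs((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)))
      seglen <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
      onseg <- cross <= eps * max(1, seglen)
      boundary[by, bx] <- boundary[by, bx] | onseg
    }
  }
  (crossings %% 2L == 1L) | boundary
}

# Linear min-max rescale of an intensity matrix to 0..255 integers.
rescale_8bit <- function(pixels) {
  rng <- range(pixels)
  if (rng[2] > rng[1]) {
    out <- round(255 * (pixels - rng[1]) / (rng[2] - rng[1]))
  } else {
    out <- matrix(0, nrow(pixels), ncol(pixels))
  }
  out
}
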