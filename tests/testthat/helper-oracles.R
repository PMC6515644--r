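# Independent brute-force oracles. These deliberately use naive per-pixel
# scans and model refits so they share no code path with the implementation.

# Bernsen: per-pixel scan of the circular neighbourhood.
oracle_bernsen <- function(pix, r, cmin, low_fg = FALSE) {
  h <- nrow(pix); w <- ncol(pix)
  d <- floor(r)
  offs <- expand.grid(dy = -d:d, dx = -d:d)
  offs <- offs[offs$dy^2 + offs$dx^2 <= r^2, ]
  out <- matrix(FALSE, h, w)
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      ys <- y + offs$dy; xs <- x + offs$dx
      ok <- ys >= 1 & ys <= h & xs >= 1 & xs <= w
      vals <- pix[cbind(ys[ok], xs[ok])]
      lo <- min(vals); hi <- max(vals)
      out[y, x] <- if (hi - lo < cmin) low_fg else pix[y, x] >= (lo + hi) / 2
    }
  }
  out
}

# Pixel-count oracle: explicit double loop.
oracle_count <- function(...) {
  masks <- list(...)
  h <- nrow(masks[[1]]); w <- ncol(masks[[1]])
  n <- 0L
  for (y in seq_len(h)) for (x in seq_len(w)) {
    all_in <- TRUE
    for (m in masks) if (!m[y, x]) { all_in <- FALSE; break }
    if (all_in) n <- n + 1L
  }
  n
}

# Scalar even-odd point-in-polygon with boundary-inclusive rule.
oracle_point_in_poly <- function(px, py, v) {
  n <- nrow(v)
  eps <- 1e-9
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    x1 <- v[j, 1]; y1 <- v[j, 2]; x2 <- v[i, 1]; y2 <- v[i, 2]
    # boundary check
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    if (abs(cross) <= eps * max(1, abs(x2 - x1) + abs(y2 - y1)) &&
        px >= min(x1, x2) - eps && px <= max(x1, x2) + eps &&
        py >= min(y1, y2) - eps && py <= max(y1, y2) + eps) return(TRUE)
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_rasterize <- function(v, shape) {
  out <- matrix(FALSE, shape[1], shape[2])
  for (y in seq_len(shape[1])) for (x in seq_len(shape[2]))
    out[y, x] <- oracle_point_in_poly(x - 1, y - 1, v)
  out
}

# Type III ANOVA by comparing full vs reduced least-squares fits on the
# sum-to-zero design matrix.
oracle_type3 <- function(y, A, B) {
  d <- data.frame(A = factor(A), B = factor(B))
  stats::contrasts(d$A) <- stats::contr.sum(2)
  stats::contrasts(d$B) <- stats::contr.sum(2)
  X <- stats::model.matrix(~ A * B, d)
  rss <- function(cols) sum(stats::lm.fit(X[, cols, drop = FALSE], y)$residuals^2)
  s_full <- rss(1:4)
  df_res <- length(y) - 4
  ss <- c(A = rss(c(1, 3, 4)) - s_full,
          B = rss(c(1, 2, 4)) - s_full,
          AB = rss(1:3) - s_full)
  ms_res <- s_full / df_res
  F <- ss / ms_res
  p <- stats::pf(F, 1, df_res, lower.tail = FALSE)
  list(ss = ss, resid_ss = s_full, df_res = df_res, F = F, p = p)
}

# Exact Mann-Whitney by enumerating subsets as bit masks (independent of
# the combn-based implementation).
oracle_mw_exact <- function(x, y) {
  ustat <- function(xv, yv)
    sum(outer(xv, yv, function(a, b) (a > b) + 0.5 * (a == b)))
  pool <- c(x, y)
  N <- length(pool); nx <- length(x)
  mid <- nx * length(y) / 2
  dev <- abs(ustat(x, y) - mid)
  hits <- 0L; total <- 0L
  for (code in 0:(2^N - 1)) {
    sel <- as.logical(bitwAnd(bitwShiftL(1L, 0:(N - 1)), code))
    if (sum(sel) != nx) next
    total <- total + 1L
    if (abs(ustat(pool[sel], pool[!sel]) - mid) >= dev - 1e-12) hits <- hits + 1L
  }
  hits / total
}

# 8-connected component labeling by BFS flood fill.
oracle_label8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (y0 in seq_len(h)) for (x0 in seq_len(w)) {
    if (!mask[y0, x0] || lab[y0, x0] > 0) next
    cur <- cur + 1L
    queue <- list(c(y0, x0)); lab[y0, x0] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dy in -1:1) for (dx in -1:1) {
        yy <- p[1] + dy; xx <- p[2] + dx
        if (yy >= 1 && yy <= h && xx >= 1 && xx <= w &&
            mask[yy, xx] && lab[yy, xx] == 0L) {
          lab[yy, xx] <- cur
          queue[[length(queue) + 1]] <- c(yy, xx)
        }
      }
    }
  }
  lab
}
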