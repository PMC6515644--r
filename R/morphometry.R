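# Vessel morphometry on the segmented CD31 mask: topology-preserving
# thinning to a medial-axis skeleton, conversion to a junction/endpoint
# graph, spur pruning, and per-edge diameter (distance-transform radius) and
# tortuosity (path length / chord length).

# Zhang-Suen thinning; returns a logical skeleton matrix.
thin_mask <- function(mask) {
  m <- mask * 1L
  nb <- function(dy, dx) mat_shift(m, -dy, -dx, 0L)  # value at (y+dy, x+dx)
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- nb(-1, 0); p3 <- nb(-1, 1); p4 <- nb(0, 1); p5 <- nb(1, 1)
      p6 <- nb(1, 0); p7 <- nb(1, -1); p8 <- nb(0, -1); p9 <- nb(-1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (pass == 1) {
        cond <- m == 1L & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1L & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# Path length of a pixel chain. The naive chain code (1 per 4-step, sqrt(2)
# per diagonal) overestimates digitized curves by up to ~20% through
# staircase jitter, so the chain is resampled as a polyline with a vertex
# every `step` pixels (plus both endpoints) and segment lengths are summed;
# collinear chains remain exact.
chain_path_length <- function(chain, step = 4) {
  n <- nrow(chain)
  if (n < 2) return(0)
  idx <- unique(c(seq(1, n, by = step), n))
  seg <- diff(chain[idx, , drop = FALSE])
  sum(sqrt(rowSums(seg^2)))
}

# 4-adjacent neighbours first: when tracing a staircase chain the diagonal
# neighbour is a redundant shortcut and the 4-connected pixel is the true
# successor.
neighbors8_of <- function(idx, h, w) {
  y <- (idx - 1L) %% h + 1L
  x <- (idx - 1L) %/% h + 1L
  dy <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
  dx <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  ny <- y + dy; nx <- x + dx
  ok <- ny >= 1L & ny <= h & nx >= 1L & nx <= w
  (nx[ok] - 1L) * h + ny[ok]
}

# Yokoi crossing number: 0->1 transitions around each pixel in the cyclic
# 8-neighbourhood. Chains have 2, endpoints 1, junctions >= 3; Zhang-Suen
# staircase corners (3 neighbours but 2 transitions) classify as chain.
crossing_number <- function(mask) {
  m <- mask * 1L
  nb <- function(dy, dx) mat_shift(m, -dy, -dx, 0L)
  p2 <- nb(-1, 0); p3 <- nb(-1, 1); p4 <- nb(0, 1); p5 <- nb(1, 1)
  p6 <- nb(1, 0); p7 <- nb(1, -1); p8 <- nb(0, -1); p9 <- nb(-1, -1)
  (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
    (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
    (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
}

# Extract a node/edge graph from a skeleton matrix. Chains are matrices of
# 0-based (x, y) coordinates including the terminal node pixels.
skeleton_to_graph <- function(skel) {
  h <- nrow(skel); w <- ncol(skel)
  cn <- crossing_number(skel)
  node_px <- skel & (cn != 2L)
  node_lab <- label_components_8(node_px)
  is_node <- node_lab > 0L
  visited <- matrix(FALSE, h, w)
  edges <- list()
  idx_xy <- function(idx) cbind((idx - 1L) %/% h, (idx - 1L) %% h)  # 0-based (x, y)
  add_edge <- function(chain_idx, from, to) {
    edges[[length(edges) + 1L]] <<- list(
      from = from, to = to, chain = idx_xy(chain_idx))
  }
  node_idx <- which(node_px)
  for (np in node_idx) {
    for (nb in neighbors8_of(np, h, w)) {
      if (!skel[nb] || is_node[nb] || visited[nb]) next
      chain <- c(np, nb)
      visited[nb] <- TRUE
      prev <- np; cur <- nb
      repeat {
        nbs <- neighbors8_of(cur, h, w)
        nbs <- nbs[skel[nbs] & nbs != prev]
        # drop fellow chain neighbours already in this chain (tight turns)
        nxt <- nbs[is_node[nbs] | !visited[nbs]]
        if (length(nxt) == 0) { add_edge(chain, node_lab[np], NA_integer_); break }
        nxt <- nxt[1]
        chain <- c(chain, nxt)
        if (is_node[nxt]) { add_edge(chain, node_lab[np], node_lab[nxt]); break }
        visited[nxt] <- TRUE
        prev <- cur; cur <- nxt
      }
    }
  }
  # direct node-to-node contacts between different clusters cannot occur
  # (adjacent node pixels share a cluster); remaining unvisited chain pixels
  # are pure cycles with no junction: trace and split at the farthest pair
  left <- which(skel & !is_node & !visited)
  for (start in left) {
    if (visited[start]) next
    visited[start] <- TRUE
    cyc <- c(start)
    prev <- start
    nbs <- neighbors8_of(start, h, w); nbs <- nbs[skel[nbs] & !is_node[nbs]]
    if (length(nbs) == 0) next
    cur <- nbs[1]
    while (cur != start) {
      visited[cur] <- TRUE
      cyc <- c(cyc, cur)
      nbs <- neighbors8_of(cur, h, w)
      nbs <- nbs[skel[nbs] & nbs != prev & !is_node[nbs]]
      nbs <- nbs[!visited[nbs] | nbs == start]
      if (length(nbs) == 0) break
      prev <- cur; cur <- nbs[1]
    }
    xy <- idx_xy(cyc)
    dd <- as.matrix(stats::dist(xy))
    far <- which(dd == max(dd), arr.ind = TRUE)[1, ]
    i <- min(far); j <- max(far)
    if (j - i >= 1) {
      edges[[length(edges) + 1L]] <- list(from = NA, to = NA,
                                          chain = xy[i:j, , drop = FALSE])
      edges[[length(edges) + 1L]] <- list(from = NA, to = NA,
                                          chain = xy[c(j:nrow(xy), 1:i), , drop = FALSE])
    }
  }
  list(edges = edges, node_labels = node_lab, skeleton = skel)
}

#' Skeletonize a vessel mask into a vessel graph
#'
#' Thins the CD31 mask to a one-pixel medial-axis skeleton (Zhang-Suen,
#' topology-preserving), converts it to a graph of junction/endpoint nodes
#' and edge pixel chains, and iteratively prunes terminal spur branches
#' shorter than `min_branch_px` (which also removes compact non-vessel
#' artifacts whose skeletons are short).
#'
#' @param cd31_mask Vessel [binary_mask] (or logical matrix).
#' @param min_branch_px Minimum terminal branch length in pixels (chain
#'   metric); default 10.
#' @param pixel_size_um Micrometres per pixel.
#' @return An object of class `vessel_graph`: list with `edges` (each with a
#'   0-based `(x, y)` chain, `path_length_px`/`_um`, `chord_length_px`/`_um`),
#'   `skeleton`, `mask` and `pixel_size_um`. Path lengths are measured on the
#'   resampled chain polyline, which is unbiased for digitized curves where
#'   the raw chain code overestimates.
#' @export
skeletonize_vessels <- function(cd31_mask, min_branch_px = 10, pixel_size_um = 1) {
  m <- mask_px(cd31_mask)
  skel <- thin_mask(m)
  repeat {
    g <- skeleton_to_graph(skel)
    if (length(g$edges) == 0) break
    lens <- vapply(g$edges, function(e) chain_path_length(e$chain), numeric(1))
    # endpoint clusters: node clusters containing an endpoint/isolated pixel
    ncnt <- crossing_number(skel)
    terminal_cluster <- tapply((ncnt < 2L)[g$node_labels > 0L],
                               g$node_labels[g$node_labels > 0L], any)
    is_term_edge <- vapply(g$edges, function(e) {
      ends <- c(e$from, e$to)
      any(is.na(ends)) && all(is.na(ends)) ||
        any(!is.na(ends) & terminal_cluster[as.character(ends)])
    }, logical(1))
    drop <- is_term_edge & lens < min_branch_px
    if (!any(drop)) break
    for (e in g$edges[drop]) {
      ch <- e$chain
      # remove chain pixels but keep pixels that belong to junction clusters
      for (k in seq_len(nrow(ch))) {
        yy <- ch[k, 2] + 1L; xx <- ch[k, 1] + 1L
        if (g$node_labels[yy, xx] > 0L && !terminal_cluster[as.character(g$node_labels[yy, xx])])
          next
        skel[yy, xx] <- FALSE
      }
    }
    skel <- thin_mask(skel)  # re-thin in case pruning left thick junction remnants
  }
  g <- skeleton_to_graph(skel)
  edges <- lapply(seq_along(g$edges), function(i) {
    e <- g$edges[[i]]
    plen <- chain_path_length(e$chain)
    chord <- sqrt(sum((e$chain[nrow(e$chain), ] - e$chain[1, ])^2))
    list(edge_id = i, chain = e$chain, from = e$from, to = e$to,
         path_length_px = plen, chord_length_px = chord,
         path_length_um = plen * pixel_size_um,
         chord_length_um = chord * pixel_size_um)
  })
  structure(list(edges = edges, skeleton = skel, mask = m,
                 pixel_size_um = pixel_size_um),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d edges, %d skeleton px, %.3g um/px\n",
              length(x$edges), sum(x$skeleton), x$pixel_size_um))
  invisible(x)
}

#' Fill per-edge vessel diameters from the distance transform
#'
#' The local vessel radius at a skeleton pixel is its Euclidean
#' distance-transform value minus half a pixel (the mask boundary is taken to
#' lie halfway between the last foreground and first background pixel
#' centers). Edge diameter is twice the mean radius along the chain, in
#' micrometres.
#'
#' @param graph A [skeletonize_vessels()] result.
#' @param cd31_mask The mask the skeleton was derived from (defaults to the
#'   mask stored in the graph).
#' @return The graph with `mean_radius_um` and `diameter_um` set per edge.
#' @export
edge_diameter <- function(graph, cd31_mask = NULL) {
  m <- if (is.null(cd31_mask)) graph$mask else mask_px(cd31_mask)
  dt <- EBImage::distmap(m * 1)
  dt <- matrix(as.numeric(dt), nrow(m), ncol(m))
  graph$edges <- lapply(graph$edges, function(e) {
    r <- dt[cbind(e$chain[, 2] + 1L, e$chain[, 1] + 1L)] - 0.5
    r <- pmax(r, 0.5)
    e$mean_radius_um <- mean(r) * graph$pixel_size_um
    e$diameter_um <- 2 * e$mean_radius_um
    e
  })
  graph
}

#' Fill per-edge tortuosity
#'
#' Tortuosity is the chain path length divided by the end-to-end chord
#' length; it is >= 1 and equals 1 for collinear chains. Closed loops were
#' already split at their farthest-point pair during graph construction, so
#' every edge has a positive chord.
#'
#' @param graph A [skeletonize_vessels()] result.
#' @return The graph with `tortuosity` set per edge.
#' @export
edge_tortuosity <- function(graph) {
  graph$edges <- lapply(graph$edges, function(e) {
    e$tortuosity <- if (e$chord_length_px > 0)
      e$path_length_px / e$chord_length_px else NA_real_
    e
  })
  graph
}

#' Tabulate and summarize a vessel graph
#'
#' @param graph A graph with diameters and tortuosity filled.
#' @param section_id Identifier column for the per-edge table.
#' @param weighted Weight per-edge means by path length (long segments
#'   dominate the biology); unweighted means otherwise.
#' @return List with `edges` (per-edge data frame) and `summary` (one row:
#'   total skeleton length, mean diameter, mean tortuosity, vessel area
#'   fraction of the mask).
#' @export
summarize_vessels <- function(graph, section_id = "s1", weighted = TRUE) {
  if (length(graph$edges) == 0) {
    return(list(
      edges = data.frame(section_id = character(0), edge_id = integer(0),
                         path_length_um = numeric(0), chord_length_um = numeric(0),
                         diameter_um = numeric(0), tortuosity = numeric(0)),
      summary = data.frame(section_id = section_id, n_edges = 0,
                           total_length_um = 0, mean_diameter_um = NA_real_,
                           mean_tortuosity = NA_real_,
                           vessel_area_fraction = mean(graph$mask))))
  }
  ed <- do.call(rbind, lapply(graph$edges, function(e)
    data.frame(section_id = section_id, edge_id = e$edge_id,
               path_length_um = e$path_length_um,
               chord_length_um = e$chord_length_um,
               diameter_um = e$diameter_um %||% NA_real_,
               tortuosity = e$tortuosity %||% NA_real_)))
  wgt <- if (weighted) ed$path_length_um else rep(1, nrow(ed))
  list(edges = ed,
       summary = data.frame(
         section_id = section_id, n_edges = nrow(ed),
         total_length_um = sum(ed$path_length_um),
         mean_diameter_um = stats::weighted.mean(ed$diameter_um, wgt, na.rm = TRUE),
         mean_tortuosity = stats::weighted.mean(ed$tortuosity, wgt, na.rm = TRUE),
         vessel_area_fraction = mean(graph$mask)))
}
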