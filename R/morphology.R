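# Low-level binary-image primitives shared by the wrinkle-network pipeline:
# 8-connected component labeling (igraph-backed) and Zhang-Suen thinning.
# EBImage's bwlabel is 4-connected, hence the igraph route here.

# Shift a matrix by (dr, dc), zero-filling exposed borders.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' 8-connected component labeling of a binary mask
#'
#' Labels connected sets of foreground pixels using 8-connectivity
#' (orthogonal and diagonal neighbours), the convention used throughout the
#' wrinkle pipeline. Labels are assigned deterministically in order of first
#' (column-major) occurrence.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return Integer matrix of the same shape; 0 = background, 1..k component
#'   ids.
#' @export
label_components <- function(mask) {
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  id <- integer(nr * nc)
  id[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  edges <- vector("list", 4L)
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (k in seq_along(shifts)) {
    dr <- shifts[[k]][1]; dc <- shifts[[k]][2]
    ok <- rows + dr >= 1L & rows + dr <= nr & cols + dc <= nc
    src <- idx[ok]
    dst <- src + dr + dc * nr
    conn <- mask[dst]
    edges[[k]] <- cbind(id[src[conn]], id[dst[conn]])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # renumber by first occurrence for determinism independent of igraph internals
  first <- !duplicated(memb)
  renum <- integer(max(memb))
  renum[memb[first]] <- seq_len(sum(first))
  lab[idx] <- renum[memb]
  lab
}

# Pixel counts per component label (label i -> sizes[i]).
component_sizes <- function(labels) {
  n <- max(labels)
  if (n == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = n)
}

#' Topology-preserving skeletonization (Guo-Hall thinning)
#'
#' Iteratively peels boundary pixels of a binary mask until a 1-pixel-wide,
#' 8-connected skeleton remains, preserving connectivity and line ends
#' (Guo & Hall 1989 two-subiteration scheme, which avoids the staircase
#' redundancy of simpler thinning rules). Used to reduce wrinkle ribbons to
#' their centrelines; the skeleton pixel count then matches the pixel count
#' of the rasterized centreline.
#'
#' @param mask Logical (or 0/1) matrix; foreground is thinned.
#' @return Logical matrix of the skeleton.
#' @export
skeletonize <- function(mask) {
  p <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours P2..P9: N, NE, E, SE, S, SW, W, NW
      p2 <- shift_mat(p,  1L,  0L); p3 <- shift_mat(p,  1L, -1L)
      p4 <- shift_mat(p,  0L, -1L); p5 <- shift_mat(p, -1L, -1L)
      p6 <- shift_mat(p, -1L,  0L); p7 <- shift_mat(p, -1L,  1L)
      p8 <- shift_mat(p,  0L,  1L); p9 <- shift_mat(p,  1L,  1L)
      cc <- (1L - p2) * pmax(p3, p4) + (1L - p4) * pmax(p5, p6) +
            (1L - p6) * pmax(p7, p8) + (1L - p8) * pmax(p9, p2)
      n1 <- pmax(p9, p2) + pmax(p3, p4) + pmax(p5, p6) + pmax(p7, p8)
      n2 <- pmax(p2, p3) + pmax(p4, p5) + pmax(p6, p7) + pmax(p8, p9)
      nm <- pmin(n1, n2)
      m <- if (sub == 1L) {
        pmax(p6, p7, 1L - p9) * p8
      } else {
        pmax(p2, p3, 1L - p5) * p4
      }
      cond <- p == 1L & cc == 1L & nm >= 2L & nm <= 3L & m == 0L
      if (any(cond)) {
        p[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p == 1L
}
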