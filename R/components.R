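# Connected-component labeling for binary stacks.
#
# In-plane adjacency is always the 8-neighborhood; the `connectivity` argument
# controls which of the 9 candidate neighbors on adjacent sections are linked:
#   6  - face only: same (row, col) on s +/- 1
#   18 - face + in-plane edges: 4-neighborhood on s +/- 1
#   26 - full 3x3 neighborhood on s +/- 1 (default; 70 nm sections are much
#        thinner than a punctum, so residual lateral jitter after integer
#        alignment must not split an object)

# Half-space neighbor offsets (dr, dc, ds): each undirected adjacency is
# enumerated once.
neighbor_offsets <- function(connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  inplane <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(-1, 1, 0))
  up <- switch(as.character(connectivity),
    "6"  = rbind(c(0, 0, 1)),
    "18" = rbind(c(0, 0, 1), c(1, 0, 1), c(-1, 0, 1), c(0, 1, 1), c(0, -1, 1)),
    "26" = as.matrix(expand.grid(dr = -1:1, dc = -1:1, ds = 1))
  )
  m <- rbind(inplane, unname(as.matrix(up)))
  storage.mode(m) <- "integer"
  colnames(m) <- c("dr", "dc", "ds")
  m
}

#' Label connected components of a 3D binary array
#'
#' Foreground voxels of `mask` (dimensions row x col x section) are grouped
#' into connected components under 8-connectivity in-plane plus the requested
#' inter-section adjacency. Labels are assigned in a reproducible order: the
#' component whose lexicographically smallest voxel (by section, then row,
#' then column) comes first gets label 1, and so on.
#'
#' @param mask logical (or 0/1 numeric) array, `dim = c(nrow, ncol, nsection)`.
#'   A matrix is treated as a single-section stack.
#' @param connectivity 6, 18 or 26 (inter-section linkage; see Details).
#' @return integer array of the same dimension; 0 = background.
#' @export
label_components <- function(mask, connectivity = 26L) {
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  stopifnot(length(dim(mask)) == 3L)
  d <- dim(mask)
  nr <- d[1L]; nc <- d[2L]; ns <- d[3L]
  fg <- which(mask != 0)
  labels <- array(0L, dim = d)
  if (length(fg) == 0L) {
    return(labels)
  }
  i0 <- fg - 1L
  r <- i0 %% nr
  c <- (i0 %/% nr) %% nc
  s <- i0 %/% (nr * nc)

  offs <- neighbor_offsets(as.integer(connectivity))
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1L]; dc <- offs[k, 2L]; ds <- offs[k, 3L]
    ok <- r + dr >= 0L & r + dr < nr &
      c + dc >= 0L & c + dc < nc &
      s + ds >= 0L & s + ds < ns
    if (!any(ok)) next
    nidx <- fg[ok] + dr + dc * nr + ds * nr * nc
    j <- match(nidx, fg)
    hit <- !is.na(j)
    from <- c(from, which(ok)[hit])
    to <- c(to, j[hit])
  }

  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
  }
  memb <- igraph::components(g)$membership

  # Deterministic relabeling by smallest (section, row, col) voxel.
  ordval <- s * (nr * nc) + r * nc + c
  first <- tapply(ordval, memb, min)
  relab <- integer(length(first))
  relab[order(first)] <- seq_along(first)
  labels[fg] <- relab[memb]
  labels
}
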