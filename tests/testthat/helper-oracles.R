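# Independent oracles, coded without reference to the package internals.

# Connected components by iterative label propagation: every foreground
# voxel starts with its own linear index as label; labels are repeatedly
# replaced by the minimum over the voxel's neighborhood until a fixed point.
# Returns an integer array whose foreground entries are the minimum linear
# index of their component (a canonical labeling).
oracle_components <- function(mask, connectivity = 26L) {
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  d <- dim(mask)
  offs <- expand.grid(dr = -1:1, dc = -1:1, ds = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0 & offs$ds == 0), ]
  keep <- switch(as.character(connectivity),
    "26" = rep(TRUE, nrow(offs)),
    "18" = offs$ds == 0 | abs(offs$dr) + abs(offs$dc) <= 1,
    "6"  = offs$ds == 0 | (offs$dr == 0 & offs$dc == 0))
  offs <- offs[keep, ]
  lab <- array(NA_integer_, dim = d)
  fg <- which(mask != 0)
  lab[fg] <- fg
  pad_shift <- function(a, dr, dc, ds) {
    out <- array(NA_integer_, dim = d)
    if (max(1, 1 + dr) > min(d[1], d[1] + dr) ||
        max(1, 1 + dc) > min(d[2], d[2] + dc) ||
        max(1, 1 + ds) > min(d[3], d[3] + ds)) {
      return(out)
    }
    rs <- max(1, 1 + dr):min(d[1], d[1] + dr)
    cs <- max(1, 1 + dc):min(d[2], d[2] + dc)
    ss <- max(1, 1 + ds):min(d[3], d[3] + ds)
    out[rs, cs, ss] <- a[rs - dr, cs - dc, ss - ds]
    out
  }
  repeat {
    new <- lab
    for (k in seq_len(nrow(offs))) {
      sh <- pad_shift(lab, offs$dr[k], offs$dc[k], offs$ds[k])
      upd <- !is.na(new) & !is.na(sh) & sh < new
      new[upd] <- sh[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  lab[is.na(lab)] <- 0L
  lab
}

# Canonical partition signature of a labeling: for every foreground voxel,
# the minimum linear index of its component, in foreground order.
partition_signature <- function(labels) {
  fg <- which(labels != 0)
  tapply_min <- tapply(fg, labels[fg], min)
  unname(tapply_min[as.character(labels[fg])])
}

random_mask <- function(dims, p_fg, seed) {
  set.seed(seed)
  array(stats::runif(prod(dims)) < p_fg, dim = dims)
}

# Make a binary_stack object from a raw logical array (test fixture).
as_binary_stack <- function(mask, pixel_size_um = 0.1,
                            section_thickness_um = 0.07,
                            channel = "test") {
  structure(list(mask = mask, pixel_size_um = pixel_size_um,
                 section_thickness_um = section_thickness_um,
                 channel = channel, method = "fixed",
                 thresholds = rep(0.5, dim(mask)[3L])),
            class = "binary_stack")
}

# Brute-force ROI classification: for every candidate window, compute the
# min and max over window pixels of the distance to the nearest plaque
# pixel by explicit all-pairs arithmetic.
oracle_window_class <- function(plaque_mask, origin, w, pixel_size_um,
                                near_um, far_um) {
  pix <- which(plaque_mask, arr.ind = TRUE)
  rr <- origin[1L]:(origin[1L] + w - 1L)
  cc <- origin[2L]:(origin[2L] + w - 1L)
  if (any(plaque_mask[rr, cc])) return("core")
  if (nrow(pix) == 0L) return("far")
  grid <- expand.grid(r = rr, c = cc)
  dmin <- Inf; dmax <- 0
  for (i in seq_len(nrow(grid))) {
    d <- sqrt(min((pix[, 1L] - grid$r[i])^2 + (pix[, 2L] - grid$c[i])^2)) *
      pixel_size_um
    dmin <- min(dmin, d); dmax <- max(dmax, d)
  }
  if (dmax < near_um) "near" else if (dmin > far_um) "far" else "excluded"
}
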