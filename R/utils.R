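#' @keywords internal
"_PACKAGE"

# Derive a reproducible sub-stream seed from a root seed.
#
# Each stochastic component (punctum placement, jitter, noise, ROI sampling,
# per-animal streams, ...) draws from its own derived seed so that adding a
# component never perturbs the stream of another. Linear-congruential mixing
# keeps results in [1, 2^31 - 2], valid for set.seed().
derive_seed <- function(root, stream) {
  stopifnot(is.numeric(root), length(root) == 1L, is.finite(root))
  m <- 2147483647 # 2^31 - 1 (prime)
  x <- (as.double(root) %% m) * 48271 %% m
  x <- (x + as.double(stream) * 69621) %% m
  as.integer(x %% (m - 1) + 1)
}

# Run an expression with a locally derived seed, restoring the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Physical position of a 1-based pixel/section index (half-open convention):
# index i covers [ (i-1)*spacing, i*spacing ); its coordinate is (i-1)*spacing.
index_to_um <- function(i, spacing) (i - 1) * spacing

um_to_index <- function(u, spacing) floor(u / spacing) + 1L

# Euclidean distance map (um) from every pixel to the nearest TRUE pixel of
# `mask`. Pixels inside the mask get 0.
distance_to_mask_um <- function(mask, pixel_size_um) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) {
    return(matrix(Inf, nrow(mask), ncol(mask)))
  }
  d <- EBImage::distmap(matrix(as.numeric(!mask), nrow(mask), ncol(mask)))
  as.matrix(d) * pixel_size_um
}

# Border of a 2D mask: TRUE pixels 4-adjacent to a FALSE pixel (or the frame).
mask_border <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  mask & !inner
}

# (row, col) indices of the TRUE pixels of a matrix.
mask_pixels <- function(mask) {
  which(mask, arr.ind = TRUE)
}
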