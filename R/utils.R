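# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# 1-based voxel index -> physical coordinate of the voxel center (um).
index_to_um <- function(i, spacing) (i - 0.5) * spacing
# physical coordinate (um) -> continuous 1-based voxel index
um_to_index <- function(x, spacing) x / spacing + 0.5

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Shift matrix rows by `by` with edge replication.
shift_rows <- function(m, by) {
  n <- nrow(m)
  idx <- pmin(pmax(seq_len(n) + by, 1L), n)
  m[idx, , drop = FALSE]
}

# Separable Gaussian smoothing of an n-d array; sigma_vox gives the standard
# deviation per axis in voxel units (0 skips an axis). Edge-replicated.
smooth_gaussian <- function(a, sigma_vox) {
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  nd <- length(d)
  stopifnot(length(sigma_vox) == nd)
  for (ax in seq_len(nd)) {
    if (sigma_vox[ax] <= 0 || d[ax] == 1) next
    k <- gaussian_kernel(sigma_vox[ax])
    r <- (length(k) - 1L) / 2L
    perm <- c(ax, setdiff(seq_len(nd), ax))
    m <- aperm(a, perm)
    dm <- dim(m)
    dim(m) <- c(d[ax], prod(d[-ax]))
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * shift_rows(m, j - r - 1L)
    dim(out) <- dm
    a <- aperm(out, order(perm))
  }
  a
}

# Otsu threshold of a numeric array (256-bin histogram over the data range),
# delegated to EBImage.
otsu_threshold <- function(a) {
  rng <- range(a, finite = TRUE)
  if (diff(rng) == 0) return(rng[1])
  EBImage::otsu(EBImage::Image((a - rng[1]) / diff(rng)), range = c(0, 1),
                levels = 256L) * diff(rng) + rng[1]
}

# n-d connected component labeling (8/26-connectivity by default).
label_components <- function(mask, full = TRUE) {
  d <- dim(mask)
  cpp_label(as.logical(mask), as.integer(d), full)
}

# Apply `fun` over the last axis (time) of an array, returning an array one
# rank lower.
collapse_time <- function(a, fun) {
  d <- dim(a)
  nt <- d[length(d)]
  m <- matrix(a, prod(d[-length(d)]), nt)
  out <- fun(m)
  dim(out) <- d[-length(d)]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
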