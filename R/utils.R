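# Internal helpers shared across modules. Images are plain numeric matrices
# indexed [row, col]; binary masks are logical matrices on the same grid.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_same_grid <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must share the same grid: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Disk structuring element
#'
#' Pixels at Euclidean distance <= radius from the centre (chessboard of
#' offsets), the convention used for all morphological operations here.
#' @noRd
disk_kernel <- function(radius_px) {
  stopifnot(radius_px >= 0)
  r <- as.integer(round(radius_px))
  if (r == 0L) return(matrix(1, 1L, 1L))
  o <- -r:r
  k <- outer(o, o, function(a, b) as.numeric(a * a + b * b <= radius_px^2))
  k
}

#' Reflect-pad a matrix by `r` pixels on every side
#' @noRd
reflect_pad <- function(x, r) {
  if (r == 0L) return(x)
  nr <- nrow(x); nc <- ncol(x)
  if (r >= nr || r >= nc) stop("padding exceeds image size", call. = FALSE)
  ri <- c(r:1, 1:nr, nr:(nr - r + 1L))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1L))
  x[ri, ci, drop = FALSE]
}

#' Moving box sum over a (2r+1) x (2r+1) window with reflected borders
#'
#' Implemented with summed-area tables so the cost is independent of the
#' window size.
#' @noRd
box_sum <- function(x, r) {
  r <- as.integer(r)
  if (r == 0L) return(x)
  p <- reflect_pad(x, r)
  # summed-area table with a zero first row/col
  s <- rbind(0, apply(p, 2, cumsum))
  s <- cbind(0, t(apply(s, 1, cumsum)))
  w <- 2L * r + 1L
  nr <- nrow(x); nc <- ncol(x)
  i0 <- 1:nr; j0 <- 1:nc          # top-left corner in padded coords (0-based in s)
  i1 <- i0 + w; j1 <- j0 + w
  s[i1, j1] - s[i0, j1] - s[i1, j0] + s[i0, j0]
}

#' Moving box mean, window clamped to whole image when it does not fit
#' @noRd
box_mean <- function(x, r) {
  if (2L * r + 1L >= min(dim(x))) {
    return(matrix(mean(x), nrow(x), ncol(x)))
  }
  box_sum(x, r) / (2L * r + 1L)^2
}

#' 8-connected component labelling
#'
#' EBImage::bwlabel() is 4-connected; diagonal contacts are merged here with
#' a union-find pass over the label adjacencies, and labels are renumbered
#' contiguously in raster order of first occurrence.
#' @noRd
label8 <- function(mask) {
  stopifnot(is.logical(mask))
  l4 <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  storage.mode(l4) <- "integer"
  n <- max(l4)
  if (n <= 1L) return(relabel_raster(l4))
  nr <- nrow(l4); nc <- ncol(l4)
  # diagonal neighbour pairs of distinct positive labels
  a1 <- l4[-nr, -nc]; b1 <- l4[-1, -1]     # down-right
  a2 <- l4[-nr, -1];  b2 <- l4[-1, -nc]    # down-left
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- l4
  out[l4 > 0L] <- root[l4[l4 > 0L]]
  relabel_raster(out)
}

#' Renumber positive labels contiguously by raster order of first occurrence
#' @noRd
relabel_raster <- function(labels) {
  storage.mode(labels) <- "integer"
  pos <- labels > 0L
  if (!any(pos)) return(labels)
  u <- unique(labels[pos])              # column-major == raster order here
  map <- integer(max(u))
  map[u] <- seq_along(u)
  labels[pos] <- map[labels[pos]]
  labels
}

#' Per-label pixel counts as a named integer vector (label k at index k)
#' @noRd
label_counts <- function(labels, nbins = max(labels)) {
  if (nbins < 1L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = nbins)
}

#' Count mask-positive pixels per label
#' @noRd
label_mask_counts <- function(labels, mask, nbins = max(labels)) {
  if (nbins < 1L) return(integer(0))
  tabulate(labels[mask & labels > 0L], nbins = nbins)
}

#' Bounding box of a logical mask, optionally padded and clipped to the image
#' @noRd
mask_bbox <- function(mask, pad = 0L) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  list(
    r0 = max(1L, min(idx[, 1L]) - pad), r1 = min(nrow(mask), max(idx[, 1L]) + pad),
    c0 = max(1L, min(idx[, 2L]) - pad), c1 = min(ncol(mask), max(idx[, 2L]) + pad)
  )
}
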