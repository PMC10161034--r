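# Internal 2-D binary morphology on logical matrices.  All routines are
# vectorised sweep/shift implementations: adequate for phantom-sized images
# without compiled code.

# 4-connected component labelling by directional label propagation.  Each
# sweep propagates the running maximum label along rows and columns inside the
# mask; convex-ish anatomy converges in a handful of sweeps.
cc_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0, nr, nc)
  lab[mask] <- which(mask)
  if (!any(mask)) return(lab)
  repeat {
    old <- lab
    for (i in 2:nr) {
      m <- mask[i, ] & mask[i - 1L, ]
      if (any(m)) lab[i, m] <- pmax(lab[i, m], lab[i - 1L, m])
    }
    for (i in (nr - 1L):1) {
      m <- mask[i, ] & mask[i + 1L, ]
      if (any(m)) lab[i, m] <- pmax(lab[i, m], lab[i + 1L, m])
    }
    for (j in 2:nc) {
      m <- mask[, j] & mask[, j - 1L]
      if (any(m)) lab[m, j] <- pmax(lab[m, j], lab[m, j - 1L])
    }
    for (j in (nc - 1L):1) {
      m <- mask[, j] & mask[, j + 1L]
      if (any(m)) lab[m, j] <- pmax(lab[m, j], lab[m, j + 1L])
    }
    if (identical(old, lab)) break
  }
  ids <- sort(unique(lab[mask]))
  lab[mask] <- match(lab[mask], ids)
  lab
}

# Drop components smaller than min_size pixels.
filter_small_components <- function(mask, min_size) {
  if (min_size <= 1L || !any(mask)) return(mask)
  lab <- cc_label(mask)
  sizes <- tabulate(lab[mask])
  keep <- which(sizes >= min_size)
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}

largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- cc_label(mask)
  sizes <- tabulate(lab[mask])
  lab == which.max(sizes)
}

# Fill interior holes: components of the complement not touching the border.
fill_holes <- function(mask) {
  comp <- cc_label(!mask)
  border_ids <- unique(c(comp[1, ], comp[nrow(comp), ],
                         comp[, 1], comp[, ncol(comp)]))
  border_ids <- border_ids[border_ids != 0]
  mask | (comp != 0 & !matrix(comp %in% border_ids, nrow(comp), ncol(comp)))
}

shift_mask <- function(m, di, dj, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  si <- seq_len(nr) - di; sj <- seq_len(nc) - dj
  oi <- si >= 1 & si <= nr; oj <- sj >= 1 & sj <= nc
  out[oi, oj] <- m[si[oi], sj[oj]]
  out
}

# One dilation step; conn 4 (diamond) or 8 (square).
dilate1 <- function(m, conn = 4L) {
  out <- m |
    shift_mask(m, 1L, 0L) | shift_mask(m, -1L, 0L) |
    shift_mask(m, 0L, 1L) | shift_mask(m, 0L, -1L)
  if (conn == 8L)
    out <- out |
      shift_mask(m, 1L, 1L) | shift_mask(m, 1L, -1L) |
      shift_mask(m, -1L, 1L) | shift_mask(m, -1L, -1L)
  out
}

erode1 <- function(m, conn = 4L) !dilate1(!m, conn)

# Approximate disk dilation/erosion of radius r pixels by alternating 4- and
# 8-connected unit steps (octagonal structuring element).
dilate <- function(m, r) {
  r <- as.integer(round(r))
  for (k in seq_len(max(r, 0L))) m <- dilate1(m, if (k %% 2L) 4L else 8L)
  m
}

erode <- function(m, r) {
  r <- as.integer(round(r))
  for (k in seq_len(max(r, 0L))) m <- erode1(m, if (k %% 2L) 4L else 8L)
  m
}

morph_close <- function(m, r) erode(dilate(m, r), r)

# Row/column-separable Gaussian blur with edge renormalisation.
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma_px))
  kern <- function(n) {
    idx <- seq_len(n)
    K <- outer(idx, idx, function(i, j) {
      d <- abs(i - j)
      ifelse(d <= half, exp(-d^2 / (2 * sigma_px^2)), 0)
    })
    K / rowSums(K)
  }
  kern(nrow(img)) %*% img %*% t(kern(ncol(img)))
}
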