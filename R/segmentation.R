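#' IsoData (iterative intermeans) auto-threshold
#'
#' Computes the classic Ridler--Calvard threshold on the 256-bin histogram of
#' an 8-bit image: starting from the global mean, iterate
#' `t <- (mean(pixels <= t) + mean(pixels > t)) / 2` (rounded to the nearest
#' bin) until a fixed point. The full histogram is used, including the extreme
#' bins. Foreground is the bright class: `mask = image > threshold`.
#'
#' A constant image has no foreground; this degenerate case is reported via
#' an empty mask with the threshold set to the constant value, not an error.
#'
#' @param image integer matrix with values in 0--255.
#' @return a list of class `binary_mask` with elements `mask` (logical
#'   matrix, `TRUE` above threshold) and `threshold_value` (in 0--255).
#' @export
isodata_threshold <- function(image) {
  if (!is.matrix(image) || length(image) == 0)
    stop_param("image must be a non-empty matrix")
  if (any(image < 0) || any(image > 255))
    stop_param("image values must lie in [0, 255]")
  h <- tabulate(as.integer(image) + 1L, nbins = 256L)
  lev <- 0:255
  if (sum(h > 0) <= 1L) {  # constant image: no foreground class exists
    t_const <- lev[h > 0][1]
    return(structure(list(mask = matrix(FALSE, nrow(image), ncol(image)),
                          threshold_value = t_const),
                     class = "binary_mask"))
  }
  t_cur <- round(sum(h * lev) / sum(h))
  seen <- logical(256)
  repeat {
    if (seen[t_cur + 1]) break  # guard against round-off 2-cycles
    seen[t_cur + 1] <- TRUE
    lo <- lev <= t_cur
    m_lo <- sum(h[lo] * lev[lo]) / sum(h[lo])
    m_hi <- sum(h[!lo] * lev[!lo]) / sum(h[!lo])
    if (is.nan(m_hi)) {  # all mass at or below t: step down
      t_new <- t_cur - 1
    } else {
      t_new <- round((m_lo + m_hi) / 2)
    }
    if (t_new == t_cur) break
    t_cur <- t_new
  }
  structure(list(mask = matrix(image > t_cur, nrow(image), ncol(image)),
                 threshold_value = as.integer(t_cur)),
            class = "binary_mask")
}

#' Watershed segmentation of a nuclear mask
#'
#' Splits touching nuclei: the Euclidean distance transform of the foreground
#' is lightly smoothed, its regional maxima (with a minimum peak separation)
#' become seeds, and a seeded watershed floods the negated distance map
#' restricted to the foreground. Plateau maxima are merged into a single seed
#' (the plateau's central pixel), so a clean disk yields exactly one label.
#' Output labels cover exactly the foreground pixels.
#'
#' @param mask a `binary_mask` from [isodata_threshold()], or a logical matrix.
#' @param min_peak_distance minimum separation between watershed seeds, px.
#' @param smooth_sigma Gaussian sigma (px) applied to the distance map before
#'   peak detection; the flooding itself uses the unsmoothed distances.
#' @return integer label matrix (0 = background); labels are consecutive
#'   from 1 in scan order.
#' @export
watershed_nuclei <- function(mask, min_peak_distance = 5, smooth_sigma = 1) {
  m <- if (inherits(mask, "binary_mask")) mask$mask else mask
  if (!is.logical(m) || !is.matrix(m))
    stop_param("mask must be a logical matrix or binary_mask")
  if (!any(m)) return(matrix(0L, nrow(m), ncol(m)))
  dist <- cpp_distance_transform(m)
  ds <- if (smooth_sigma > 0) cpp_gaussian_blur(dist, smooth_sigma) else dist
  ds[!m] <- 0
  # regional maxima under a Chebyshev window of radius = min separation
  mx <- cpp_max_filter(ds, as.integer(min_peak_distance))
  peak <- m & (ds >= mx - 1e-9) & (ds > 0)
  peak_lab <- cpp_label_components(peak, 8L)
  n_seeds <- max(peak_lab)
  # one seed pixel per plateau component: the member nearest its centroid
  seeds <- matrix(0L, nrow(m), ncol(m))
  idx <- which(peak_lab > 0)
  labs <- peak_lab[idx]
  rr <- (idx - 1L) %% nrow(m) + 1L
  cc <- (idx - 1L) %/% nrow(m) + 1L
  for (k in seq_len(n_seeds)) {
    sel <- labs == k
    mr <- mean(rr[sel]); mc <- mean(cc[sel])
    j <- which.min((rr[sel] - mr)^2 + (cc[sel] - mc)^2)
    seeds[rr[sel][j], cc[sel][j]] <- k
  }
  cpp_watershed(-dist, seeds, m)
}

#' Size- and border-filter labeled nucleus segments
#'
#' Retains segments whose pixel area lies in `[min_area, max_area]`
#' (inclusive) and, when `exclude_border` is set, that touch no image edge --
#' partial nuclei at the field boundary would otherwise bias counts.
#' The number of retained segments is the field's nucleus count.
#'
#' @param labels integer label matrix (0 = background).
#' @param min_area,max_area inclusive pixel-area window (defaults 15 and 230).
#' @param exclude_border drop segments touching the first/last row or column.
#' @return list with `segments` (data frame: `label`, `area_px`,
#'   `centroid_row`, `centroid_col`, `touches_border`, `retained`) and
#'   `labels` (label matrix with non-retained segments zeroed, original label
#'   ids kept).
#' @export
filter_segments <- function(labels, min_area = 15, max_area = 230,
                            exclude_border = TRUE) {
  if (min_area > max_area)
    stop_param("min_area (", min_area, ") exceeds max_area (", max_area, ")")
  H <- nrow(labels); W <- ncol(labels)
  idx <- which(labels > 0)
  if (length(idx) == 0) {
    return(list(segments = data.frame(label = integer(0), area_px = integer(0),
                                      centroid_row = numeric(0),
                                      centroid_col = numeric(0),
                                      touches_border = logical(0),
                                      retained = logical(0)),
                labels = matrix(0L, H, W)))
  }
  lab <- labels[idx]
  rr <- (idx - 1L) %% H + 1L
  cc <- (idx - 1L) %/% H + 1L
  ids <- sort(unique(lab))
  key <- match(lab, ids)
  area <- tabulate(key, nbins = length(ids))
  cen_r <- rowsum(rr, key)[, 1] / area
  cen_c <- rowsum(cc, key)[, 1] / area
  border_px <- rr == 1L | rr == H | cc == 1L | cc == W
  touches <- rowsum(as.integer(border_px), key)[, 1] > 0
  retained <- area >= min_area & area <= max_area &
    (!exclude_border | !touches)
  seg <- data.frame(label = ids, area_px = area,
                    centroid_row = cen_r, centroid_col = cen_c,
                    touches_border = touches, retained = retained)
  out_lab <- labels
  drop <- !retained[key]
  out_lab[idx[drop]] <- 0L
  list(segments = seg, labels = out_lab)
}

#' Segment nuclei on the DAPI channel
#'
#' Convenience composition of the nuclear-segmentation steps:
#' [isodata_threshold()], [watershed_nuclei()] and [filter_segments()].
#'
#' @param dapi integer matrix, the nuclear-stain channel.
#' @param min_area,max_area,exclude_border passed to [filter_segments()].
#' @param min_peak_distance passed to [watershed_nuclei()].
#' @return as [filter_segments()], plus `threshold_value`.
#' @export
segment_nuclei <- function(dapi, min_area = 15, max_area = 230,
                           exclude_border = TRUE, min_peak_distance = 5) {
  bm <- isodata_threshold(dapi)
  lab <- watershed_nuclei(bm, min_peak_distance = min_peak_distance)
  out <- filter_segments(lab, min_area = min_area, max_area = max_area,
                         exclude_border = exclude_border)
  out$threshold_value <- bm$threshold_value
  out
}
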