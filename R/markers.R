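#' Detect marker segments on a green/red immunofluorescence channel
#'
#' IsoData threshold, 8-connected component labeling, then the same
#' 15--230 px size window used for nuclei (to suppress speckle and large
#' artifacts). Border segments are retained: only partial *nuclei* warrant
#' edge exclusion, marker signal clipped by the field edge still indicates
#' staining of an interior nucleus.
#'
#' @param channel_image integer matrix in 0--255.
#' @param min_area,max_area inclusive size window in pixels.
#' @return list with `segments` data frame and filtered `labels` matrix,
#'   as [filter_segments()].
#' @export
detect_marker_segments <- function(channel_image, min_area = 15,
                                   max_area = 230) {
  bm <- isodata_threshold(channel_image)
  lab <- cpp_label_components(bm$mask, 8L)
  filter_segments(lab, min_area = min_area, max_area = max_area,
                  exclude_border = FALSE)
}

#' Call per-nucleus marker positivity
#'
#' For every retained nucleus the outline is projected onto the marker
#' channels: under the default `"intersection"` rule a nucleus is positive
#' for a channel iff at least one size-filtered marker segment shares a pixel
#' with the nucleus region; under `"containment"` the marker segment must lie
#' entirely within one nucleus. A nucleus positive for both channels is
#' double-positive.
#'
#' @param nuclei result of [filter_segments()]/[segment_nuclei()] on DAPI
#'   (list with `segments` and `labels`).
#' @param green_labels,red_labels filtered marker label matrices from
#'   [detect_marker_segments()] (either may be `NULL` when that channel was
#'   not stained).
#' @param rule `"intersection"` (default) or `"containment"`.
#' @return data frame (one row per retained nucleus): `nucleus_label`,
#'   `green_positive`, `red_positive`, `double_positive`.
#' @export
assign_markers <- function(nuclei, green_labels = NULL, red_labels = NULL,
                           rule = c("intersection", "containment")) {
  rule <- match.arg(rule)
  seg <- nuclei$segments[nuclei$segments$retained, , drop = FALSE]
  if (anyDuplicated(seg$label))
    stop_param("duplicate nucleus labels")
  nl <- nuclei$labels
  positive_set <- function(marker_labels) {
    if (is.null(marker_labels)) return(integer(0))
    if (!identical(dim(marker_labels), dim(nl)))
      stop_param("marker and nucleus label images differ in shape")
    idx <- which(marker_labels > 0)
    if (length(idx) == 0) return(integer(0))
    if (rule == "intersection") {
      unique(nl[idx][nl[idx] > 0])
    } else {
      # containment: every pixel of the marker segment inside one nucleus
      under <- split(nl[idx], marker_labels[idx])
      hosts <- vapply(under, function(v) {
        u <- unique(v)
        if (length(u) == 1L && u != 0L) u else 0L
      }, integer(1))
      unique(hosts[hosts > 0])
    }
  }
  g <- positive_set(green_labels)
  r <- positive_set(red_labels)
  data.frame(nucleus_label = seg$label,
             green_positive = seg$label %in% g,
             red_positive = seg$label %in% r,
             double_positive = seg$label %in% g & seg$label %in% r)
}

#' Detect myotubes on the MyHC channel
#'
#' A myotube is a MyHC-positive object containing at least two nuclei.
#' The MyHC channel is IsoData-thresholded, connected components smaller
#' than `min_myotube_area` are discarded as speckle, each retained nucleus
#' whose centroid falls inside a component is assigned to it, and components
#' with at least two assigned nuclei become myotube records.
#'
#' @param myhc_image integer matrix in 0--255.
#' @param nuclei result of [segment_nuclei()] (retained nuclei are used).
#' @param min_myotube_area minimum MyHC component area in pixels.
#' @return list with `myotubes` (data frame sorted by label: `myotube_label`,
#'   `area_px`, `n_nuclei`), `membership` (data frame `nucleus_label`,
#'   `myotube_label`) and `n_nuclei_in_myotubes`.
#' @export
detect_myotubes <- function(myhc_image, nuclei, min_myotube_area = 300) {
  bm <- isodata_threshold(myhc_image)
  lab <- cpp_label_components(bm$mask, 8L)
  seg <- nuclei$segments[nuclei$segments$retained, , drop = FALSE]
  empty <- list(myotubes = data.frame(myotube_label = integer(0),
                                      area_px = integer(0),
                                      n_nuclei = integer(0)),
                membership = data.frame(nucleus_label = integer(0),
                                        myotube_label = integer(0)),
                n_nuclei_in_myotubes = 0L)
  if (max(lab) == 0L || nrow(seg) == 0L) return(empty)
  area <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(area >= min_myotube_area)
  if (length(keep) == 0L) return(empty)
  # nucleus -> component via the component label under the centroid pixel
  pr <- pmin(pmax(round(seg$centroid_row), 1L), nrow(lab))
  pc <- pmin(pmax(round(seg$centroid_col), 1L), ncol(lab))
  comp <- lab[cbind(pr, pc)]
  comp[!comp %in% keep] <- 0L
  counts <- table(comp[comp > 0])
  tube_ids <- as.integer(names(counts))[counts >= 2L]
  tube_ids <- sort(tube_ids)
  membership <- data.frame(nucleus_label = seg$label[comp %in% tube_ids],
                           myotube_label = comp[comp %in% tube_ids])
  list(myotubes = data.frame(myotube_label = tube_ids,
                             area_px = area[tube_ids],
                             n_nuclei = as.integer(counts[as.character(tube_ids)])),
       membership = membership,
       n_nuclei_in_myotubes = nrow(membership))
}

#' Quantify one field
#'
#' Runs the full per-field pipeline -- split channels, segment nuclei on
#' DAPI, detect and assign marker segments, and (when a `myhc` channel is
#' present or requested) detect myotubes -- and returns the per-field counts
#' from which all indices derive.
#'
#' Modes mirror the staining combinations: `"pax7-myod"` (green = Pax7,
#' red = MyoD), `"myog-myod"` (green = MyoG, red = MyoD) and `"myhc"`
#' (myotube stain only). `"auto"` quantifies every channel present.
#'
#' @param stack a [channel_stack].
#' @param mode staining mode; determines which channels are required.
#' @param config list of parameters: `min_area`, `max_area`,
#'   `exclude_border`, `min_peak_distance`, `marker_rule`,
#'   `min_myotube_area`.
#' @return a one-row data frame of class `field_quantification`:
#'   provenance labels, `mode`, `n_nuclei`, `n_green`, `n_red`, `n_double`,
#'   `n_myotubes`, `n_nuclei_in_myotubes` (marker/myotube counts are `NA`
#'   when the corresponding channel is absent from the mode).
#' @export
quantify_field <- function(stack, mode = c("auto", "pax7-myod", "myog-myod",
                                           "myhc"),
                           config = list()) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "channel_stack"))
  cfg <- modifyList(list(min_area = 15, max_area = 230, exclude_border = TRUE,
                         min_peak_distance = 5, marker_rule = "intersection",
                         min_myotube_area = 300), config)
  chans <- split_channels(stack)
  if (!"dapi" %in% names(chans))
    stop_param("stack has no 'dapi' channel")
  need <- switch(mode,
                 "pax7-myod" = c("green", "red"),
                 "myog-myod" = c("green", "red"),
                 "myhc" = "myhc",
                 "auto" = character(0))
  missing_ch <- setdiff(need, names(chans))
  if (length(missing_ch))
    stop_param("mode '", mode, "' requires channel(s): ",
               paste(missing_ch, collapse = ", "))
  use_markers <- mode %in% c("pax7-myod", "myog-myod") ||
    (mode == "auto" && any(c("green", "red") %in% names(chans)))
  use_myhc <- mode == "myhc" || (mode == "auto" && "myhc" %in% names(chans))
  nuc <- segment_nuclei(chans$dapi, min_area = cfg$min_area,
                        max_area = cfg$max_area,
                        exclude_border = cfg$exclude_border,
                        min_peak_distance = cfg$min_peak_distance)
  n_nuclei <- sum(nuc$segments$retained)
  n_green <- n_red <- n_double <- NA_integer_
  if (use_markers) {
    gl <- if ("green" %in% names(chans))
      detect_marker_segments(chans$green, cfg$min_area, cfg$max_area)$labels
    rl <- if ("red" %in% names(chans))
      detect_marker_segments(chans$red, cfg$min_area, cfg$max_area)$labels
    ph <- assign_markers(nuc, green_labels = gl, red_labels = rl,
                         rule = cfg$marker_rule)
    n_green <- sum(ph$green_positive)
    n_red <- sum(ph$red_positive)
    n_double <- sum(ph$double_positive)
  }
  n_myotubes <- n_in <- NA_integer_
  if (use_myhc) {
    mt <- detect_myotubes(chans$myhc, nuc,
                          min_myotube_area = cfg$min_myotube_area)
    n_myotubes <- nrow(mt$myotubes)
    n_in <- mt$n_nuclei_in_myotubes
  }
  prov <- stack$provenance
  out <- data.frame(coating = prov$coating %||% NA_character_,
                    day = prov$day %||% NA_integer_,
                    well = prov$well %||% NA_integer_,
                    field = prov$field %||% NA_integer_,
                    mode = mode,
                    n_nuclei = n_nuclei, n_green = n_green, n_red = n_red,
                    n_double = n_double, n_myotubes = n_myotubes,
                    n_nuclei_in_myotubes = n_in)
  class(out) <- c("field_quantification", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
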