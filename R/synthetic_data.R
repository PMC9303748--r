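#' Scene parameters for the synthetic field generator
#'
#' Describes one simulated microscope field of a myoblast culture at 10x
#' magnification. Defaults encode the imaging conventions the pipeline is
#' designed for: 1 um/px, round nuclei of ~10 um diameter (about 78 px of
#' area, comfortably inside the 15--230 px acceptance window), nuclear-
#' localized green/red marker signal, and elongated cytoplasmic MyHC-positive
#' myotubes that each span at least two nuclei.
#'
#' Marker co-expression is specified by the double-positive probability
#' `p_double` together with the marginals `p_green >= p_double` and
#' `p_red >= p_double`, so a target index (double / one marginal) can be
#' dialed in exactly.
#'
#' @param n_nuclei total nuclei in the field (fused + unfused).
#' @param nucleus_diameter_um,nucleus_diameter_sd_um mean and SD of the
#'   nucleus diameter in micrometers (draws are clamped to 6--16 um so that
#'   rendered areas stay inside the size window).
#' @param pixel_size_um micrometers per pixel (1.0 at 10x by convention).
#' @param p_green,p_red,p_double per-nucleus marker probabilities;
#'   `p_double <= min(p_green, p_red)` and
#'   `p_green + p_red - p_double <= 1`.
#' @param n_myotubes number of myotubes to place.
#' @param nuclei_per_myotube mean nuclei per myotube; each myotube receives
#'   `2 + Poisson(nuclei_per_myotube - 2)` member nuclei (minimum 2).
#' @param noise_sd additive Gaussian read noise, 8-bit intensity units.
#' @param blur_sigma_px Gaussian point-spread blur, pixels.
#' @param image_size height and width of the field, pixels.
#' @param min_separation_px floor on the distance between nucleus centroids
#'   (the effective separation also accounts for the two radii).
#' @param overlap_fraction fraction of unfused nuclei deliberately placed
#'   close enough to touch a neighbour, to exercise the watershed split.
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   output.
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(n_nuclei = 150,
                         nucleus_diameter_um = 10,
                         nucleus_diameter_sd_um = 1.2,
                         pixel_size_um = 1,
                         p_green = 0.5, p_red = 0.5, p_double = 0.25,
                         n_myotubes = 0, nuclei_per_myotube = 4,
                         noise_sd = 5, blur_sigma_px = 0.8,
                         image_size = c(512, 512),
                         min_separation_px = 12,
                         overlap_fraction = 0.08,
                         seed = 1) {
  if (!is_count(n_nuclei)) stop_param("n_nuclei must be a non-negative integer")
  if (!is_count(n_myotubes)) stop_param("n_myotubes must be a non-negative integer")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop_param("pixel_size_um must be positive")
  for (p in c(p_green = p_green, p_red = p_red, p_double = p_double)) {
    if (!is.numeric(p) || is.na(p) || p < 0 || p > 1)
      stop_param("marker probabilities must lie in [0, 1]")
  }
  if (p_double > min(p_green, p_red) + 1e-12)
    stop_param("p_double must not exceed min(p_green, p_red)")
  if (p_green + p_red - p_double > 1 + 1e-12)
    stop_param("p_green + p_red - p_double must not exceed 1")
  if (nuclei_per_myotube < 2)
    stop_param("nuclei_per_myotube must be at least 2")
  if (noise_sd < 0 || blur_sigma_px < 0)
    stop_param("noise_sd and blur_sigma_px must be non-negative")
  if (length(image_size) != 2 || any(image_size < 64))
    stop_param("image_size must be two dimensions of at least 64 px")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop_param("overlap_fraction must lie in [0, 1]")
  structure(list(n_nuclei = as.integer(n_nuclei),
                 nucleus_diameter_um = nucleus_diameter_um,
                 nucleus_diameter_sd_um = nucleus_diameter_sd_um,
                 pixel_size_um = pixel_size_um,
                 p_green = p_green, p_red = p_red, p_double = p_double,
                 n_myotubes = as.integer(n_myotubes),
                 nuclei_per_myotube = nuclei_per_myotube,
                 noise_sd = noise_sd, blur_sigma_px = blur_sigma_px,
                 image_size = as.integer(image_size),
                 min_separation_px = min_separation_px,
                 overlap_fraction = overlap_fraction,
                 seed = as.integer(seed)),
            class = "scene_params")
}

# linear indices of the pixels of a disk, clipped to the image
disk_indices <- function(H, W, r0, c0, radius) {
  rr <- max(1L, floor(r0 - radius)):min(H, ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(W, ceiling(c0 + radius))
  g <- expand.grid(r = rr, c = cc)
  keep <- (g$r - r0)^2 + (g$c - c0)^2 <= radius^2
  (g$c[keep] - 1L) * H + g$r[keep]
}

# linear indices of a capsule (all pixels within w/2 of the segment p1--p2)
capsule_indices <- function(H, W, p1, p2, width) {
  hw <- width / 2
  rr <- max(1L, floor(min(p1[1], p2[1]) - hw)):min(H, ceiling(max(p1[1], p2[1]) + hw))
  cc <- max(1L, floor(min(p1[2], p2[2]) - hw)):min(W, ceiling(max(p1[2], p2[2]) + hw))
  g <- expand.grid(r = rr, c = cc)
  v <- p2 - p1
  len2 <- sum(v^2)
  t <- if (len2 == 0) rep(0, nrow(g)) else
    pmin(1, pmax(0, ((g$r - p1[1]) * v[1] + (g$c - p1[2]) * v[2]) / len2))
  d2 <- (g$r - (p1[1] + t * v[1]))^2 + (g$c - (p1[2] + t * v[2]))^2
  keep <- d2 <= hw^2
  (g$c[keep] - 1L) * H + g$r[keep]
}

# shortest distance between two line segments (for tube overlap rejection)
segment_distance <- function(a1, a2, b1, b2) {
  pts_t <- seq(0, 1, length.out = 9)
  pa <- cbind(a1[1] + pts_t * (a2[1] - a1[1]), a1[2] + pts_t * (a2[2] - a1[2]))
  point_seg <- function(p, q1, q2) {
    v <- q2 - q1
    len2 <- sum(v^2)
    t <- if (len2 == 0) 0 else min(1, max(0, sum((p - q1) * v) / len2))
    sqrt(sum((p - (q1 + t * v))^2))
  }
  d1 <- min(vapply(seq_len(nrow(pa)), function(i) point_seg(pa[i, ], b1, b2),
                   numeric(1)))
  pb <- cbind(b1[1] + pts_t * (b2[1] - b1[1]), b1[2] + pts_t * (b2[2] - b1[2]))
  d2 <- min(vapply(seq_len(nrow(pb)), function(i) point_seg(pb[i, ], a1, a2),
                   numeric(1)))
  min(d1, d2)
}

#' Generate one synthetic field with ground truth
#'
#' Renders a multi-channel 8-bit field of a simulated myoblast culture and
#' returns it together with the generating ground truth. The blue (DAPI)
#' channel shows every nucleus as a bright disk; green and red channels show
#' nuclear-localized marker signal only over marker-positive nuclei; the MyHC
#' channel shows elongated capsule-shaped myotubes, each overlapping its
#' member nuclei. Rendering order: place myotubes, place their member nuclei
#' along the tube axis, place unfused nuclei by rejection sampling (minimum
#' centroid separation, centroids kept outside myotubes), assign marker
#' states, render, blur, add read noise, quantize to 8 bits.
#'
#' @param params a [scene_params] object.
#' @param channels which channels to render (subset of
#'   `c("dapi", "green", "red", "myhc")`; `dapi` is always rendered).
#' @param provenance provenance labels stored on the returned stack.
#' @return list with `stack` (a [channel_stack]) and `truth` (class
#'   `ground_truth`: `nuclei` and `myotubes` data frames, `true_counts`,
#'   and `true_indices` computed by applying the index formulas to the true
#'   states).
#' @export
generate_field <- function(params,
                           channels = c("dapi", "green", "red", "myhc"),
                           provenance = list()) {
  stopifnot(inherits(params, "scene_params"))
  channels <- union("dapi", match.arg(channels, several.ok = TRUE))
  with_seed(params$seed, generate_field_impl(params, channels, provenance))
}

generate_field_impl <- function(params, channels, provenance) {
  H <- params$image_size[1]
  W <- params$image_size[2]
  n <- params$n_nuclei
  bg <- 8

  # --- myotube member counts (each tube has >= 2 nuclei) ---
  m <- integer(0)
  if (params$n_myotubes > 0) {
    if (2L * params$n_myotubes > n)
      stop_param("n_nuclei too small for ", params$n_myotubes,
                 " myotubes of >= 2 nuclei each")
    m <- 2L + rpois(params$n_myotubes, params$nuclei_per_myotube - 2)
    while (sum(m) > n) m[which.max(m)] <- m[which.max(m)] - 1L
  }

  # --- place myotube capsules (reject overlapping placements) ---
  tubes <- NULL
  if (length(m) > 0) {
    tubes <- data.frame(id = seq_along(m), r1 = NA_real_, c1 = NA_real_,
                        r2 = NA_real_, c2 = NA_real_, width = NA_real_,
                        n_members = m)
    for (j in seq_along(m)) {
      wdt <- runif(1, 10, 20)
      best <- NULL
      best_d <- -Inf
      for (a in seq_len(400)) {
        len_max <- min(200, sqrt((H - wdt - 8)^2 + (W - wdt - 8)^2))
        if (len_max < 60)
          stop_param("image too small to place 60-px myotubes")
        len <- runif(1, 60, len_max)
        th <- runif(1, 0, pi)
        half <- c(cos(th), sin(th)) * len / 2
        # pick the center so both capsule ends stay inside the image
        lo <- abs(half) + wdt / 2 + 3
        hi <- c(H, W) - lo
        if (any(hi <= lo)) next
        ctr <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
        p1 <- ctr - half
        p2 <- ctr + half
        dmin <- Inf
        if (j > 1) {
          for (k in seq_len(j - 1)) {
            dk <- segment_distance(p1, p2, c(tubes$r1[k], tubes$c1[k]),
                                   c(tubes$r2[k], tubes$c2[k])) -
              (wdt + tubes$width[k]) / 2
            dmin <- min(dmin, dk)
          }
        }
        if (dmin > 2) { best <- list(p1 = p1, p2 = p2); break }
        if (dmin > best_d) { best_d <- dmin; best <- list(p1 = p1, p2 = p2) }
      }
      if (is.null(best))
        stop_param("could not place myotube ", j, " inside the image")
      tubes[j, c("r1", "c1")] <- best$p1
      tubes[j, c("r2", "c2")] <- best$p2
      tubes$width[j] <- wdt
    }
    # rebalance members toward longer tubes: each tube can hold about one
    # nucleus per 12 px of axis without its nuclei touching, and real
    # myotubes hold more nuclei the longer they are
    len_j <- sqrt((tubes$r2 - tubes$r1)^2 + (tubes$c2 - tubes$c1)^2)
    cap <- pmax(2L, as.integer(floor(len_j / 12)))
    repeat {
      over <- which(m > cap)
      slack <- which(m < cap)
      if (length(over) == 0 || length(slack) == 0) break
      m[over[1]] <- m[over[1]] - 1L
      j2 <- slack[which.max(cap[slack] - m[slack])]
      m[j2] <- m[j2] + 1L
    }
    tubes$n_members <- m
  }

  # --- nucleus radii (px), clamped so rendered areas stay in [15, 230] ---
  d_um <- pmin(16, pmax(6, rnorm(n, params$nucleus_diameter_um,
                                 params$nucleus_diameter_sd_um)))
  radius <- d_um / (2 * params$pixel_size_um)

  # --- nucleus placement ---
  cen <- matrix(NA_real_, n, 2)
  tube_of <- rep(NA_integer_, n)
  i <- 0L
  if (length(m) > 0) {
    for (j in seq_along(m)) {
      p1 <- c(tubes$r1[j], tubes$c1[j])
      p2 <- c(tubes$r2[j], tubes$c2[j])
      wdt <- tubes$width[j]
      for (k in seq_len(m[j])) {
        i <- i + 1L
        t_ax <- (k - 0.5) / m[j] + runif(1, -0.2, 0.2) / m[j]
        t_ax <- min(0.95, max(0.05, t_ax))
        lat_max <- max(0.5, wdt / 2 - 2)
        lat <- runif(1, -lat_max, lat_max)
        v <- p2 - p1
        nv <- c(-v[2], v[1]) / sqrt(sum(v^2))
        p <- p1 + t_ax * v + lat * nv
        cen[i, ] <- pmin(c(H, W) - 8, pmax(8, p))
        tube_of[i] <- j
      }
    }
  }
  n_bg <- n - i
  if (n_bg > 0) {
    n_touch <- round(params$overlap_fraction * n_bg)
    for (k in seq_len(n_bg)) {
      i <- i + 1L
      margin <- radius[i] + 4
      allow_touch <- k <= n_touch && i > 1L
      best <- NULL
      best_score <- -Inf
      for (a in seq_len(300)) {
        p <- c(runif(1, margin, H - margin), runif(1, margin, W - margin))
        # keep unfused centroids out of myotubes (buffered), so ground-truth
        # membership matches centroid-in-component assignment downstream
        if (!is.null(tubes)) {
          ok <- TRUE
          for (jj in seq_len(nrow(tubes))) {
            v <- c(tubes$r2[jj] - tubes$r1[jj], tubes$c2[jj] - tubes$c1[jj])
            q1 <- c(tubes$r1[jj], tubes$c1[jj])
            len2 <- sum(v^2)
            tt <- min(1, max(0, sum((p - q1) * v) / len2))
            if (sqrt(sum((p - (q1 + tt * v))^2)) < tubes$width[jj] / 2 + 3) {
              ok <- FALSE
              break
            }
          }
          if (!ok) next
        }
        if (i == 1L) { best <- p; break }
        prev <- seq_len(i - 1L)
        dmin_req <- pmax(params$min_separation_px,
                         radius[i] + radius[prev] + 3)
        d <- sqrt((cen[prev, 1] - p[1])^2 + (cen[prev, 2] - p[2])^2)
        if (allow_touch) {
          # touching pair: closer than the full separation but far enough
          # that the two distance-transform peaks stay distinct
          req_lo <- 0.8 * (radius[i] + radius[prev])
          if (all(d >= req_lo) && any(d < dmin_req)) { best <- p; break }
          viol <- min(d - req_lo)
          # candidates below the touch floor would render overlapping,
          # unsplittable nuclei: penalize them heavily in the fallback
          score <- if (viol >= 0) -viol else 1000 * viol
        } else {
          if (all(d >= dmin_req)) { best <- p; break }
          score <- min(d - dmin_req)
        }
        if (score > best_score) { best_score <- score; best <- p }
      }
      cen[i, ] <- best
    }
  }

  # --- marker states: one uniform per nucleus partitions the four classes ---
  u <- runif(n)
  green <- u < params$p_green
  red <- u < params$p_double |
    (u >= params$p_green & u < params$p_green + params$p_red - params$p_double)

  # --- render ---
  dapi <- matrix(bg, H, W)
  img_g <- if ("green" %in% channels) matrix(bg, H, W)
  img_r <- if ("red" %in% channels) matrix(bg, H, W)
  img_m <- if ("myhc" %in% channels) matrix(bg, H, W)
  area_px <- integer(n)
  dapi_int <- runif(n, 150, 220)
  mark_int <- runif(n, 120, 180)
  if (n > 0) {
    for (k in seq_len(n)) {
      px <- disk_indices(H, W, cen[k, 1], cen[k, 2], radius[k])
      area_px[k] <- length(px)
      dapi[px] <- pmax(dapi[px], dapi_int[k])
      # marker disk stays >= 15 px after thresholding (radius 2.5 -> 21 px),
      # so a positive nucleus is never lost to the marker size filter
      mpx <- disk_indices(H, W, cen[k, 1], cen[k, 2], max(2.5, radius[k] - 1))
      if (!is.null(img_g) && green[k]) img_g[mpx] <- pmax(img_g[mpx], mark_int[k])
      if (!is.null(img_r) && red[k]) img_r[mpx] <- pmax(img_r[mpx], mark_int[k])
    }
  }
  if (!is.null(img_m) && !is.null(tubes)) {
    tube_int <- runif(nrow(tubes), 100, 150)
    for (j in seq_len(nrow(tubes))) {
      px <- capsule_indices(H, W, c(tubes$r1[j], tubes$c1[j]),
                            c(tubes$r2[j], tubes$c2[j]), tubes$width[j])
      img_m[px] <- pmax(img_m[px], tube_int[j])
    }
  }
  degrade <- function(img) {
    if (is.null(img)) return(NULL)
    if (params$blur_sigma_px > 0) img <- cpp_gaussian_blur(img, params$blur_sigma_px)
    if (params$noise_sd > 0) img <- img + rnorm(length(img), 0, params$noise_sd)
    clamp8(img)
  }
  chans <- list(dapi = degrade(dapi))
  if (!is.null(img_g)) chans$green <- degrade(img_g)
  if (!is.null(img_r)) chans$red <- degrade(img_r)
  if (!is.null(img_m)) chans$myhc <- degrade(img_m)

  # --- ground truth ---
  nuclei <- data.frame(id = seq_len(n),
                       centroid_row = cen[, 1], centroid_col = cen[, 2],
                       radius_px = radius, area_px = area_px,
                       green = green, red = red,
                       myotube_id = tube_of)[seq_len(n), , drop = FALSE]
  myotubes <- if (!is.null(tubes)) tubes else
    data.frame(id = integer(0), r1 = numeric(0), c1 = numeric(0),
               r2 = numeric(0), c2 = numeric(0), width = numeric(0),
               n_members = integer(0))
  n_green <- sum(green)
  n_red <- sum(red)
  n_double <- sum(green & red)
  n_in <- sum(!is.na(tube_of))
  true_counts <- data.frame(n_nuclei = n, n_green = n_green, n_red = n_red,
                            n_double = n_double,
                            n_myotubes = nrow(myotubes),
                            n_nuclei_in_myotubes = n_in)
  true_indices <- list(
    proliferation_pct = if (n_green > 0) proliferation_index(n_double, n_green)
                        else NA_real_,
    differentiation_pct = if (n_red > 0) differentiation_index(n_double, n_red)
                          else NA_real_,
    fusion_pct = if (n > 0) fusion_index(n_in, n) else NA_real_,
    myotube_count = nrow(myotubes))
  truth <- structure(list(nuclei = nuclei, myotubes = myotubes,
                          true_counts = true_counts,
                          true_indices = true_indices),
                     class = "ground_truth")
  stack <- channel_stack(chans, pixel_size_um = params$pixel_size_um,
                         provenance = provenance)
  list(stack = stack, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", x$true_counts$n_nuclei, "nuclei,",
      x$true_counts$n_myotubes, "myotubes\n")
  cat("  counts: green", x$true_counts$n_green,
      "red", x$true_counts$n_red,
      "double", x$true_counts$n_double,
      "fused", x$true_counts$n_nuclei_in_myotubes, "\n")
  invisible(x)
}

#' Generate a full synthetic culture study on disk
#'
#' Emulates the study layout -- a grid of coatings x days x triplicate wells
#' x five fields per well -- writing one per-channel TIFF set and one
#' ground-truth CSV per field plus a study-level manifest. Per-field seeds
#' are derived deterministically from the master seed and the field's
#' position in the design, so a study regenerates bit-identically.
#'
#' @param design list with `coatings` (character), `days` (integer),
#'   `wells` (default 3) and `fields` (default 5); or a data frame with
#'   columns `coating`, `day`, `well`, `field`.
#' @param out_dir output directory; refused if it already holds a manifest
#'   and `overwrite` is `FALSE`.
#' @param base_params a [scene_params] used for every field.
#' @param condition_params optional named list of parameter overrides, keyed
#'   by `"<coating>"` or `"<coating>:<day>"` (e.g.
#'   `list("matrigel:5" = list(p_double = 0.29))`).
#' @param channels channels to render.
#' @param seed master seed.
#' @param overwrite replace an existing study directory.
#' @return the manifest data frame, invisibly; on disk: `images/` (TIFFs
#'   named `<coating>_<day>_w<well>_f<field>_<channel>.tif`), `truth/`
#'   (per-field nucleus CSVs), `manifest.csv` (one row per field with
#'   condition labels, file prefix and true counts).
#' @export
generate_study <- function(design, out_dir,
                           base_params = scene_params(),
                           condition_params = NULL,
                           channels = c("dapi", "green", "red", "myhc"),
                           seed = 1, overwrite = FALSE) {
  grid <- if (is.data.frame(design)) design else
    expand.grid(field = seq_len(design$fields %||% 5),
                well = seq_len(design$wells %||% 3),
                day = design$days, coating = design$coatings,
                stringsAsFactors = FALSE)[, c("coating", "day", "well", "field")]
  manifest_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite)
    stop_param("output directory already contains a study (", manifest_path,
               "); pass overwrite = TRUE to replace it")
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- base_params
    for (key in c(g$coating, paste0(g$coating, ":", g$day))) {
      ov <- condition_params[[key]]
      if (!is.null(ov)) p <- do.call(scene_params, modifyList(unclass(p), ov))
    }
    p$seed <- derive_seed(seed, i)
    prefix <- sprintf("%s_%s_w%d_f%d", g$coating, g$day, g$well, g$field)
    fg <- generate_field(p, channels = channels,
                         provenance = list(coating = g$coating, day = g$day,
                                           well = g$well, field = g$field))
    write_stack(fg$stack, file.path(out_dir, "images"), prefix)
    write.csv(fg$truth$nuclei,
              file.path(out_dir, "truth", paste0(prefix, "_truth.csv")),
              row.names = FALSE)
    rows[[i]] <- cbind(data.frame(coating = g$coating, day = g$day,
                                  well = g$well, field = g$field,
                                  prefix = prefix, seed = p$seed),
                       fg$truth$true_counts)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest)
}
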