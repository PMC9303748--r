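# shared fixture builders (everything is generated in code; no binary files)

# small, fast field parameters for unit tests
tiny_params <- function(...) {
  defaults <- list(n_nuclei = 30, image_size = c(256, 256), seed = 42)
  do.call(scene_params, modifyList(defaults, list(...)))
}

# noise-free, blur-free, non-touching: the pipeline must be exact here
clean_params <- function(...) {
  tiny_params(noise_sd = 0, blur_sigma_px = 0, overlap_fraction = 0, ...)
}

# draw a disk into a matrix (independent of the package's renderer)
draw_disk <- function(img, r0, c0, radius, value = 200) {
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      if ((r - r0)^2 + (c - c0)^2 <= radius^2) img[r, c] <- value
    }
  }
  img
}

# brute-force Euclidean distance transform (oracle; O(n^2), tiny images only)
brute_edt <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  D <- matrix(0, H, W)
  for (i in which(mask)) {
    r <- (i - 1) %% H + 1
    c <- (i - 1) %/% H + 1
    D[r, c] <- sqrt(min((bg[, 1] - r)^2 + (bg[, 2] - c)^2))
  }
  D
}

# brute-force count of regional-maximum plateaus of a matrix within a
# Chebyshev radius, restricted to positive values (oracle for watershed seeds)
brute_peak_count <- function(D, radius = 5) {
  H <- nrow(D); W <- ncol(D)
  is_peak <- matrix(FALSE, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      if (D[r, c] <= 0) next
      rr <- max(1, r - radius):min(H, r + radius)
      cc <- max(1, c - radius):min(W, c + radius)
      if (D[r, c] >= max(D[rr, cc]) - 1e-9) is_peak[r, c] <- TRUE
    }
  }
  # merge adjacent peak pixels into plateaus via a simple flood fill
  lab <- matrix(0L, H, W)
  nlab <- 0L
  for (start in which(is_peak & lab == 0)) {
    nlab <- nlab + 1L
    queue <- start
    lab[start] <- nlab
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pr <- (p - 1) %% H + 1; pc <- (p - 1) %/% H + 1
      for (dr in -1:1) for (dc in -1:1) {
        nr <- pr + dr; nc <- pc + dc
        if (nr < 1 || nr > H || nc < 1 || nc > W) next
        q <- (nc - 1) * H + nr
        if (is_peak[q] && lab[q] == 0L) { lab[q] <- nlab; queue <- c(queue, q) }
      }
    }
  }
  nlab
}

# connected-component count through igraph (independent of the package's
# labeling kernel); 8-connectivity
igraph_cc_count <- function(mask) {
  H <- nrow(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(0L)
  id <- match(idx, idx)
  pos <- cbind((idx - 1) %% H + 1, (idx - 1) %/% H + 1)
  edges <- NULL
  key <- rep(NA_integer_, length(mask))
  key[idx] <- seq_along(idx)
  for (dr in -1:1) for (dc in 0:1) {
    if (dc == 0 && dr <= 0) next
    nr <- pos[, 1] + dr; nc <- pos[, 2] + dc
    ok <- nr >= 1 & nr <= H & nc >= 1 & nc <= ncol(mask)
    q <- (nc[ok] - 1) * H + nr[ok]
    hit <- !is.na(key[q])
    edges <- rbind(edges, cbind(which(ok)[hit], key[q][hit]))
  }
  if (is.null(edges)) return(length(idx))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  igraph::components(g)$no
}

# draw under a local seed without disturbing the session RNG
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# known cell-mean grids for regression tests
cells_additive <- function() {
  co <- c(matrigel = 40, fibrin = 10, fibrin_lec = 35, lec = 30)
  dy <- c(`1` = 0, `5` = 5, `7` = 8, `9` = 12)
  outer(co, dy, `+`)
}

cells_interacting <- function() {
  m <- cells_additive()
  m["fibrin", "9"] <- m["fibrin", "9"] + 25  # one cell breaks additivity
  m
}

# tidy analysis table with known cell means: 4 coatings x 4 days x n wells
make_table <- function(cell_means, n_wells = 3, noise_sd = 0, outcome = "y",
                       seed = 1) {
  coatings <- rownames(cell_means)
  days <- as.integer(colnames(cell_means))
  set.seed(seed)
  do.call(rbind, lapply(coatings, function(co) {
    do.call(rbind, lapply(days, function(dy) {
      data.frame(coating = co, day = dy, well = seq_len(n_wells),
                 outcome = outcome,
                 value = cell_means[co, as.character(dy)] +
                   rnorm(n_wells, 0, noise_sd))
    }))
  }))
}
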