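# Independent oracles and small fixture builders used across test files.

# winding-number point-in-polygon oracle, independent of the ray-crossing
# implementation: sums signed turn angles around the point
winding_inside <- function(px, py, ring) {
  ring <- as.matrix(ring)
  n <- nrow(ring)
  vapply(seq_along(px), function(i) {
    dx <- ring[, 1] - px[i]
    dy <- ring[, 2] - py[i]
    # on a vertex or edge counts as inside, matching the implementation
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      cross <- dx[k] * dy[k2] - dx[k2] * dy[k]
      dot <- dx[k] * dx[k2] + dy[k] * dy[k2]
      if (abs(cross) < 1e-9 && dot <= 1e-9) return(TRUE)
    }
    ang <- atan2(dy, dx)
    turns <- diff(c(ang, ang[1]))
    turns <- (turns + pi) %% (2 * pi) - pi
    abs(sum(turns)) > pi
  }, logical(1))
}

# naive double-loop mask mean, the brute-force MFI oracle
brute_mfi <- function(labels, channel) {
  ks <- sort(unique(labels[labels > 0]))
  out <- numeric(length(ks))
  for (i in seq_along(ks)) {
    tot <- 0; cnt <- 0
    for (r in seq_len(nrow(labels))) {
      for (c in seq_len(ncol(labels))) {
        if (labels[r, c] == ks[i]) {
          tot <- tot + channel[r, c]
          cnt <- cnt + 1
        }
      }
    }
    out[i] <- tot / cnt
  }
  setNames(out, ks)
}

# random star-shaped (hence simple) polygon around a center
random_polygon <- function(n_vertices, cx = 0, cy = 0, r_range = c(1, 3)) {
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, r_range[1], r_range[2])
  cbind(x = cx + r * cos(ang), y = cy + r * sin(ang))
}

# scaled-down retina config: full-scale zone geometry shrunk to `image_size`
# with counts scaled by area so placement density matches the default
small_retina_cfg <- function(seed, image_size = 800, zone_mix = NULL, ...) {
  counts <- c(PA = 12, PV = 12, Art = 16, Ven = 16, MC = 250, AFC = 90,
              Tip = 12, Stalk = 12)
  counts <- pmax(round(counts * (image_size / 800)^2), 1)
  args <- list(image_size = image_size, zone_counts = counts, seed = seed, ...)
  if (!is.null(zone_mix)) args$zone_mix <- zone_mix
  do.call(retina_sim_config, args)
}

# two rendered Gaussian spots on a blank image (for split/centroid tests)
two_spot_image <- function(size, c1, c2, sigma = 2, amp = 1) {
  xs <- matrix(rep(0:(size - 1), each = size), size, size)  # col index = x
  ys <- matrix(rep(0:(size - 1), times = size), size, size) # row index = y
  g <- function(cx, cy) amp * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sigma^2))
  g(c1[1], c1[2]) + g(c2[1], c2[2])
}

# run the image pipeline on a synthetic dataset and return truth/called pairs
pipeline_on_dataset <- function(ds) {
  res <- analyze_retina(ds$channels, retina_id = ds$retina_id)
  m <- match_nuclei(ds$nuclei, res$nuclei)
  anns <- remap_id_annotations(ds$annotations, m)
  zoned <- assign_zones(res$nuclei, anns)
  list(
    nuclei = zoned,
    matches = m,
    truth_phase = ds$nuclei$phase[match(m$truth_id, ds$nuclei$nucleus_id)],
    called_phase = zoned$phase[match(m$measured_id, zoned$nucleus_id)],
    truth_zone = ds$nuclei$zone[match(m$truth_id, ds$nuclei$nucleus_id)],
    called_zone = zoned$zone[match(m$measured_id, zoned$nucleus_id)]
  )
}
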