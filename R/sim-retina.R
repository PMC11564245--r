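# Synthetic retina generator: a stylized radial retina (artery/vein spokes,
# capillary annuli, a tip/stalk band at the angiogenic front) with nuclei
# placed inside their zones, per-zone cell-cycle phase mixtures, and
# phase-conditional lognormal reporter intensities rendered as Gaussian
# spots. Every stage of the analysis pipeline can be exercised against the
# generator's ground truth; no microscope data is required.
#
# Defaults encode the biology the pipeline targets: a whole-retina
# G1/G0:S:G2 mixture of 86:9:5 with an 18% reporter-unlabeled fraction,
# front-zone mixtures with G2-enriched tip (17.3%) and stalk (18.9%) cells
# versus front capillaries (8.4% G2, 15.5% S), S-depleted tip cells (1%),
# quieter arteries (~2% S), and EdU/Ki67 marker models
# (P(EdU+|S) = 0.89, P(EdU+|G2) = 0.05 from the 2-hour labeling window,
# P(Ki67+|G1/G0) = 0.24, cycling phases essentially Ki67+).

DEFAULT_ZONE_MIX <- list(
  PA    = c(G1G0 = 97.0, S = 2.0,  G2 = 1.0),
  PV    = c(G1G0 = 91.0, S = 6.0,  G2 = 3.0),
  Art   = c(G1G0 = 97.0, S = 2.0,  G2 = 1.0),
  Ven   = c(G1G0 = 91.0, S = 6.0,  G2 = 3.0),
  MC    = c(G1G0 = 90.0, S = 7.0,  G2 = 3.0),
  AFC   = c(G1G0 = 76.1, S = 15.5, G2 = 8.4),
  Tip   = c(G1G0 = 81.7, S = 1.0,  G2 = 17.3),
  Stalk = c(G1G0 = 72.4, S = 8.7,  G2 = 18.9)
)

DEFAULT_ZONE_COUNTS <- c(PA = 120, PV = 120, Art = 160, Ven = 160,
                         MC = 2400, AFC = 800, Tip = 40, Stalk = 40)

#' Configuration for the synthetic retina generator
#'
#' @param image_size square image side (px).
#' @param zone_counts named vector of nuclei per zone (names from
#'   [ZONE_LEVELS] minus `UNASSIGNED`).
#' @param zone_mix named list of per-zone phase mixtures, each a 3-vector
#'   over `G1G0`, `S`, `G2` (any positive scale; normalized internally). A
#'   single unnamed 3-vector applies to all zones.
#' @param unlabeled_frac probability that a nucleus is reporter-unlabeled
#'   (both channels at background), regardless of zone.
#' @param nucleus_radius nominal nucleus radius (px); rendered Gaussian
#'   sigma is half of it, and placed centers keep a minimum spacing of
#'   `2.5 * nucleus_radius`.
#' @param intensity list of lognormal intensity parameters (`meanlog` /
#'   `sdlog` for `venus_on`, `venus_off`, `cherry_on`, `cherry_off`, `erg`);
#'   the on/off log-mode separation of the defaults is far beyond 4 sigma,
#'   the regime in which phase calls are expected to be near-perfect.
#' @param noise_sd additive Gaussian pixel noise (images are clipped at 0).
#' @param p_edu,p_ki67 named per-phase Bernoulli marker probabilities.
#' @param seed integer seed; all generator randomness flows from it.
#' @return list of class `retina_sim_config`.
#' @export
retina_sim_config <- function(image_size = 2400,
                              zone_counts = DEFAULT_ZONE_COUNTS,
                              zone_mix = DEFAULT_ZONE_MIX,
                              unlabeled_frac = 0.18,
                              nucleus_radius = 4,
                              intensity = list(
                                venus_on = c(meanlog = log(0.55), sdlog = 0.15),
                                venus_off = c(meanlog = log(0.02), sdlog = 0.20),
                                cherry_on = c(meanlog = log(0.55), sdlog = 0.15),
                                cherry_off = c(meanlog = log(0.02), sdlog = 0.20),
                                erg = c(meanlog = log(0.50), sdlog = 0.15)
                              ),
                              noise_sd = 0.01,
                              p_edu = c(G1G0 = 0, S = 0.89, G2 = 0.05),
                              p_ki67 = c(G1G0 = 0.24, S = 0.99, G2 = 0.99),
                              seed = 1) {
  if (!is.list(zone_mix)) {
    zone_mix <- setNames(rep(list(zone_mix), length(zone_counts)),
                         names(zone_counts))
  }
  zone_mix <- lapply(zone_mix, function(m) {
    stopifnot(length(m) == 3, all(m >= 0), sum(m) > 0)
    setNames(m / sum(m), c("G1G0", "S", "G2"))
  })
  stopifnot(length(names(zone_counts)) == length(zone_counts),
            all(names(zone_counts) %in% setdiff(ZONE_LEVELS, "UNASSIGNED")),
            all(zone_counts >= 0), unlabeled_frac >= 0, unlabeled_frac < 1,
            noise_sd >= 0)
  structure(list(image_size = image_size, zone_counts = zone_counts,
                 zone_mix = zone_mix, unlabeled_frac = unlabeled_frac,
                 nucleus_radius = nucleus_radius, intensity = intensity,
                 noise_sd = noise_sd, p_edu = p_edu, p_ki67 = p_ki67,
                 seed = as.integer(seed)),
            class = "retina_sim_config")
}

# polygon ring of an annular sector (angles in degrees), traversed outer arc
# forward then inner arc backward; simple for sectors < 360 degrees
sector_ring <- function(cx, cy, r_in, r_out, a1, a2, step = 4) {
  ang <- seq(a1, a2, by = step)
  if (ang[length(ang)] != a2) ang <- c(ang, a2)
  rad <- ang * pi / 180
  outer <- cbind(cx + r_out * cos(rad), cy + r_out * sin(rad))
  inner <- cbind(cx + r_in * cos(rev(rad)), cy + r_in * sin(rev(rad)))
  ring <- rbind(outer, inner)
  colnames(ring) <- c("x", "y")
  ring
}

# stylized radial zone layout: spoke sectors for PA/PV/Art/Ven, the rest of
# the inner annulus as MC, an AFC annulus, and tip/stalk placement bands
# (radius ranges, no polygons). All radii relative to R = 0.48 * image_size.
zone_layout <- function(image_size) {
  c0 <- (image_size - 1) / 2
  R <- 0.48 * image_size
  spokes <- list(PA = c(-8, 8), Art = c(28, 44), PV = c(172, 188),
                 Ven = c(208, 224))
  inner <- c(0.06, 0.40) * R
  zones <- lapply(spokes, function(a) {
    list(sectors = list(c(r_in = inner[1], r_out = inner[2], a1 = a[1], a2 = a[2])))
  })
  # MC: complement of the spokes within the inner annulus, 3-degree gaps
  gap <- 3
  sp <- do.call(rbind, spokes)
  sp <- sp[order(sp[, 1]), ]
  mc_arcs <- list()
  for (i in seq_len(nrow(sp))) {
    a_from <- sp[i, 2] + gap
    a_to <- if (i < nrow(sp)) sp[i + 1, 1] - gap else sp[1, 1] - gap + 360
    mc_arcs[[i]] <- unname(c(a_from, a_to))
  }
  zones$MC <- list(sectors = lapply(mc_arcs, function(a) {
    c(r_in = inner[1], r_out = inner[2], a1 = a[1], a2 = a[2])
  }))
  zones$AFC <- list(sectors = list(
    c(r_in = 0.43 * R, r_out = 0.52 * R, a1 = 0, a2 = 178),
    c(r_in = 0.43 * R, r_out = 0.52 * R, a1 = 182, a2 = 358)
  ))
  polygons <- lapply(zones, function(z) {
    lapply(z$sectors, function(s) {
      sector_ring(c0, c0, s["r_in"], s["r_out"], s["a1"], s["a2"])
    })
  })
  list(center = c0, R = R, sectors = zones, polygons = polygons,
       bands = list(Stalk = c(0.53, 0.555) * R, Tip = c(0.565, 0.59) * R))
}

# uniform sample in an annular sector, shrunk by `margin` so points stay
# strictly interior to the drawn polygon
sample_sector <- function(n, c0, s, margin) {
  r_in <- s["r_in"] + margin; r_out <- s["r_out"] - margin
  r <- sqrt(runif(n, r_in^2, r_out^2))
  # angular margin shrinks with radius; clamp at the sector midline so
  # narrow sectors stay sampleable near the center
  a_margin <- pmin(margin / r * 180 / pi, (s["a2"] - s["a1"]) / 2 - 1e-6)
  a <- runif(n, s["a1"] + a_margin, s["a2"] - a_margin) * pi / 180
  cbind(x = c0 + r * cos(a), y = c0 + r * sin(a))
}

# sequential placement with a minimum center spacing, rejection-sampled
place_nuclei <- function(cfg, layout) {
  spacing <- 2.5 * cfg$nucleus_radius
  margin <- cfg$nucleus_radius + 1
  placed <- matrix(numeric(0), 0, 2)
  zone_of <- character()
  for (zone in names(cfg$zone_counts)) {
    count <- cfg$zone_counts[[zone]]
    if (count == 0) next
    sectors <- if (zone %in% names(layout$sectors)) {
      lapply(layout$sectors[[zone]]$sectors, identity)
    } else {
      band <- layout$bands[[zone]]
      list(c(r_in = band[1], r_out = band[2], a1 = 0, a2 = 360))
    }
    band_margin <- if (zone %in% c("Tip", "Stalk")) 0 else margin
    areas <- vapply(sectors, function(s) {
      (s["r_out"]^2 - s["r_in"]^2) * (s["a2"] - s["a1"])
    }, numeric(1))
    got <- 0L
    attempts <- 0L
    max_attempts <- 400L * count
    while (got < count) {
      if (attempts >= max_attempts) {
        stop(sprintf("zone %s too small for %d nuclei at spacing %.1f px",
                     zone, count, spacing), call. = FALSE)
      }
      attempts <- attempts + 1L
      s <- sectors[[sample.int(length(sectors), 1, prob = areas)]]
      p <- sample_sector(1L, layout$center, s, band_margin)
      if (nrow(placed)) {
        d2 <- (placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2
        if (min(d2) < spacing^2) next
      }
      placed <- rbind(placed, p)
      zone_of <- c(zone_of, zone)
      got <- got + 1L
    }
  }
  list(xy = placed, zone = zone_of)
}

render_spots <- function(size, xy, amplitude, sigma, noise_sd) {
  img <- matrix(0, size, size)
  half <- ceiling(3 * sigma)
  off <- seq(-half, half)
  prof <- exp(-(off^2) / (2 * sigma^2))
  for (i in seq_len(nrow(xy))) {
    cx <- xy[i, 1]; cy <- xy[i, 2]
    col0 <- round(cx) + 1L; row0 <- round(cy) + 1L
    cols <- col0 + off; rows <- row0 + off
    ok_c <- cols >= 1 & cols <= size; ok_r <- rows >= 1 & rows <= size
    # sub-pixel-accurate Gaussian evaluated at the kept pixel grid
    gx <- exp(-(((cols[ok_c] - 1) - cx)^2) / (2 * sigma^2))
    gy <- exp(-(((rows[ok_r] - 1) - cy)^2) / (2 * sigma^2))
    patch <- amplitude[i] * outer(gy, gx)
    img[rows[ok_r], cols[ok_c]] <- img[rows[ok_r], cols[ok_c]] + patch
  }
  if (noise_sd > 0) {
    img <- img + matrix(rnorm(size * size, 0, noise_sd), size, size)
    img[img < 0] <- 0
  }
  img
}

#' Generate a synthetic retina with ground truth
#'
#' Places `zone_counts` nuclei strictly inside their zone geometry (minimum
#' center spacing `2.5 * nucleus_radius`, rejection sampling), draws each
#' nucleus's true phase from its zone's mixture (after an independent
#' `unlabeled_frac` coin flip), draws marker labels and phase-conditional
#' reporter amplitudes, and optionally renders ERG/venus/cherry channel
#' images as Gaussian spots with additive noise. The ERG amplitude is drawn
#' for every nucleus regardless of phase. Fully reproducible from
#' `cfg$seed`; the global RNG state is left untouched.
#'
#' @param cfg a [retina_sim_config()].
#' @param retina_id identifier stamped into the truth table.
#' @param render render channel images? Set `FALSE` for truth-table-only
#'   simulations (fast path for statistical tests).
#' @return a [retina_dataset()]: `channels` (`erg`, `venus`, `cherry`;
#'   empty list when `render = FALSE`), `nuclei` (truth table: true phase,
#'   zone, markers, centroid, and true reporter amplitudes in the MFI
#'   columns) and `annotations` (zone polygons plus Tip/Stalk ID lists).
#' @export
generate_retina <- function(cfg, retina_id = "sim_retina", render = TRUE) {
  stopifnot(inherits(cfg, "retina_sim_config"))
  withr::with_seed(cfg$seed, {
    layout <- zone_layout(cfg$image_size)
    pl <- place_nuclei(cfg, layout)
    n <- nrow(pl$xy)

    unlab <- runif(n) < cfg$unlabeled_frac
    phase <- character(n)
    for (zone in unique(pl$zone)) {
      idx <- which(pl$zone == zone)
      mix <- cfg$zone_mix[[zone]] %||% cfg$zone_mix[[1]]
      phase[idx] <- sample(names(mix), length(idx), replace = TRUE, prob = mix)
    }
    phase[unlab] <- "UNLABELED"

    draw <- function(par, n) rlnorm(n, par["meanlog"], par["sdlog"])
    venus_on <- phase %in% c("G1G0", "G2")
    cherry_on <- phase %in% c("S", "G2")
    amp_venus <- ifelse(venus_on, draw(cfg$intensity$venus_on, n),
                        draw(cfg$intensity$venus_off, n))
    amp_cherry <- ifelse(cherry_on, draw(cfg$intensity$cherry_on, n),
                         draw(cfg$intensity$cherry_off, n))
    amp_erg <- draw(cfg$intensity$erg, n)

    p_of <- function(p, phase) ifelse(phase %in% names(p), p[phase], 0)
    edu <- rbinom(n, 1, p_of(cfg$p_edu, phase)) == 1
    ki67 <- rbinom(n, 1, p_of(cfg$p_ki67, phase)) == 1

    truth <- nucleus_table(
      nucleus_id = seq_len(n),
      x = pl$xy[, 1], y = pl$xy[, 2],
      area_px = round(pi * cfg$nucleus_radius^2),
      mfi_venus = amp_venus, mfi_cherry = amp_cherry,
      phase = phase, zone = pl$zone, retina_id = retina_id,
      edu = edu, ki67 = ki67
    )

    annotations <- c(
      lapply(names(layout$polygons), function(z) {
        zone_annotation(z, polygons = layout$polygons[[z]])
      }),
      lapply(c("Tip", "Stalk"), function(z) {
        zone_annotation(z, nucleus_ids = truth$nucleus_id[truth$zone == z])
      })
    )

    channels <- list()
    if (render) {
      sigma <- cfg$nucleus_radius / 2
      channels <- list(
        erg = render_spots(cfg$image_size, pl$xy, amp_erg, sigma, cfg$noise_sd),
        venus = render_spots(cfg$image_size, pl$xy, amp_venus, sigma, cfg$noise_sd),
        cherry = render_spots(cfg$image_size, pl$xy, amp_cherry, sigma, cfg$noise_sd)
      )
    }

    retina_dataset(retina_id, channels = channels, nuclei = truth,
                   annotations = annotations,
                   meta = list(config = unclass(cfg)))
  })
}

#' Match segmented nuclei to ground-truth nuclei by centroid
#'
#' Nearest-centroid matching within `max_dist` pixels, greedy from the
#' closest pair. Used to transfer truth labels (phase, zone, Tip/Stalk ID
#' lists) onto a segmentation of a synthetic image.
#'
#' @param truth,measured nucleus tables.
#' @param max_dist maximum centroid distance (px) for a valid match.
#' @return data.frame with `truth_id`, `measured_id`, `dist`.
#' @export
match_nuclei <- function(truth, measured, max_dist = 3) {
  if (nrow(truth) == 0 || nrow(measured) == 0) {
    return(data.frame(truth_id = integer(), measured_id = integer(),
                      dist = numeric()))
  }
  pairs <- list()
  taken <- logical(nrow(truth))
  for (j in seq_len(nrow(measured))) {
    d2 <- (truth$x - measured$x[j])^2 + (truth$y - measured$y[j])^2
    d2[taken] <- Inf
    i <- which.min(d2)
    if (d2[i] <= max_dist^2) {
      taken[i] <- TRUE
      pairs[[length(pairs) + 1L]] <-
        data.frame(truth_id = truth$nucleus_id[i],
                   measured_id = measured$nucleus_id[j],
                   dist = sqrt(d2[i]))
    }
  }
  if (!length(pairs)) {
    return(data.frame(truth_id = integer(), measured_id = integer(),
                      dist = numeric()))
  }
  do.call(rbind, pairs)
}

#' Re-express Tip/Stalk ID-list annotations in a segmentation's ID space
#'
#' Tip and stalk annotations name nuclei by ID; after segmenting a synthetic
#' image the IDs refer to the truth table, not the measured one. This maps
#' them across a [match_nuclei()] result (unmatched IDs are dropped).
#' Polygon annotations pass through unchanged.
#'
#' @param annotations list of [zone_annotation()] objects (truth ID space).
#' @param matches data.frame from [match_nuclei()].
#' @return list of [zone_annotation()] objects in measured ID space.
#' @export
remap_id_annotations <- function(annotations, matches) {
  lapply(annotations, function(a) {
    if (!length(a$nucleus_ids)) return(a)
    mapped <- matches$measured_id[match(a$nucleus_ids, matches$truth_id)]
    zone_annotation(a$zone_name, nucleus_ids = mapped[!is.na(mapped)])
  })
}
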