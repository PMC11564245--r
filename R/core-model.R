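# Core data model: nucleus tables, zone annotations, retina datasets.
#
# A "nucleus table" is a plain data.frame with one row per segmented ERG+
# nucleus and (at least) the columns in NUCLEUS_COLUMNS. Coordinates are
# 0-based pixel indices: x is the column (rightward), y the row (downward),
# the same frame used for zone polygons, so mask and annotation never differ
# by one pixel.

#' Recognized cell-cycle phase tokens
#'
#' `G1G0`, `S` and `G2` are the three callable reporter states (mVenus+ only,
#' mCherry+ only, and double-positive; the reporter cannot separate G2 from M,
#' and `G2M` is accepted as an input alias for `G2`). `UNLABELED` marks nuclei
#' negative in both reporter channels, which are excluded from phase
#' quantification; `UNCALLED` marks nuclei not yet classified.
#' @export
PHASE_LEVELS <- c("G1G0", "S", "G2", "UNLABELED", "UNCALLED")

#' Recognized vascular zone tokens
#'
#' Primary arteries/veins (`PA`/`PV`), arterioles/venules (`Art`/`Ven`),
#' mature capillaries (`MC`), angiogenic front capillaries (`AFC`), sprouting
#' tip cells (`Tip`) and the stalk cells behind them (`Stalk`).
#' `UNASSIGNED` marks nuclei falling in no annotated zone.
#' @export
ZONE_LEVELS <- c("PA", "PV", "Art", "Ven", "MC", "AFC", "Tip", "Stalk",
                 "UNASSIGNED")

# zones carried by polygons, in assignment precedence order
POLYGON_ZONES <- c("PA", "PV", "Art", "Ven", "AFC", "MC")
ID_ZONES <- c("Tip", "Stalk")

NUCLEUS_COLUMNS <- c("retina_id", "nucleus_id", "x", "y", "area_px",
                     "mfi_venus", "mfi_cherry", "phase", "zone")
NUCLEUS_REQUIRED <- c("nucleus_id", "x", "y", "area_px",
                      "mfi_venus", "mfi_cherry")

normalize_phase <- function(phase) {
  phase <- toupper(as.character(phase))
  phase[phase == "G2M"] <- "G2"
  bad <- setdiff(unique(phase[!is.na(phase)]), PHASE_LEVELS)
  if (length(bad)) {
    stop(sprintf("unknown phase token(s): %s (allowed: %s)",
                 paste(bad, collapse = ", "),
                 paste(PHASE_LEVELS, collapse = ", ")), call. = FALSE)
  }
  phase[is.na(phase)] <- "UNCALLED"
  phase
}

normalize_zone <- function(zone) {
  zone <- as.character(zone)
  # zone tokens are mixed-case by convention; match case-insensitively
  idx <- match(toupper(zone), toupper(ZONE_LEVELS))
  bad <- unique(zone[is.na(idx) & !is.na(zone)])
  if (length(bad)) {
    stop(sprintf("unknown zone name(s): %s (allowed: %s)",
                 paste(bad, collapse = ", "),
                 paste(ZONE_LEVELS, collapse = ", ")), call. = FALSE)
  }
  out <- ZONE_LEVELS[idx]
  out[is.na(out)] <- "UNASSIGNED"
  out
}

#' Build a nucleus table
#'
#' Assembles and validates the canonical per-nucleus data.frame used by every
#' pipeline stage.
#'
#' @param nucleus_id positive integer IDs, unique within a retina.
#' @param x,y nucleus centroid in 0-based pixel coordinates (x = column,
#'   y = row).
#' @param area_px nucleus area in pixels.
#' @param mfi_venus,mfi_cherry mean fluorescence intensity of the mVenus and
#'   mCherry reporter channels over the nucleus mask (arbitrary units, >= 0).
#' @param phase cell-cycle phase token (see [PHASE_LEVELS]); default
#'   `"UNCALLED"`.
#' @param zone vascular zone token (see [ZONE_LEVELS]); default
#'   `"UNASSIGNED"`.
#' @param retina_id retina identifier (recycled).
#' @param edu,ki67 optional logical marker labels (EdU incorporation, Ki67
#'   positivity).
#' @return data.frame with one row per nucleus.
#' @export
nucleus_table <- function(nucleus_id, x, y, area_px, mfi_venus, mfi_cherry,
                          phase = "UNCALLED", zone = "UNASSIGNED",
                          retina_id = "retina", edu = NULL, ki67 = NULL) {
  n <- length(nucleus_id)
  df <- data.frame(
    retina_id = rep_len(as.character(retina_id), n),
    nucleus_id = as.integer(nucleus_id),
    x = as.numeric(x), y = as.numeric(y),
    area_px = as.numeric(area_px),
    mfi_venus = as.numeric(mfi_venus),
    mfi_cherry = as.numeric(mfi_cherry),
    phase = rep_len(normalize_phase(phase), n),
    zone = rep_len(normalize_zone(zone), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(edu)) df$edu <- rep_len(as.logical(edu), n)
  if (!is.null(ki67)) df$ki67 <- rep_len(as.logical(ki67), n)
  assert_nucleus_table(df)
  df
}

assert_nucleus_table <- function(df, what = "nucleus table") {
  abort_missing_cols(df, NUCLEUS_REQUIRED, what)
  dup <- unique(df$nucleus_id[duplicated(df$nucleus_id)])
  if (length(dup)) {
    stop(sprintf("%s: duplicate nucleus_id: %s", what,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(df$mfi_venus)) || any(!is.finite(df$mfi_cherry)) ||
      any(df$mfi_venus < 0) || any(df$mfi_cherry < 0)) {
    stop(sprintf("%s: MFIs must be finite and >= 0", what), call. = FALSE)
  }
  invisible(df)
}

#' Read / write a nucleus table as CSV
#'
#' The canonical on-disk format is plain CSV with header
#' `retina_id,nucleus_id,x,y,area_px,mfi_venus,mfi_cherry,phase,zone,edu,ki67`
#' (marker columns optional). Numeric fields round-trip exactly at full
#' double precision. Unknown phase or zone tokens and duplicated IDs are
#' rejected.
#'
#' @param path CSV file path.
#' @return `read_nucleus_table()`: validated nucleus data.frame.
#' @export
read_nucleus_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  abort_missing_cols(df, NUCLEUS_REQUIRED, basename(path))
  if (is.null(df$retina_id)) df$retina_id <- "retina"
  df$phase <- normalize_phase(if (is.null(df$phase)) NA else df$phase)
  df$zone <- normalize_zone(if (is.null(df$zone)) {
    rep(NA_character_, nrow(df))
  } else df$zone)
  for (m in c("edu", "ki67")) if (!is.null(df[[m]])) df[[m]] <- as.logical(df[[m]])
  keep <- c(NUCLEUS_COLUMNS, intersect(c("edu", "ki67"), names(df)))
  df <- df[, keep]
  assert_nucleus_table(df, basename(path))
  df
}

#' @rdname read_nucleus_table
#' @param df nucleus data.frame.
#' @return `write_nucleus_table()`: `path`, invisibly.
#' @export
write_nucleus_table <- function(df, path) {
  assert_nucleus_table(df)
  keep <- c(NUCLEUS_COLUMNS, intersect(c("edu", "ki67"), names(df)))
  write.csv(df[, keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a zone annotation
#'
#' A zone annotation names one vascular zone and carries either a set of
#' polygon rings (hand-drawn region outlines, in image pixel coordinates) or,
#' for the `Tip` and `Stalk` zones, an explicit list of nucleus IDs — tip and
#' stalk cells are identified per nucleus, not per region.
#'
#' @param zone_name one of [ZONE_LEVELS] except `UNASSIGNED`.
#' @param polygons list of numeric matrices with columns `x`, `y`; each ring
#'   must have >= 3 distinct vertices and be simple. A closing vertex equal to
#'   the first is accepted and dropped.
#' @param nucleus_ids integer nucleus IDs (only for `Tip`/`Stalk`).
#' @return object of class `zone_annotation`.
#' @export
zone_annotation <- function(zone_name, polygons = list(), nucleus_ids = integer()) {
  zone_name <- normalize_zone(zone_name)
  if (zone_name == "UNASSIGNED") {
    stop("UNASSIGNED is not an annotatable zone", call. = FALSE)
  }
  if (zone_name %in% ID_ZONES && length(polygons)) {
    stop(sprintf("%s annotations carry nucleus IDs, not polygons", zone_name),
         call. = FALSE)
  }
  polygons <- lapply(polygons, normalize_ring)
  structure(list(zone_name = zone_name, polygons = polygons,
                 nucleus_ids = as.integer(nucleus_ids)),
            class = "zone_annotation")
}

# drop duplicated closing vertex, validate >= 3 vertices and simplicity
normalize_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2) stop("polygon ring must be an n x 2 matrix", call. = FALSE)
  storage.mode(ring) <- "double"
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  if (nrow(ring) < 3) stop("polygon ring needs >= 3 distinct vertices", call. = FALSE)
  if (!all(is.finite(ring))) stop("polygon ring has non-finite vertices", call. = FALSE)
  if (!ring_is_simple(ring)) stop("polygon ring is self-intersecting", call. = FALSE)
  colnames(ring) <- c("x", "y")
  ring
}

# simplicity check: no two non-adjacent edges intersect
ring_is_simple <- function(ring) {
  n <- nrow(ring)
  a <- ring
  b <- ring[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    # edge n is adjacent to edge 1
    if (i == 1L) js <- js[js != n]
    for (j in js) {
      if (segments_intersect(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(p, q, r) {
    min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
      min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

#' Read / write zone annotations as GeoJSON
#'
#' Zone annotations are stored as a GeoJSON FeatureCollection. Polygon zones
#' are `Polygon`/`MultiPolygon` features with a `zone_name` property;
#' `Tip`/`Stalk` features carry a `nucleus_ids` property and a null geometry.
#' Coordinates are image pixel coordinates (x = column, y = row, 0-based),
#' not geographic.
#'
#' @param path GeoJSON file path.
#' @return `read_zone_annotations()`: list of [zone_annotation()] objects.
#' @export
read_zone_annotations <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- gj$features %||% list(gj)
  lapply(feats, function(f) {
    props <- f$properties %||% list()
    zname <- props$zone_name %||% stop("feature lacks a zone_name property",
                                       call. = FALSE)
    ids <- as.integer(unlist(props$nucleus_ids))
    geom <- f$geometry
    polys <- list()
    if (!is.null(geom) && !is.null(geom$type)) {
      coords <- geom$coordinates
      rings <- switch(geom$type,
        Polygon = coords[1],              # outer ring only; holes unsupported
        MultiPolygon = lapply(coords, `[[`, 1),
        stop(sprintf("unsupported geometry type '%s'", geom$type), call. = FALSE))
      polys <- lapply(rings, function(r) {
        do.call(rbind, lapply(r, function(v) as.numeric(unlist(v))))
      })
    }
    zone_annotation(zname, polygons = polys, nucleus_ids = ids)
  })
}

#' @rdname read_zone_annotations
#' @param annotations list of [zone_annotation()] objects.
#' @return `write_zone_annotations()`: `path`, invisibly.
#' @export
write_zone_annotations <- function(annotations, path) {
  feats <- lapply(annotations, function(a) {
    geom <- NULL
    if (length(a$polygons)) {
      rings <- lapply(a$polygons, function(p) {
        p <- rbind(p, p[1, ])  # GeoJSON rings are explicitly closed
        list(lapply(seq_len(nrow(p)), function(i) as.list(unname(p[i, ]))))
      })
      geom <- if (length(rings) == 1L) {
        list(type = "Polygon", coordinates = rings[[1]])
      } else {
        list(type = "MultiPolygon", coordinates = rings)
      }
    }
    list(type = "Feature",
         properties = list(zone_name = a$zone_name,
                           nucleus_ids = as.list(a$nucleus_ids)),
         geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Bundle images, nuclei and annotations for one retina
#'
#' @param retina_id retina identifier.
#' @param channels named list of 2D numeric matrices (same shape), typically
#'   `erg`, `venus`, `cherry`.
#' @param nuclei nucleus table (see [nucleus_table()]).
#' @param annotations list of [zone_annotation()] objects.
#' @param meta free-form metadata list (genotype tag, pixel size, ...).
#' @return object of class `retina_dataset`.
#' @export
retina_dataset <- function(retina_id, channels = list(), nuclei = NULL,
                           annotations = list(), meta = list()) {
  structure(list(retina_id = as.character(retina_id), channels = channels,
                 nuclei = nuclei, annotations = annotations, meta = meta),
            class = "retina_dataset")
}

#' @export
print.retina_dataset <- function(x, ...) {
  cat(sprintf("<retina_dataset '%s': %d channel(s), %d nuclei, %d annotation(s)>\n",
              x$retina_id, length(x$channels),
              if (is.null(x$nuclei)) 0L else nrow(x$nuclei),
              length(x$annotations)))
  invisible(x)
}

#' Validate a retina dataset
#'
#' Report-only check of every structural invariant: channel shapes agree,
#' nucleus IDs are unique, MFIs finite and non-negative, phase/zone tokens
#' valid, polygon rings well-formed, and every Tip/Stalk nucleus ID references
#' an existing nucleus. Never raises on malformed-but-parsable input.
#'
#' @param ds a [retina_dataset()].
#' @param min_area minimum accepted nucleus area (px).
#' @return character vector of violations; `character(0)` means valid.
#' @export
validate_dataset <- function(ds, min_area = 1) {
  v <- character()
  shapes <- lapply(ds$channels, dim)
  if (length(shapes) > 1 && !all(vapply(shapes, identical, TRUE, shapes[[1]]))) {
    v <- c(v, "channel images do not share one shape")
  }
  nuc <- ds$nuclei
  if (!is.null(nuc)) {
    miss <- setdiff(NUCLEUS_REQUIRED, names(nuc))
    if (length(miss)) {
      v <- c(v, sprintf("nucleus table missing column(s): %s",
                        paste(miss, collapse = ", ")))
    } else {
      dup <- unique(nuc$nucleus_id[duplicated(nuc$nucleus_id)])
      if (length(dup)) v <- c(v, sprintf("duplicate nucleus_id: %s",
                                         paste(dup, collapse = ", ")))
      if (any(nuc$area_px < min_area)) {
        v <- c(v, sprintf("%d nucleus/nuclei under min_area = %g",
                          sum(nuc$area_px < min_area), min_area))
      }
      bad_mfi <- !is.finite(nuc$mfi_venus) | !is.finite(nuc$mfi_cherry) |
        nuc$mfi_venus < 0 | nuc$mfi_cherry < 0
      if (any(bad_mfi)) v <- c(v, sprintf("%d nucleus/nuclei with invalid MFI",
                                          sum(bad_mfi)))
      if (!is.null(nuc$phase) && !all(nuc$phase %in% PHASE_LEVELS)) {
        v <- c(v, "invalid phase token(s) in nucleus table")
      }
      if (!is.null(nuc$zone) && !all(nuc$zone %in% ZONE_LEVELS)) {
        v <- c(v, "invalid zone token(s) in nucleus table")
      }
    }
  }
  for (a in ds$annotations) {
    if (!inherits(a, "zone_annotation")) {
      v <- c(v, "annotation is not a zone_annotation object")
      next
    }
    if (a$zone_name %in% ID_ZONES && !is.null(nuc)) {
      orphan <- setdiff(a$nucleus_ids, nuc$nucleus_id)
      if (length(orphan)) {
        v <- c(v, sprintf("%s annotation references absent nucleus ID(s): %s",
                          a$zone_name, paste(orphan, collapse = ", ")))
      }
    }
    for (p in a$polygons) {
      if (nrow(p) < 3) v <- c(v, sprintf("%s polygon with < 3 vertices", a$zone_name))
    }
  }
  tips <- unlist(lapply(ds$annotations,
                        function(a) if (identical(a$zone_name, "Tip")) a$nucleus_ids))
  stalks <- unlist(lapply(ds$annotations,
                          function(a) if (identical(a$zone_name, "Stalk")) a$nucleus_ids))
  both <- intersect(tips, stalks)
  if (length(both)) {
    v <- c(v, sprintf("nucleus ID(s) in both Tip and Stalk lists: %s",
                      paste(both, collapse = ", ")))
  }
  v
}

#' Read a multichannel TIFF as named channel matrices
#'
#' @param path TIFF file (one channel per page, or a single page).
#' @param channel_names names for the pages, in page order, e.g.
#'   `c("erg", "venus", "cherry")`.
#' @return named list of numeric matrices (rows = y, columns = x).
#' @export
read_channels_tiff <- function(path, channel_names = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse stray RGB pages
    p
  })
  if (!is.null(channel_names)) {
    if (length(channel_names) != length(pages)) {
      stop(sprintf("TIFF has %d page(s) but %d channel name(s) given",
                   length(pages), length(channel_names)), call. = FALSE)
    }
    names(pages) <- channel_names
  }
  pages
}

#' Write named channel matrices as a multi-page TIFF
#'
#' Intensities are rescaled to the unit range page-wise if any value exceeds 1
#' (TIFF stores [0, 1] floats here); the synthetic generator keeps amplitudes
#' within [0, 1] so its images round-trip unscaled.
#'
#' @param channels named list of matrices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_channels_tiff <- function(channels, path) {
  pages <- lapply(channels, function(m) {
    m[m < 0] <- 0
    if (max(m) > 1) m <- m / max(m)
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
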