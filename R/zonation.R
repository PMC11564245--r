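# Vascular zone assignment: every nucleus centroid is tested against the
# hand-drawn zone polygons; tip and stalk cells are taken from explicit
# nucleus-ID lists. Zone classification is mutually exclusive per nucleus.

#' Point-in-polygon test (even-odd rule)
#'
#' Ray-crossing (even-odd) membership test. Points lying exactly on an edge
#' or vertex count as inside, so a nucleus sitting on a drawn boundary is
#' kept rather than silently dropped.
#'
#' @param px,py point coordinates (vectors of equal length).
#' @param ring n x 2 matrix of polygon vertices (open ring, >= 3 vertices,
#'   simple).
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, ring) {
  ring <- normalize_ring(ring)
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- logical(length(px))
  onedge <- logical(length(px))
  for (i in seq_len(n)) {
    x1 <- xs[i]; y1 <- ys[i]; x2 <- xe[i]; y2 <- ye[i]
    # boundary: collinear and within the segment's bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    onedge <- onedge | (abs(cross) < 1e-12 * max(1, abs(x2 - x1), abs(y2 - y1)) &
                          px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
                          py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12)
    # half-open rule on y avoids double-counting vertices
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    inside <- xor(inside, crosses & !is.na(crosses))
  }
  inside | onedge
}

in_any_polygon <- function(px, py, polygons) {
  hit <- logical(length(px))
  for (ring in polygons) hit <- hit | point_in_polygon(px, py, ring)
  hit
}

#' Assign vascular zones to nuclei
#'
#' Assignment precedence per nucleus: (1) listed as a tip cell; (2) listed as
#' a stalk cell; (3) centroid inside a polygon of, in order, PA, PV, Art,
#' Ven, AFC, MC; (4) otherwise `UNASSIGNED`. Multiple polygons of one zone
#' act as their union (data from all polygons of a zone are merged per
#' retina). Membership is tested on the centroid. Overlaps between polygons
#' of different zones are resolved by the precedence order and reported in
#' the `zonation_warnings` attribute; a nucleus listed as both tip and stalk
#' is an error, since zone classification is mutually exclusive.
#'
#' @param records nucleus table.
#' @param annotations list of [zone_annotation()] objects.
#' @return the nucleus table with `zone` set, with attribute
#'   `zonation_warnings` (character vector, possibly empty).
#' @export
assign_zones <- function(records, annotations) {
  ids_of <- function(zone) {
    unlist(lapply(annotations,
                  function(a) if (identical(a$zone_name, zone)) a$nucleus_ids))
  }
  tip_ids <- ids_of("Tip"); stalk_ids <- ids_of("Stalk")
  both <- intersect(tip_ids, stalk_ids)
  if (length(both)) {
    stop(sprintf("nucleus ID(s) listed as both Tip and Stalk: %s",
                 paste(both, collapse = ", ")), call. = FALSE)
  }
  polys <- lapply(POLYGON_ZONES, function(z) {
    do.call(c, lapply(annotations,
                      function(a) if (identical(a$zone_name, z)) a$polygons))
  })
  names(polys) <- POLYGON_ZONES

  hits <- vapply(POLYGON_ZONES, function(z) {
    if (length(polys[[z]])) in_any_polygon(records$x, records$y, polys[[z]])
    else logical(nrow(records))
  }, logical(nrow(records)))
  if (nrow(records) == 1L) hits <- matrix(hits, nrow = 1,
                                          dimnames = list(NULL, POLYGON_ZONES))

  zone <- rep("UNASSIGNED", nrow(records))
  for (z in rev(POLYGON_ZONES)) zone[hits[, z]] <- z  # first in order wins
  zone[records$nucleus_id %in% stalk_ids] <- "Stalk"
  zone[records$nucleus_id %in% tip_ids] <- "Tip"

  warnings <- character()
  multi <- rowSums(hits) > 1
  if (any(multi)) {
    warnings <- c(warnings, sprintf(
      "%d nucleus/nuclei fall in polygons of more than one zone; resolved by precedence %s",
      sum(multi), paste(POLYGON_ZONES, collapse = " > ")))
  }
  records$zone <- zone
  attr(records, "zonation_warnings") <- warnings
  records
}

#' Per-zone counts of labeled nuclei
#'
#' Counts reporter-labeled (non-`UNLABELED`, non-`UNCALLED`) nuclei per
#' vascular zone; `UNASSIGNED` labeled nuclei are reported under their own
#' key so that the zone counts plus `UNASSIGNED` always add up to the number
#' of labeled nuclei.
#'
#' @param records nucleus table with phases and zones set.
#' @return named integer vector over [ZONE_LEVELS].
#' @export
zone_census <- function(records) {
  labeled <- records[records$phase %in% c("G1G0", "S", "G2"), ]
  counts <- table(factor(labeled$zone, levels = ZONE_LEVELS))
  setNames(as.integer(counts), names(counts))
}
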