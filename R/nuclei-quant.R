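# Nuclear segmentation from the ERG channel and per-nucleus MFI measurement.
#
# The ERG stain marks every endothelial nucleus; its mask is the measurement
# unit for both reporter channels. Segmentation is classical: Gaussian
# smoothing, Otsu global threshold, hole filling, small-object removal and an
# optional distance-transform watershed to split touching nuclei. All
# parameters are exposed; defaults suit ~10-20 px diameter nuclei.

#' Segmentation parameters
#'
#' @param sigma Gaussian smoothing sigma (px) applied before thresholding.
#' @param min_area minimum object area (px); smaller components are dropped.
#' @param watershed split touching nuclei by watershed on the distance
#'   transform of the binary mask?
#' @param watershed_tolerance minimum height (px of distance transform)
#'   separating two objects for the watershed to keep them distinct; larger
#'   values split less.
#' @param exclude_border drop nuclei whose mask touches the image border?
#'   Border nuclei are partially observed, so their area and MFI are biased.
#' @return list of class `seg_params`.
#' @export
seg_params <- function(sigma = 2, min_area = 30, watershed = TRUE,
                       watershed_tolerance = 1, exclude_border = TRUE) {
  structure(list(sigma = sigma, min_area = min_area, watershed = watershed,
                 watershed_tolerance = watershed_tolerance,
                 exclude_border = exclude_border),
            class = "seg_params")
}

#' Segment endothelial nuclei from the ERG channel
#'
#' @param erg 2D numeric matrix (rows = y, columns = x), finite-valued.
#' @param params a [seg_params()] list.
#' @param retina_id retina identifier stamped into the nucleus table.
#' @return list with `labels` (integer matrix, 0 = background, k = nucleus k,
#'   labels consecutive in raster order of each object's first pixel, with the
#'   parameters used attached as attribute `provenance`) and `nuclei` (nucleus
#'   table with centroid, area and zeroed MFIs).
#' @export
segment_nuclei <- function(erg, params = seg_params(), retina_id = "retina") {
  stopifnot(is.matrix(erg), all(is.finite(erg)))
  empty <- function() {
    labels <- matrix(0L, nrow(erg), ncol(erg))
    attr(labels, "provenance") <- unclass(params)
    list(labels = labels,
         nuclei = nucleus_table(integer(), numeric(), numeric(), numeric(),
                                numeric(), numeric(), retina_id = retina_id))
  }
  rng <- range(erg)
  if (diff(rng) <= 0) return(empty())  # constant image: nothing to segment

  img <- (erg - rng[1]) / diff(rng)
  sm <- if (params$sigma > 0) EBImage::gblur(img, sigma = params$sigma) else img
  thr <- EBImage::otsu(sm, range = c(0, 1))
  mask <- sm > thr
  if (!any(mask)) return(empty())
  mask <- EBImage::fillHull(mask)

  labels <- if (params$watershed) {
    EBImage::watershed(EBImage::distmap(mask),
                       tolerance = params$watershed_tolerance)
  } else {
    EBImage::bwlabel(mask)
  }
  labels <- matrix(as.integer(labels), nrow(erg), ncol(erg))

  area <- tabulate(labels[labels > 0L])
  drop <- which(area < params$min_area)
  if (params$exclude_border) {
    border <- unique(c(labels[1, ], labels[nrow(labels), ],
                       labels[, 1], labels[, ncol(labels)]))
    drop <- union(drop, border[border > 0L])
  }
  if (length(drop)) labels[labels %in% drop] <- 0L
  if (!any(labels > 0L)) return(empty())

  # relabel 1..N by raster order (row-major: y then x) of first pixel
  idx <- which(labels > 0L)
  row <- (idx - 1L) %% nrow(labels) + 1L
  col <- (idx - 1L) %/% nrow(labels) + 1L
  raster <- (row - 1L) * ncol(labels) + col
  old <- labels[idx]
  first_seen <- tapply(raster, old, min)
  order_new <- rank(first_seen, ties.method = "first")
  remap <- integer(max(old))
  remap[as.integer(names(first_seen))] <- as.integer(order_new)
  labels[idx] <- remap[old]

  k <- labels[idx]
  nuclei <- nucleus_table(
    nucleus_id = sort(unique(k)),
    x = tapply(col - 1L, k, mean),
    y = tapply(row - 1L, k, mean),
    area_px = as.numeric(tabulate(k)),
    mfi_venus = 0, mfi_cherry = 0,
    retina_id = retina_id
  )
  attr(labels, "provenance") <- unclass(params)
  list(labels = labels, nuclei = nuclei)
}

#' Mean fluorescence intensity per labeled nucleus
#'
#' `MFI(k)` is the arithmetic mean of `channel` over the pixels where
#' `labels == k` — a plain mask-mean on raw values, no background
#' subtraction unless `background` is given.
#'
#' @param labels integer label matrix from [segment_nuclei()].
#' @param channel 2D numeric matrix, same shape as `labels`.
#' @param background optional constant subtracted from `channel` before
#'   averaging (result floored at 0).
#' @return named numeric vector: MFI for each label `1..N` present.
#' @export
measure_mfi <- function(labels, channel, background = 0) {
  if (!all(dim(labels) == dim(channel))) {
    stop("labels and channel images differ in shape", call. = FALSE)
  }
  idx <- labels > 0L
  vals <- channel[idx] - background
  if (background != 0) vals[vals < 0] <- 0
  ks <- labels[idx]
  out <- tapply(vals, ks, mean)
  setNames(as.numeric(out), names(out))
}

#' Measure reporter MFIs into a nucleus table
#'
#' Convenience wrapper: measures one or more channels over a label map and
#' writes the values into the matching nucleus-table columns.
#'
#' @param seg result of [segment_nuclei()].
#' @param channels named list of channel matrices; names `venus` and `cherry`
#'   populate `mfi_venus` / `mfi_cherry`.
#' @inheritParams measure_mfi
#' @return the nucleus table with MFI columns filled in.
#' @export
measure_nuclei <- function(seg, channels, background = 0) {
  nuc <- seg$nuclei
  for (ch in intersect(c("venus", "cherry"), names(channels))) {
    mfi <- measure_mfi(seg$labels, channels[[ch]], background = background)
    stopifnot(identical(as.integer(names(mfi)), nuc$nucleus_id))
    nuc[[paste0("mfi_", ch)]] <- as.numeric(mfi)
  }
  assert_nucleus_table(nuc)
  nuc
}

#' Write a label map as 16-bit TIFF
#'
#' @param labels integer label matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
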