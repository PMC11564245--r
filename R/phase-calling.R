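# Phase calling from the two reporter MFIs.
#
# PIP-FUCCI logic: mVenus-Cdt1(1-17) is present in G1/G0 and G2, absent in S;
# mCherry-Gem(1-110) is present in S and G2, absent in G1/G0. A nucleus
# negative in both channels is UNLABELED and excluded from quantification.
# Positivity thresholds are estimated per retina because reporter expression
# and staining vary between animals.

#' Channel positivity thresholds
#'
#' @param venus_on,cherry_on strictly positive MFI thresholds; MFI equal to
#'   the threshold counts as positive.
#' @param method tag recording how the thresholds were obtained.
#' @return list of class `channel_thresholds`.
#' @export
channel_thresholds <- function(venus_on, cherry_on, method = "manual") {
  stopifnot(is.finite(venus_on), is.finite(cherry_on),
            venus_on > 0, cherry_on > 0)
  structure(list(venus_on = venus_on, cherry_on = cherry_on, method = method),
            class = "channel_thresholds")
}

#' Estimate per-retina reporter positivity thresholds
#'
#' Default method is Otsu's criterion on `log1p(MFI)` per channel: reporter
#' MFIs are strongly bimodal (expressing vs. non-expressing nuclei) and the
#' log transform symmetrizes the right-skewed fluorescence distribution. The
#' alternative `"mad"` method places the threshold at the background mode plus
#' `k` robust standard deviations (`mode + k * MAD`); it is also the fallback
#' when a channel's distribution is degenerate (effectively unimodal), in
#' which case a warning is emitted.
#'
#' @param records nucleus table with >= 20 rows of finite MFIs.
#' @param method `"otsu"` (default) or `"mad"`.
#' @param k multiplier for the MAD method.
#' @return a [channel_thresholds()] object (thresholds on the raw MFI scale).
#' @export
estimate_thresholds <- function(records, method = c("otsu", "mad"), k = 3) {
  method <- match.arg(method)
  if (nrow(records) < 20) {
    stop(sprintf("threshold estimation needs >= 20 nuclei, got %d",
                 nrow(records)), call. = FALSE)
  }
  one <- function(x, channel) {
    if (method == "otsu") {
      t_log <- otsu_1d(log1p(x))
      if (!isTRUE(attr(t_log, "degenerate"))) {
        return(list(thr = expm1(as.numeric(t_log)), method = "otsu"))
      }
      warning(sprintf("%s MFI distribution is degenerate; falling back to mode + %g*MAD",
                      channel, k), call. = FALSE)
    }
    # background mode via kernel density peak, plus k robust SDs
    if (length(unique(x)) == 1L) {
      return(list(thr = max(x[1], .Machine$double.eps), method = "mad"))
    }
    d <- density(x)
    mode_x <- d$x[which.max(d$y)]
    list(thr = max(mode_x + k * mad(x), .Machine$double.eps), method = "mad")
  }
  v <- one(records$mfi_venus, "venus")
  c_ <- one(records$mfi_cherry, "cherry")
  channel_thresholds(max(v$thr, .Machine$double.eps),
                     max(c_$thr, .Machine$double.eps),
                     method = paste(unique(c(v$method, c_$method)), collapse = "+"))
}

#' Call cell-cycle phases from reporter MFIs
#'
#' A pure function of `(mfi_venus, mfi_cherry, thr)`:
#' venus+ cherry- is `G1G0`; venus- cherry+ is `S`; double-positive is `G2`
#' (the reporter cannot separate G2 from M); double-negative is `UNLABELED`
#' and takes no part in phase quantification. "Positive" means MFI >= the
#' channel threshold.
#'
#' @param records nucleus table.
#' @param thr a [channel_thresholds()] object.
#' @return the nucleus table with `phase` set for every row.
#' @export
call_phases <- function(records, thr) {
  stopifnot(inherits(thr, "channel_thresholds"))
  vp <- records$mfi_venus >= thr$venus_on
  cp <- records$mfi_cherry >= thr$cherry_on
  records$phase <- ifelse(vp & !cp, "G1G0",
                   ifelse(!vp & cp, "S",
                   ifelse(vp & cp, "G2", "UNLABELED")))
  records
}

#' Fraction of ERG+ nuclei carrying a reporter label
#'
#' Labeled means called `G1G0`, `S` or `G2`; `UNLABELED` and `UNCALLED`
#' nuclei count in the denominator only.
#'
#' @param records nucleus table with phases called.
#' @return fraction in [0, 1].
#' @export
labeling_fraction <- function(records) {
  if (nrow(records) == 0) stop("empty nucleus table", call. = FALSE)
  mean(records$phase %in% c("G1G0", "S", "G2"))
}
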