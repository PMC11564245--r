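# Per-retina, per-zone cell-cycle statistics: phase proportions, capped
# count ratios, marker concordance and group comparisons. The retina is the
# experimental unit: proportions and ratios are computed per retina and only
# then averaged across retinas.

LABELED_PHASES <- c("G1G0", "S", "G2")

#' Per-retina per-zone phase proportions
#'
#' For every `(retina_id, zone)` combination with at least one
#' reporter-labeled nucleus: counts of G1/G0, S and G2 nuclei, their
#' percentages of the labeled nuclei in that zone, and the capped G2/S and
#' G2/G1 count ratios (see [capped_ratio()]). A pseudo-zone `WHOLE_RETINA`
#' aggregates all labeled nuclei of each retina, including `UNASSIGNED` ones.
#' Zones present in the data but with zero labeled nuclei get a row with
#' `flag = "no_labeled_nuclei"` and `NA` percentages.
#'
#' @param records nucleus table with phases (and, for zone rows, zones)
#'   assigned.
#' @return data.frame with columns `retina_id`, `zone`, `n_G1G0`, `n_S`,
#'   `n_G2`, `n_labeled`, `p_G1G0`, `p_S`, `p_G2`, `r_G2S`, `r_G2G1`, `flag`.
#' @export
phase_proportions <- function(records) {
  one_row <- function(retina_id, zone, sub) {
    n <- c(G1G0 = sum(sub$phase == "G1G0"), S = sum(sub$phase == "S"),
           G2 = sum(sub$phase == "G2"))
    tot <- sum(n)
    p <- if (tot > 0) 100 * n / tot else c(G1G0 = NA_real_, S = NA_real_,
                                           G2 = NA_real_)
    data.frame(retina_id = retina_id, zone = zone,
               n_G1G0 = n[["G1G0"]], n_S = n[["S"]], n_G2 = n[["G2"]],
               n_labeled = tot,
               p_G1G0 = p[["G1G0"]], p_S = p[["S"]], p_G2 = p[["G2"]],
               r_G2S = capped_ratio(n[["G2"]], n[["S"]]),
               r_G2G1 = capped_ratio(n[["G2"]], n[["G1G0"]]),
               flag = if (tot > 0) "" else "no_labeled_nuclei",
               stringsAsFactors = FALSE)
  }
  labeled <- records[records$phase %in% LABELED_PHASES, ]
  rows <- list()
  for (rid in unique(records$retina_id)) {
    sub_all <- records[records$retina_id == rid, ]
    rows[[length(rows) + 1L]] <- one_row(rid, "WHOLE_RETINA",
                                         sub_all[sub_all$phase %in% LABELED_PHASES, ])
    zones <- intersect(ZONE_LEVELS, unique(sub_all$zone))
    zones <- setdiff(zones, "UNASSIGNED")
    for (z in zones) {
      rows[[length(rows) + 1L]] <-
        one_row(rid, z, labeled[labeled$retina_id == rid & labeled$zone == z, ])
    }
  }
  do.call(rbind, rows)
}

#' Capped count ratio
#'
#' Ratio of two phase counts with the zero-denominator convention used for
#' zone statistics: if the denominator is zero but the numerator positive the
#' ratio is set to `cap` (default 10) so that retinas with, e.g., G2 tip
#' cells but no S tip cells still enter calculations and statistics; if both
#' counts are zero the ratio is 0 and flagged via the `"both_zero"`
#' attribute.
#'
#' @param numerator,denominator non-negative counts (vectorized).
#' @param cap value substituted when the denominator is 0 and the numerator
#'   positive.
#' @return numeric vector of ratios, with attribute `both_zero` (logical
#'   vector) marking 0/0 entries.
#' @export
capped_ratio <- function(numerator, denominator, cap = 10) {
  if (any(numerator < 0) || any(denominator < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  stopifnot(cap > 0)
  out <- ifelse(denominator > 0, numerator / denominator,
                ifelse(numerator > 0, cap, 0))
  attr(out, "both_zero") <- numerator == 0 & denominator == 0
  out
}

#' Across-retina summary of a zone's capped ratio
#'
#' Extracts the per-retina capped ratio of one zone from a
#' [phase_proportions()] table and averages it across retinas (the retina,
#' not the pooled counts, is the unit of analysis). The reported mean is
#' rounded half away from zero to 1 decimal when >= 1 and 2 decimals when
#' < 1, matching how such ratios are conventionally quoted.
#'
#' @param table a [phase_proportions()] data.frame.
#' @param zone zone to summarize.
#' @param ratio `"G2S"` or `"G2G1"`.
#' @return list with `per_retina` (named numeric), `mean` (raw mean) and
#'   `mean_reported` (rounded as above).
#' @export
ratio_summary <- function(table, zone, ratio = c("G2S", "G2G1")) {
  ratio <- match.arg(ratio)
  col <- paste0("r_", ratio)
  sub <- table[table$zone == zone, ]
  if (nrow(sub) == 0) stop(sprintf("no rows for zone '%s'", zone), call. = FALSE)
  vals <- setNames(sub[[col]], sub$retina_id)
  m <- mean(vals)
  list(per_retina = vals, mean = m,
       mean_reported = round_half_away(m, if (abs(m) >= 1) 1 else 2))
}

#' Concordance between phase calls and a binary marker
#'
#' Cross-tabulates reporter phase calls against a per-nucleus binary marker
#' (EdU incorporation or Ki67 positivity). For each phase it reports the
#' percentage of marker-positive labeled cells falling in that phase
#' (`pct_of_marker_pos`, columns sum to 100) and the percentage of that
#' phase's cells that are marker-positive (`pct_marker_pos_in_phase`).
#' `UNLABELED`/`UNCALLED` nuclei are excluded from all denominators.
#'
#' @param records nucleus table with phases called and a logical marker
#'   column.
#' @param marker marker column name (`"edu"` or `"ki67"`).
#' @return data.frame, one row per phase, with counts and the two
#'   percentages; attribute `flag` is `"no_marker_positive"` when no labeled
#'   cell is marker-positive (the `pct_of_marker_pos` breakdown is then NA).
#' @export
marker_concordance <- function(records, marker) {
  if (is.null(records[[marker]])) {
    stop(sprintf("no marker column '%s'", marker), call. = FALSE)
  }
  lab <- records[records$phase %in% LABELED_PHASES & !is.na(records[[marker]]), ]
  pos <- lab[[marker]]
  n_pos <- sum(pos)
  out <- do.call(rbind, lapply(LABELED_PHASES, function(ph) {
    in_ph <- lab$phase == ph
    data.frame(
      phase = ph,
      n = sum(in_ph),
      n_marker_pos = sum(in_ph & pos),
      pct_of_marker_pos = if (n_pos > 0) 100 * sum(in_ph & pos) / n_pos else NA_real_,
      pct_marker_pos_in_phase = if (sum(in_ph) > 0) {
        100 * sum(in_ph & pos) / sum(in_ph)
      } else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  attr(out, "flag") <- if (n_pos == 0) "no_marker_positive" else ""
  out
}

#' Group comparisons of per-retina summaries
#'
#' Standard designs used on zone-level summaries, with the retina as the
#' unit:
#' * `"one_way"`: one-way ANOVA of `value ~ group` followed by Sidak-adjusted
#'   pairwise comparisons (via \pkg{emmeans}).
#' * `"two_way"`: two-way factorial ANOVA `value ~ group * group2` with
#'   Sidak-adjusted comparisons of `group` within `group2`.
#' * `"paired"`: paired t test between the two levels of `group`, pairing on
#'   `retina_id`.
#'
#' @param df data.frame with columns `value`, `group`, `retina_id`, and for
#'   the two-way design `group2`.
#' @param design `"one_way"`, `"two_way"` or `"paired"`.
#' @param alternative passed to [t.test()] for the paired design.
#' @return list with elements `design`, `anova` (for ANOVA designs),
#'   `comparisons` (data.frame of contrasts with Sidak-adjusted p values) or,
#'   for the paired design, `estimate`, `statistic`, `p_value`, and
#'   `group_means`.
#' @export
compare_groups <- function(df, design = c("one_way", "two_way", "paired"),
                           alternative = "two.sided") {
  design <- match.arg(design)
  df$group <- factor(df$group)
  counts <- table(df$group)
  if (any(counts < 2)) {
    stop(sprintf("group(s) with < 2 replicates: %s",
                 paste(names(counts)[counts < 2], collapse = ", ")),
         call. = FALSE)
  }
  group_means <- tapply(df$value, df$group, mean)

  if (design == "paired") {
    lv <- levels(df$group)
    if (length(lv) != 2) stop("paired design needs exactly 2 groups", call. = FALSE)
    wide <- merge(df[df$group == lv[1], c("retina_id", "value")],
                  df[df$group == lv[2], c("retina_id", "value")],
                  by = "retina_id")
    tt <- t.test(wide$value.x, wide$value.y, paired = TRUE,
                 alternative = alternative)
    return(list(design = design, estimate = unname(tt$estimate),
                statistic = unname(tt$statistic), p_value = tt$p.value,
                group_means = group_means))
  }

  fml <- if (design == "one_way") value ~ group else value ~ group * group2
  if (design == "two_way") df$group2 <- factor(df$group2)
  fit <- aov(fml, data = df)
  em <- if (design == "one_way") {
    emmeans::emmeans(fit, "group")
  } else {
    emmeans::emmeans(fit, "group", by = "group2")
  }
  cmp <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise",
                                                 adjust = "sidak")))
  list(design = design, anova = summary(fit), comparisons = cmp,
       group_means = group_means)
}
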