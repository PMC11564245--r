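counts_table <- function(n_g1, n_s, n_g2, zone = "MC", retina_id = "r1") {
  phase <- rep(c("G1G0", "S", "G2"), c(n_g1, n_s, n_g2))
  nucleus_table(seq_along(phase), x = 0, y = 0, area_px = 40,
                mfi_venus = 1, mfi_cherry = 1, phase = phase, zone = zone,
                retina_id = retina_id)
}

test_that("phase proportions reproduce closed-form percentages", {
  pp <- phase_proportions(counts_table(86, 9, 5))
  row <- pp[pp$zone == "MC", ]
  expect_equal(c(row$p_G1G0, row$p_S, row$p_G2), c(86, 9, 5))
  row2 <- phase_proportions(counts_table(0, 0, 4))
  row2 <- row2[row2$zone == "MC", ]
  expect_equal(c(row2$p_G1G0, row2$p_S, row2$p_G2), c(0, 0, 100))
})

test_that("percentages per row sum to 100 and zero-count zones are flagged", {
  ds <- generate_retina(small_retina_cfg(seed = 2), render = FALSE)
  rec <- call_phases(ds$nuclei, estimate_thresholds(ds$nuclei))
  pp <- phase_proportions(rec)
  ok <- pp$flag == ""
  expect_true(all(abs(pp$p_G1G0[ok] + pp$p_S[ok] + pp$p_G2[ok] - 100) < 0.01))

  rec2 <- counts_table(5, 2, 1)
  rec2$phase[rec2$zone == "MC"][1] <- "UNLABELED"
  rec2$zone[8] <- "Tip"; rec2$phase[8] <- "UNLABELED"
  pp2 <- phase_proportions(rec2)
  tip <- pp2[pp2$zone == "Tip", ]
  expect_identical(tip$flag, "no_labeled_nuclei")
  expect_true(is.na(tip$p_G1G0))
})

test_that("seeded phase mixtures are recovered within multinomial tolerance", {
  cfg <- small_retina_cfg(seed = 2, image_size = 2400,
                          zone_mix = c(86, 9, 5))
  cfg$zone_counts <- round(cfg$zone_counts / sum(cfg$zone_counts) * 4000)
  ds <- generate_retina(cfg, render = FALSE)
  rec <- call_phases(ds$nuclei, estimate_thresholds(ds$nuclei))
  w <- phase_proportions(rec)
  w <- w[w$zone == "WHOLE_RETINA", ]
  # 3 SE of the seeded multinomial at n ~ 4000*0.82 is ~1.5 points
  expect_equal(w$p_G1G0, 86, tolerance = 1.5 / 86)
  expect_equal(w$p_S, 9, tolerance = 1.5 / 9)
  expect_equal(w$p_G2, 5, tolerance = 1.5 / 5)
})

test_that("capped_ratio implements the zero-denominator convention", {
  expect_equal(as.numeric(capped_ratio(5, 0)), 10)
  expect_equal(as.numeric(capped_ratio(0, 7)), 0)
  expect_equal(as.numeric(capped_ratio(9, 1)), 9)
  expect_error(capped_ratio(-1, 2), "non-negative")
  r <- capped_ratio(0, 0)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "both_zero"))
  # cap applies for every positive numerator; monotone in the numerator
  expect_true(all(as.numeric(capped_ratio(1:20, 0)) == 10))
  expect_true(all(diff(as.numeric(capped_ratio(0:10, 3))) >= 0))
})

test_that("ratio_summary averages per-retina ratios with reporting rounding", {
  tabs <- do.call(rbind, lapply(1:4, function(i) {
    # S counts 0,0,1,1 with G2 counts chosen to give ratios 10,10,9,8
    counts_table(c(20, 20, 30, 30)[i], c(0, 0, 1, 1)[i], c(3, 5, 9, 8)[i],
                 zone = "Tip", retina_id = paste0("r", i))
  }))
  pp <- phase_proportions(tabs)
  rs <- ratio_summary(pp, "Tip", "G2S")
  expect_equal(unname(rs$per_retina), c(10, 10, 9, 8))
  expect_equal(rs$mean, 9.25)
  expect_equal(rs$mean_reported, 9.3)  # half away from zero at 1 decimal

  single <- phase_proportions(counts_table(10, 5, 3, zone = "AFC"))
  rs2 <- ratio_summary(single, "AFC", "G2S")
  expect_equal(rs2$mean_reported, 0.6)  # < 1: two decimals (0.60)
})

test_that("ratio_summary equals brute-force recomputation from raw counts", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      counts <- matrix(rpois(12, 4), 4, 3)
      tabs <- do.call(rbind, lapply(1:4, function(i) {
        counts_table(counts[i, 1], counts[i, 2], counts[i, 3],
                     zone = "Stalk", retina_id = paste0("r", i))
      }))
      rs <- ratio_summary(phase_proportions(tabs), "Stalk", "G2G1")
      brute <- mean(vapply(1:4, function(i) {
        g2 <- counts[i, 3]; g1 <- counts[i, 1]
        if (g1 > 0) g2 / g1 else if (g2 > 0) 10 else 0
      }, numeric(1)))
      expect_equal(rs$mean, brute)
    }
  })
})

test_that("marker concordance recovers seeded EdU and Ki67 models", {
  rec <- counts_table(0, 6, 0)
  rec$edu <- TRUE
  mc <- marker_concordance(rec, "edu")
  expect_equal(mc$pct_of_marker_pos[mc$phase == "S"], 100)

  cfg <- small_retina_cfg(seed = 9)
  cfg$zone_counts <- round(cfg$zone_counts / sum(cfg$zone_counts) * 5000)
  cfg$image_size <- 2600
  ds <- generate_retina(cfg, render = FALSE)
  rec <- call_phases(ds$nuclei, estimate_thresholds(ds$nuclei))
  rec$edu <- ds$nuclei$edu
  rec$ki67 <- ds$nuclei$ki67
  edu <- marker_concordance(rec, "edu")
  expect_equal(edu$pct_marker_pos_in_phase[edu$phase == "S"], 89,
               tolerance = 2 / 89)
  ki <- marker_concordance(rec, "ki67")
  pct_neg_g1 <- 100 - ki$pct_marker_pos_in_phase[ki$phase == "G1G0"]
  expect_equal(pct_neg_g1, 76, tolerance = 2 / 76)
})

test_that("marker concordance flags the no-positive case", {
  rec <- counts_table(5, 3, 2)
  rec$edu <- FALSE
  mc <- marker_concordance(rec, "edu")
  expect_identical(attr(mc, "flag"), "no_marker_positive")
  expect_true(all(is.na(mc$pct_of_marker_pos)))
  expect_error(marker_concordance(rec, "ki67"), "no marker column")
})

test_that("identical groups compare with zero difference and p near 1", {
  df <- data.frame(value = rep(c(1, 2, 3, 4), 2),
                   group = rep(c("A", "B"), each = 4),
                   retina_id = rep(paste0("r", 1:4), 2))
  cmp <- compare_groups(df, "one_way")
  expect_equal(cmp$comparisons$estimate, 0)
  expect_gt(cmp$comparisons$p.value, 0.99)
})

test_that("paired t matches the closed-form textbook statistic", {
  tip <- c(10, 10, 9, 8)
  afc <- c(1, 0.5, 0.7, 0.6)
  df <- data.frame(value = c(tip, afc),
                   group = rep(c("Tip", "AFC"), each = 4),
                   retina_id = rep(paste0("r", 1:4), 2))
  cmp <- compare_groups(df, "paired")
  d <- afc - tip  # groups are compared in factor order (AFC first)
  t_exp <- mean(d) / (sd(d) / sqrt(4))
  p_exp <- 2 * pt(-abs(t_exp), df = 3)
  expect_equal(cmp$statistic, t_exp, tolerance = 1e-9)
  expect_equal(cmp$p_value, p_exp, tolerance = 1e-9)
  expect_equal(cmp$estimate, mean(d), tolerance = 1e-9)
})

test_that("insufficient replicates abort with the group named", {
  df <- data.frame(value = c(1, 2, 3), group = c("A", "A", "B"),
                   retina_id = c("r1", "r2", "r1"))
  expect_error(compare_groups(df, "one_way"), "B")
})

test_that("a 9-point front-zone G2 gap is detected in most simulated cohorts", {
  # Monte-Carlo power of the paired comparison at 150 cells per front zone
  # across 4 retinas (small tip zones of ~40 cells have less power; see the
  # methods vignette)
  withr::with_seed(13, {
    detected <- replicate(100, {
      tip <- rbinom(4, 150, 0.173) / 150 * 100
      afc <- rbinom(4, 150, 0.084) / 150 * 100
      df <- data.frame(value = c(tip, afc),
                       group = rep(c("Tip", "AFC"), each = 4),
                       retina_id = rep(paste0("r", 1:4), 2))
      compare_groups(df, "paired", alternative = "less")$p_value < 0.05
    })
    expect_gte(mean(detected), 0.8)
  })
})
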