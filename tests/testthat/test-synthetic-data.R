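test_that("sim_config validates proportions and feasibility knobs", {
  expect_error(sim_config(class_props = c(0.5, 0.2, 0.2, 0.2)), "sum")
  expect_error(sim_config(companion_max_gap = 3000, flank = 1000))
  cfg <- sim_config()
  expect_equal(sum(cfg$class_props), 1)
  expect_equal(unname(cfg$chrom_sizes["chrM"]), 16569)
})

test_that("generators are deterministic given (config, seed)", {
  cfg <- sim_config(n_beta = 60, n_alpha_only = 10)
  a <- suppressMessages(simulate_peaks(cfg, seed = 5))
  b <- suppressMessages(simulate_peaks(cfg, seed = 5))
  expect_identical(a, b)
  c <- suppressMessages(simulate_peaks(cfg, seed = 6))
  expect_false(identical(a$beta$start, c$beta$start))
  s1 <- simulate_sequences(20, seed = 9)
  s2 <- simulate_sequences(20, seed = 9)
  expect_identical(s1, s2)
})

test_that("simulate_peaks honors the planted co-binding design", {
  cfg <- sim_config(n_beta = 120, n_alpha_only = 20)
  sim <- suppressMessages(simulate_peaks(cfg, seed = 17))
  expect_equal(nrow(sim$beta), 120)
  truth_beta <- sim$truth[sim$truth$set == "beta", ]
  # class counts follow the configured proportions exactly (largest-remainder)
  expect_equal(unname(table(truth_beta$class)[paste0("class", 1:4)]),
               unname(ersitemap:::.assign_counts(120, cfg$class_props)),
               ignore_attr = TRUE)
  # zero-overlap design: no companions -> no heterodimers
  cfg0 <- sim_config(n_beta = 40, n_alpha_only = 10,
                     class_props = c(class1 = 0, class2 = 0,
                                     class3 = 1, class4 = 0),
                     class5_frac = 1)
  sim0 <- suppressMessages(simulate_peaks(cfg0, seed = 3))
  br <- suppressMessages(merge_regions(extend_intervals(sim0$beta, 1000,
                                                        cfg0$chrom_sizes)))
  ar <- suppressMessages(merge_regions(extend_intervals(sim0$alpha_tap, 1000,
                                                        cfg0$chrom_sizes)))
  p <- suppressMessages(partition_subtypes(br, ar))
  expect_equal(nrow(p$heterodimer), 0)
  # full-overlap design: every beta region is a heterodimer
  cfg1 <- sim_config(n_beta = 40, n_alpha_only = 0,
                     class_props = c(class1 = 0, class2 = 1,
                                     class3 = 0, class4 = 0))
  sim1 <- suppressMessages(simulate_peaks(cfg1, seed = 3))
  br1 <- suppressMessages(merge_regions(extend_intervals(sim1$beta, 1000,
                                                         cfg1$chrom_sizes)))
  ar1 <- suppressMessages(merge_regions(extend_intervals(sim1$alpha_tap, 1000,
                                                         cfg1$chrom_sizes)))
  p1 <- suppressMessages(partition_subtypes(br1, ar1))
  expect_equal(nrow(p1$homodimer_beta), 0)
  # infeasible design errors
  expect_error(suppressMessages(simulate_peaks(
    sim_config(chrom_sizes = c(s1 = 1e5), n_beta = 500), seed = 1)),
    "infeasible")
})

test_that("classify_six recovers planted labels on the simulated design", {
  cfg <- sim_config(n_beta = 200, n_alpha_only = 30)
  sim <- suppressMessages(simulate_peaks(cfg, seed = 23))
  mk <- function(x) suppressMessages(
    merge_regions(extend_intervals(x, cfg$flank, cfg$chrom_sizes)))
  cls <- suppressMessages(classify_six(sim$beta, mk(sim$beta),
                                       mk(sim$alpha_tap), mk(sim$alpha_wt),
                                       sim$alpha_tap))
  truth <- sim$truth
  got_beta <- substr(as.character(cls$class[cls$set == "beta"]), 1, 6)
  expect_equal(got_beta, truth$class[truth$set == "beta"])
  # alpha-only peaks appear after the companion alpha peaks in alpha_tap
  n_comp <- nrow(sim$alpha_tap) - sum(truth$set == "alpha_tap")
  got_alpha <- substr(as.character(cls$class[cls$set == "alpha_tap"]), 1, 6)
  expect_equal(got_alpha[seq_len(sum(truth$set == "alpha_tap")) + n_comp],
               truth$class[truth$set == "alpha_tap"])
})

test_that("simulate_sequences plants exact class mixes when cleaning", {
  sim <- simulate_sequences(100, fractions = c(ere = 0.5, here = 0.3,
                                               none = 0.2), seed = 29)
  cls <- classify_ere(sim$sequences)
  expect_equal(as.character(cls), sim$truth$class, ignore_attr = TRUE)
  expect_equal(unname(table(sim$truth$class)),
               unname(c(ERE_PLUS = 50, HERE_PLUS = 30, NONE = 20)),
               ignore_attr = TRUE)
  expect_error(simulate_sequences(5, site_len = 10), "site_len")
})

test_that("full-ERE planting survives the configured mismatch budget", {
  sim <- simulate_sequences(60, fractions = c(ere = 1, here = 0, none = 0),
                            k_mismatch = 1, seed = 31)
  cls <- classify_ere(sim$sequences)
  expect_true(all(cls == "ERE_PLUS"))
})

test_that("raw (unclean) background yields a bounded chance ERE+ rate", {
  # measured false-positive rate of the open consensus PWM at default
  # thresholds on 200-bp uniform sites; the analytic per-offset rate
  # (~3.7e-4 x ~376 strand-offsets) predicts ~12-13%, not <5%
  sim <- simulate_sequences(400, fractions = c(ere = 0, here = 0, none = 1),
                            clean = FALSE, seed = 37)
  cls <- classify_ere(sim$sequences)
  fp <- mean(cls == "ERE_PLUS")
  expect_gt(fp, 0.02)
  expect_lt(fp, 0.25)
})

test_that("simulate_genes produces valid gene models on the toy genome", {
  cfg <- sim_config(n_genes = 40)
  g <- simulate_genes(cfg, seed = 41)
  expect_equal(nrow(g), 40)
  expect_true(all(g$strand %in% c("+", "-")))
  expect_true(all(vapply(seq_len(nrow(g)), function(i) {
    ex <- g$exons[[i]]
    all(ex[, 1] < ex[, 2]) && ex[1, 1] >= g$tx_start[i] &&
      ex[nrow(ex), 2] <= g$tx_end[i]
  }, logical(1))))
  expect_true(all(g$tss == ifelse(g$strand == "+", g$tx_start, g$tx_end - 1)))
})

test_that("simulate_expression echoes the configured group proportions", {
  cfg <- sim_config(expr_props = c(wt_only = 0.25, both = 0.17,
                                   beta_only = 0.56, opposite = 0.02))
  sim <- simulate_expression(sprintf("g%04d", 1:1000), cfg, seed = 43)
  counts <- table(sim$truth$group)
  expect_equal(unname(counts[c("WT_ONLY", "BOTH_CONCORDANT", "BETA_ONLY",
                               "OPPOSITE")]),
               unname(c(250, 170, 560, 20)), ignore_attr = TRUE)
  expect_true(all(sim$table$diffscore[sim$table$time == 0] == 0))
})

test_that("simulate_mirna places the requested loci with planted proximity", {
  cfg <- sim_config(n_beta = 60, n_alpha_only = 10)
  peaks <- suppressMessages(simulate_peaks(cfg, seed = 47))
  mir <- simulate_mirna(peaks$beta, cfg$chrom_sizes, n_loci = 40, f = 0.5,
                        seed = 49)
  expect_equal(nrow(mir$loci), 40)
  expect_equal(sum(mir$truth$planted), 20)
  # every planted locus really is within the window of some site
  planted <- mir$loci[mir$truth$planted, ]
  o <- oracle_proximity(peaks$beta, planted, 10000)
  expect_equal(o$n_loci_near, 20)
})
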