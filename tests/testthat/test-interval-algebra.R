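toy_sizes <- c(chrA = 1e5, chrB = 1e5)

test_that("extend_intervals does flank arithmetic with boundary clipping", {
  cs <- c(chr1 = 10000)
  x <- genomic_intervals("chr1", c(5000, 300), c(5200, 500), id = c("a", "b"))
  e <- extend_intervals(x, 1000, c(chr1 = 1e6))
  expect_equal(e$start, c(4000, 0))
  expect_equal(e$end, c(6200, 1500))
  e2 <- extend_intervals(genomic_intervals("chr1", 9500, 9800), 1000, cs)
  expect_equal(c(e2$start, e2$end), c(8500, 10000))
  expect_equal(extend_intervals(x, 0, cs)[c("start", "end")],
               x[c("start", "end")])
  expect_error(extend_intervals(x, 100, c(chr2 = 1000)), "absent")
})

test_that("merge_regions merges overlap components, not book-ended spans", {
  x <- genomic_intervals(rep("chr1", 3), c(0, 50, 200), c(100, 150, 300),
                         id = c("a", "b", "c"))
  m <- suppressMessages(merge_regions(x))
  expect_equal(m$start, c(0, 200))
  expect_equal(m$end, c(150, 300))
  expect_equal(m$member_ids[[1]], c("a", "b"))
  expect_equal(m$n_members, c(2L, 1L))

  # book-ended intervals share zero bases and stay separate
  b <- suppressMessages(merge_regions(
    genomic_intervals("chr1", c(0, 100), c(100, 200))))
  expect_equal(nrow(b), 2)
})

test_that("merge matches the per-basepair mask oracle and is idempotent", {
  withr::local_seed(11)
  for (rep in 1:25) {
    x <- random_intervals(200, toy_sizes)
    m <- merge_regions(x)
    o <- oracle_merge_spans(x, toy_sizes)
    expect_equal(m[c("chrom", "start", "end")], o, ignore_attr = TRUE)
    # union of spans preserved, members overlap their region
    m2 <- merge_regions(genomic_intervals(m$chrom, m$start, m$end))
    expect_equal(m2[c("chrom", "start", "end")], o, ignore_attr = TRUE)
    xi <- split(seq_len(nrow(x)), x$id)
    for (r in sample(nrow(m), 5)) {
      for (id in m$member_ids[[r]]) {
        i <- xi[[id]]
        expect_true(x$chrom[i] == m$chrom[r] &&
                      x$start[i] < m$end[r] && x$end[i] > m$start[r])
      }
    }
  }
})

test_that("partition_subtypes splits het/homo regions and conserves counts", {
  beta <- genomic_intervals("c1", c(0, 300), c(100, 400))
  alpha <- genomic_intervals("c1", 50, 150)
  p <- suppressMessages(partition_subtypes(beta, alpha))
  expect_equal(nrow(p$heterodimer), 1)
  expect_equal(p$heterodimer$start, 0)
  expect_equal(nrow(p$homodimer_beta), 1)
  expect_equal(nrow(p$homodimer_alpha), 0)

  d <- suppressMessages(partition_subtypes(
    genomic_intervals("c1", 0, 100), genomic_intervals("c1", 200, 300)))
  expect_equal(nrow(d$heterodimer), 0)
  expect_equal(nrow(d$homodimer_beta), 1)
  expect_equal(nrow(d$homodimer_alpha), 1)

  over <- genomic_intervals("c1", c(0, 50), c(100, 150))
  expect_error(suppressMessages(partition_subtypes(over, alpha)),
               "overlapping regions")

  withr::local_seed(5)
  for (rep in 1:10) {
    b <- suppressMessages(merge_regions(random_intervals(60, toy_sizes)))
    a <- suppressMessages(merge_regions(random_intervals(40, toy_sizes)))
    p <- suppressMessages(partition_subtypes(b, a))
    expect_equal(nrow(p$heterodimer) + nrow(p$homodimer_beta), nrow(b))
    expect_equal(p$n_alpha_partners + nrow(p$homodimer_alpha), nrow(a))
    hit <- oracle_overlaps_any(b, a)
    expect_equal(p$heterodimer$region_id, b$region_id[hit])
    expect_equal(p$homodimer_beta$region_id, b$region_id[!hit])
    expect_equal(p$homodimer_alpha$region_id,
                 a$region_id[!oracle_overlaps_any(a, b)])
  }
})

test_that("prevalent_sites finds subtype-only peaks through their regions", {
  cs <- c(c1 = 1e6)
  lone <- genomic_intervals("c1", 5000, 5200, id = "b1")
  lr <- suppressMessages(merge_regions(extend_intervals(lone, 1000, cs)))
  none <- genomic_intervals(character(0), numeric(0), numeric(0))
  nr <- suppressMessages(merge_regions(none))
  p <- suppressMessages(prevalent_sites(lone, none, lr, nr))
  expect_equal(p$beta_only$id, "b1")
  expect_equal(nrow(p$alpha_only), 0)

  # peaks 500 bp apart: +/-1000 extension makes their regions overlap,
  # so neither peak is subtype-only
  b <- genomic_intervals("c1", 5000, 5200, id = "b1")
  a <- genomic_intervals("c1", 5700, 5900, id = "a1")
  br <- suppressMessages(merge_regions(extend_intervals(b, 1000, cs)))
  ar <- suppressMessages(merge_regions(extend_intervals(a, 1000, cs)))
  p <- suppressMessages(prevalent_sites(b, a, br, ar))
  expect_equal(nrow(p$beta_only), 0)
  expect_equal(nrow(p$alpha_only), 0)

  # region/peak provenance mismatch: peak far outside every region
  stray <- genomic_intervals("c1", 900000, 900200, id = "x1")
  expect_error(suppressMessages(prevalent_sites(stray, none, br, nr)),
               "provenance mismatch")
})

test_that("classify_six assigns definitional labels on hand-built cases", {
  cs <- c(c1 = 1e6)
  regions_of <- function(x) {
    if (nrow(x) == 0) return(suppressMessages(merge_regions(x)))
    suppressMessages(merge_regions(extend_intervals(x, 1000, cs)))
  }
  none <- genomic_intervals(character(0), numeric(0), numeric(0))
  b <- genomic_intervals("c1", 50000, 50200, id = "b1")
  awt <- genomic_intervals("c1", 50300, 50500, id = "w1")
  cls <- suppressMessages(classify_six(b, regions_of(b), regions_of(none),
                                       regions_of(awt), none))
  expect_equal(as.character(cls$class), "class1_competition")

  cls <- suppressMessages(classify_six(b, regions_of(b), regions_of(none),
                                       regions_of(none), none))
  expect_equal(as.character(cls$class), "class3_beta_specific")

  atap <- genomic_intervals("c1", 90000, 90200, id = "t1")
  cls <- suppressMessages(classify_six(b, regions_of(b), regions_of(atap),
                                       regions_of(none), atap))
  expect_equal(as.character(cls$class[cls$set == "beta"]),
               "class3_beta_specific")
  expect_equal(as.character(cls$class[cls$set == "alpha_tap"]),
               "class5_alpha_displacement")
  cls <- suppressMessages(classify_six(b, regions_of(b), regions_of(atap),
                                       regions_of(atap), atap))
  expect_equal(as.character(cls$class[cls$set == "alpha_tap"]),
               "class6_alpha_specific")
})

test_that("classify_six matches the brute-force oracle and is exhaustive", {
  withr::local_seed(23)
  cs <- c(chrA = 5e5, chrB = 5e5)
  for (rep in 1:10) {
    b <- random_intervals(20, cs)
    at <- random_intervals(12, cs)
    aw <- random_intervals(12, cs)
    br <- suppressMessages(merge_regions(extend_intervals(b, 1000, cs)))
    atr <- suppressMessages(merge_regions(extend_intervals(at, 1000, cs)))
    awr <- suppressMessages(merge_regions(extend_intervals(aw, 1000, cs)))
    cls <- suppressMessages(classify_six(b, br, atr, awr, at))
    o <- oracle_classify_six(b, br, atr, awr, at)
    expect_equal(as.character(cls$class[cls$set == "beta"]), o$beta)
    expect_equal(as.character(cls$class[cls$set == "alpha_tap"]), o$alpha)
    expect_false(anyNA(cls$class))  # exhaustive over both universes
  }
})

test_that("tag_density_filter keeps density >= threshold, boundary inclusive", {
  x <- genomic_intervals(rep("c1", 3), c(0, 200, 400), c(100, 300, 500),
                         id = c("keep60", "drop40", "keep50"),
                         tag_count = c(60, 40, 50))
  kept <- suppressMessages(tag_density_filter(x, 0.5))
  expect_equal(kept$id, c("keep60", "keep50"))
  no_tags <- genomic_intervals("c1", 0, 100)
  expect_error(suppressMessages(tag_density_filter(no_tags)), "tag_count")
})

test_that("extension composes additively before clipping", {
  withr::local_seed(3)
  cs <- c(chrA = 1e7)
  x <- random_intervals(50, c(chrA = 1e6))
  one <- extend_intervals(extend_intervals(x, 300, cs), 700, cs)
  two <- extend_intervals(x, 1000, cs)
  expect_equal(one[c("start", "end")], two[c("start", "end")])
  # with clipping, spans are subsets of the unclipped extension
  small <- c(chrA = 1e6)
  clipped <- extend_intervals(x, 1000, small)
  expect_true(all(clipped$start >= two$start & clipped$end <= two$end))
})
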