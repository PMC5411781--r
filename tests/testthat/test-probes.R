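test_that("concordance requires insert within mean +/- 3 SD and opposite strands", {
  pl <- data.frame(probe_id = sprintf("p%d", 1:4), ref_chrom = "chr1",
                   start = 0,
                   end = c(150e3, 181e3, 150e3, 120e3),
                   strand1 = c("+", "+", "+", "+"),
                   strand2 = c("-", "-", "+", "-"),
                   stringsAsFactors = FALSE)
  keep <- filter_concordant(pl, 150e3, 10e3)
  expect_setequal(keep$probe_id, c("p1", "p4"))   # 181 kb > 180 kb bound; (+,+) out
  # boundary: exactly mean + 3 SD stays in
  pl$end[2] <- 180e3
  expect_true("p2" %in% filter_concordant(pl, 150e3, 10e3)$probe_id)
})

test_that("concordance is invariant to swapping the two end records", {
  set.seed(15)
  pl <- data.frame(probe_id = sprintf("p%d", 1:50), ref_chrom = "chr1",
                   start = 0, end = round(rnorm(50, 150e3, 15e3)),
                   strand1 = sample(c("+", "-"), 50, TRUE),
                   strand2 = sample(c("+", "-"), 50, TRUE),
                   stringsAsFactors = FALSE)
  sw <- pl; sw$strand1 <- pl$strand2; sw$strand2 <- pl$strand1
  expect_equal(filter_concordant(pl, 150e3, 10e3)$probe_id,
               filter_concordant(sw, 150e3, 10e3)$probe_id)
})

test_that("probe features match per-base counting on random tracks", {
  set.seed(16)
  len <- 2e5
  chrom_len <- c(chr1 = len)
  rand_track <- function(n, max_len) {
    s <- sort(sample.int(len - max_len, n))
    data.frame(chrom = "chr1", start = s,
               end = s + sample.int(max_len, n, replace = TRUE))
  }
  for (i in 1:8) {
    aln <- rand_track(12, 5000); ce <- rand_track(8, 800)
    rep_t <- rand_track(10, 2000)
    probes <- data.frame(probe_id = sprintf("b%d", 1:5), chrom = "chr1",
                         start = sort(sample.int(len - 5e4, 5)))
    probes$end <- probes$start + 4e4
    f <- extract_features(probes, aln, ce, rep_t)
    plen <- probes$end - probes$start
    expect_equal(f$alignable_fraction * plen,
                 brute_overlap_bases(probes, aln, chrom_len))
    expect_equal(f$total_repeat_len,
                 brute_overlap_bases(probes, rep_t, chrom_len))
    # max clipped CE by brute force
    ce_m <- chromforge:::iv_merge(ce)
    for (k in 1:5) {
      cl <- pmin(ce_m$end, probes$end[k]) - pmax(ce_m$start, probes$start[k])
      cl <- cl[cl > 0]
      expect_equal(f$max_ce_len[k], if (length(cl)) max(cl) else 0)
    }
  }
})

test_that("feature counts are additive under probe splitting", {
  set.seed(17)
  tr <- data.frame(chrom = "chr1", start = c(100, 5000, 12000),
                   end = c(1500, 9000, 20000))
  whole <- data.frame(probe_id = "w", chrom = "chr1", start = 0, end = 25000)
  left <- data.frame(probe_id = "l", chrom = "chr1", start = 0, end = 8000)
  right <- data.frame(probe_id = "r", chrom = "chr1", start = 8000, end = 25000)
  fw <- extract_features(whole, tr, tr[0, ], tr)
  fl <- extract_features(left, tr, tr[0, ], tr)
  fr <- extract_features(right, tr, tr[0, ], tr)
  expect_equal(fw$total_repeat_len, fl$total_repeat_len + fr$total_repeat_len)
  expect_equal(fw$alignable_fraction * 25000,
               fl$alignable_fraction * 8000 + fr$alignable_fraction * 17000)
})

test_that("the universality rule reproduces its truth table on all boundary combinations", {
  grid <- expand.grid(alignable_fraction = c(0.92, 0.93),
                      max_ce_len = c(299, 300),
                      total_repeat_len = c(1289, 1290))
  grid$has_ce_ge_3bp <- TRUE
  got <- classify_universal(grid)
  want <- with(grid, alignable_fraction >= 0.93 &
                 (max_ce_len >= 300 | (total_repeat_len < 1290 & has_ce_ge_3bp)))
  expect_equal(got == "universal_candidate", want)
  # the short-repeat branch requires the >= 3 bp CE presence flag
  no_ce <- data.frame(alignable_fraction = 0.95, max_ce_len = 10,
                      total_repeat_len = 100, has_ce_ge_3bp = FALSE)
  expect_equal(as.character(classify_universal(no_ce)), "restricted")
  # long repeats are tolerated when a long CE exists
  long_rep <- data.frame(alignable_fraction = 0.93, max_ce_len = 300,
                         total_repeat_len = 5000, has_ce_ge_3bp = TRUE)
  expect_equal(as.character(classify_universal(long_rep)), "universal_candidate")
})

test_that("greedy spaced panel accepts every 10th candidate on a regular grid", {
  cand <- data.frame(probe_id = sprintf("p%03d", 1:100), chrom = "chr1",
                     start = (1:100) * 1e5 - 500, end = (1:100) * 1e5 + 500)
  res <- select_spaced_panel(cand, 1e6)
  expect_equal(nrow(res$panel), 10)
  expect_equal(res$panel$probe_id, sprintf("p%03d", seq(1, 100, by = 10)))
  one <- select_spaced_panel(cand[5, ], 1e6)
  expect_equal(nrow(one$panel), 1)
})

test_that("panel gaps are never below the target spacing (gap-scan oracle)", {
  set.seed(18)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    cand <- data.frame(probe_id = sprintf("p%d", seq_len(n)),
                       chrom = sample(c("c1", "c2"), n, TRUE),
                       start = sample.int(5e6, n))
    cand$end <- cand$start + 1000
    res <- select_spaced_panel(cand, 3e5, chrom_levels = c("c1", "c2", "c3"))
    for (ch in unique(res$panel$chrom)) {
      p <- sort(res$panel$pos[res$panel$chrom == ch])
      if (length(p) > 1) expect_true(all(diff(p) >= 3e5))
      # maximality: every rejected candidate is within spacing of an accepted one
      rej <- setdiff(cand$probe_id[cand$chrom == ch], res$panel$probe_id)
      for (r in rej) {
        pos <- cand$start[cand$probe_id == r] + 500
        expect_true(min(abs(pos - p)) < 3e5)
      }
    }
    expect_true("c3" %in% res$uncovered)
  }
})
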