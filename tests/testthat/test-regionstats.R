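test_that("flank density profiles follow the five-window arithmetic", {
  ebr <- data.frame(ref_chrom = "chr1", start = 50e3, end = 60e3)
  cne <- data.frame(chrom = "chr1",
                    start = c(31e3, 41e3, 61e3, 71e3),
                    end = c(32e3, 42e3, 62e3, 72e3))
  prof <- flank_density_profile(ebr, cne, 200e3)
  expect_equal(unname(prof), c(0.1, 0.1, 0.0, 0.1, 0.1))
  # chromosome start: lower-coordinate flanks unavailable
  ebr0 <- data.frame(ref_chrom = "chr1", start = 0, end = 10e3)
  prof0 <- flank_density_profile(ebr0, cne, 200e3)
  expect_true(all(is.na(prof0[c("-2", "-1")])))
  expect_false(anyNA(prof0[c("EBR", "+1", "+2")]))
  expect_error(flank_density_profile(data.frame(ref_chrom = "chr1",
                                                start = 5, end = 5),
                                     cne, 200e3), "length 0")
})

test_that("flank profiles and window counts match per-base oracles", {
  set.seed(23)
  len <- 5e5
  chrom_len <- c(c1 = len)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    s <- sort(sample.int(len - 500, n))
    cne <- data.frame(chrom = "c1", start = s,
                      end = s + sample.int(400, n, replace = TRUE))
    w <- sample(c(7e3, 11e3, 20e3), 1)
    a <- sample.int(len - 6 * w, 1) + 2 * w
    ebr <- data.frame(ref_chrom = "c1", start = a, end = a + w)
    prof <- flank_density_profile(ebr, cne, len)
    q <- data.frame(chrom = "c1", start = a + w * (-2:2), end = a + w * (-1:3))
    expect_equal(unname(prof) * w, brute_overlap_bases(q, cne, chrom_len))
  }
})

test_that("window scan labels classes with EBR precedence and the coverage filter", {
  lens <- c(c1 = 20e3)
  cne <- data.frame(chrom = "c1", start = 0, end = 0)[0, ]
  mshsb <- data.frame(chrom = "c1", start = 0, end = 10e3)   # below 1.5 Mb cutoff
  ebrs <- structure(data.frame(ref_chrom = "c1", start = 4e3, end = 6e3,
                               type = "intra", excluded = FALSE,
                               partner_chrom = NA, partner_start = NA,
                               partner_end = NA, stringsAsFactors = FALSE),
                    class = c("ebr_set", "data.frame"))
  tr <- window_scan(lens, cne, mshsb, ebrs, w = 1000)
  expect_equal(nrow(tr), 20)
  expect_true(all(tr$class[tr$start >= 4e3 & tr$start < 6e3] == "intra_EBR"))
  expect_false(any(tr$class == "msHSB"))   # filtered by the >1.5 Mb rule
  # msHSB large enough labels, EBR still wins on overlap
  big <- window_scan(c(c1 = 4e6), cne,
                     data.frame(chrom = "c1", start = 0, end = 2e6), ebrs)
  expect_equal(unique(big$class[big$start < 4e3]), "msHSB")
  expect_equal(unique(big$class[big$start >= 4e3 & big$start < 6e3]),
               "intra_EBR")
  expect_equal(unique(big$class[big$start >= 2e6]), "rest")
  # windows at most half-covered are unusable
  cov <- data.frame(chrom = "c1", start = 0, end = 10.5e3)
  tr2 <- window_scan(lens, cne, mshsb, ebrs, covered = cov)
  expect_equal(sum(tr2$usable), 10)   # window 11 has exactly 500 covered bases
  # terminal short window dropped
  tr3 <- window_scan(c(c1 = 20.4e3), cne, mshsb, ebrs)
  expect_equal(max(tr3$end), 20e3)
})

test_that("window class means reflect the generating densities", {
  sim <- small_sim(seed = 24)
  tracks <- simulate_feature_tracks(sim$anc, sim$des$ebrs, seed = 25)
  ebrs <- structure(data.frame(ref_chrom = character(), start = numeric(),
                               end = numeric(), type = character(),
                               excluded = logical(), stringsAsFactors = FALSE),
                    class = c("ebr_set", "data.frame"))
  tr <- window_scan(sim$anc$chrom_lengths, tracks$cne, sim$anc$mshsb, ebrs,
                    min_mshsb_bp = 0)
  cd <- class_densities(tr)
  expect_lt(abs(cd$mean_density[cd$class == "msHSB"] - 0.11), 0.02)
  expect_lt(cd$mean_density[cd$class == "rest"], 0.03)
})

test_that("zero-window distances match brute-force nearest search", {
  mk_track <- function(dens, w = 1000) {
    structure(data.frame(chrom = "c1", start = (seq_along(dens) - 1) * w,
                         end = seq_along(dens) * w, covered = w,
                         cne_bases = dens * w, te_bases = 0,
                         class = "rest", usable = TRUE),
              class = c("window_track", "data.frame"))
  }
  res <- zero_window_distances(mk_track(c(0.11, 0, 0, 0.12)), 0.11)
  expect_equal(res$distances$distance, c(1, 1))
  # no qualifying window: all zero-windows excluded and tallied
  res2 <- zero_window_distances(mk_track(c(0, 0.01, 0)), 0.11)
  expect_equal(nrow(res2$distances), 0)
  expect_equal(res2$excluded, 2)
  # uniformly dense track has no zero windows at all
  res3 <- zero_window_distances(mk_track(rep(0.2, 5)), 0.11)
  expect_equal(nrow(res3$distances), 0)
  set.seed(26)
  for (i in 1:20) {
    dens <- sample(c(0, 0, 0.05, 0.12, 0.3), sample(5:40, 1), replace = TRUE)
    got <- zero_window_distances(mk_track(dens), 0.11)$distances$distance
    want <- brute_zero_distances(seq_along(dens) - 1, dens, 0.11)
    want <- want[!is.na(want)]
    expect_equal(got, want)
  }
})

test_that("zero-window distances are symmetric under chromosome reversal", {
  set.seed(27)
  dens <- sample(c(0, 0, 0.05, 0.15), 30, replace = TRUE)
  mk <- function(d) structure(
    data.frame(chrom = "c1", start = (seq_along(d) - 1) * 1000,
               end = seq_along(d) * 1000, covered = 1000,
               cne_bases = d * 1000, te_bases = 0, class = "rest",
               usable = TRUE), class = c("window_track", "data.frame"))
  fwd <- zero_window_distances(mk(dens), 0.11)$distances$distance
  rev_ <- zero_window_distances(mk(rev(dens)), 0.11)$distances$distance
  expect_equal(sort(fwd), sort(rev_))
})

test_that("identical groups give a non-significant omnibus test", {
  g <- list(a = rep(c(1, 2, 3, 4), 5), b = rep(c(1, 2, 3, 4), 5),
            c = rep(c(1, 2, 3, 4), 5))
  cmp <- compare_groups(g)
  expect_gt(cmp$omnibus$p, 0.9)
  expect_null(cmp$pairwise)
})

test_that("pairwise Mann-Whitney p equals the exhaustive permutation p for n <= 8", {
  set.seed(28)
  for (i in 1:15) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- sample(1:6, n1, replace = TRUE)   # ties on purpose
    y <- sample(1:6, n2, replace = TRUE) + sample(0:3, 1)
    cmp <- compare_groups(list(x = x, y = y), alpha = 1.01)
    expect_equal(cmp$pairwise$p, brute_mw_p(x, y))
  }
  # tie-free data also agrees with wilcox.test's exact two-sided p
  x <- c(1.2, 3.4, 5.1, 7.9); y <- c(2.2, 4.4, 9.1, 10.3, 11.7)
  cmp <- compare_groups(list(x = x, y = y), alpha = 1.01)
  expect_equal(cmp$pairwise$p, stats::wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("shifted groups recover the planted median ordering", {
  set.seed(5)
  shift <- c(msHSB = 4, intra = 19, fusion = 23, fission = 35)
  g <- lapply(shift, function(s) s + stats::rexp(200, 1 / 6))
  cmp <- compare_groups(g)
  expect_lt(cmp$omnibus$p, 0.05)
  med <- cmp$groups$median[match(names(shift), cmp$groups$group)]
  expect_true(all(diff(med) > 0))
  expect_true(all(cmp$pairwise$p_adj < 0.05))
})

test_that("groups below n = 2 are excluded with a warning", {
  expect_warning(cmp <- compare_groups(list(a = 1:10, b = 11:20, c = 5)),
                 "excluding")
  expect_equal(nrow(cmp$groups), 2)
  expect_error(suppressWarnings(compare_groups(list(a = 1:10, b = 2))),
               "two non-empty")
})

test_that("TE enrichment detects planted doubling and stays quiet under the null", {
  set.seed(29)
  lens <- c(c1 = 4e6)
  wins_n <- 400
  ebrs <- structure(data.frame(ref_chrom = "c1", start = seq(0, 1e6 - 1e4,
                                                             by = 1e4 * 2),
                               end = seq(0, 1e6 - 1e4, by = 2e4) + 1e4,
                               type = "intra", excluded = FALSE,
                               partner_chrom = NA, partner_start = NA,
                               partner_end = NA, stringsAsFactors = FALSE),
                    class = c("ebr_set", "data.frame"))
  mk_te <- function(rate_in, rate_out) {
    pos <- sort(sample.int(4e6 - 500, 4000))
    in_ebr <- pos < 1e6 & (pos %/% 1e4) %% 2 == 0
    keep <- runif(length(pos)) < ifelse(in_ebr, rate_in, rate_out)
    data.frame(chrom = "c1", start = pos[keep], end = pos[keep] + 400,
               name = "LTR-ERV1")
  }
  null_te <- mk_te(0.3, 0.3)
  res0 <- te_enrichment(null_te, ebrs, lens)
  expect_false(any(res0$significant))
  hot_te <- mk_te(0.85, 0.3)
  res1 <- te_enrichment(hot_te, ebrs, lens)
  expect_true(res1$significant[res1$family == "LTR-ERV1"])
  expect_gt(res1$mean_ebr, res1$mean_rest)
  # families of short elements (mean <= 100 bp) are skipped
  tiny <- data.frame(chrom = "c1", start = seq(0, 3e6, by = 1e4),
                     end = seq(0, 3e6, by = 1e4) + 50, name = "SINE-ish")
  expect_equal(nrow(te_enrichment(tiny, ebrs, lens)), 0)
})
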