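make_sfs <- function(df, resolution = 150e3) {
  df$sf_id <- sprintf("SF%04d", seq_len(nrow(df)))
  df$n_blocks <- 1L
  structure(df, resolution = resolution, class = c("sf_set", "data.frame"))
}

pairs_at <- function(scaf, pos, n = 5, halfspan = 1000) {
  data.frame(scaffold = scaf, start1 = pos - halfspan, end1 = pos - halfspan + 100,
             start2 = pos + halfspan - 100, end2 = pos + halfspan,
             orientation = "FR", stringsAsFactors = FALSE)[rep(1, n), ]
}

test_that("physical coverage counts strictly spanning fragments", {
  none <- data.frame(scaffold = character(), start1 = numeric(),
                     end1 = numeric(), start2 = numeric(), end2 = numeric(),
                     orientation = character())
  expect_equal(physical_coverage(none, "s1", c(0, 10)), c(0L, 0L))
  two <- data.frame(scaffold = "s1", start1 = c(0, 50), end1 = c(10, 60),
                    start2 = c(90, 140), end2 = c(100, 150),
                    orientation = "FR")
  expect_equal(physical_coverage(two, "s1", 75), 2L)
  expect_equal(physical_coverage(two, "s1", 100), 1L)  # end-exclusive
})

test_that("physical coverage equals the brute-force span count on random pairs", {
  set.seed(9)
  n <- 1000
  st <- sample.int(9e4, n)
  fl <- sample(2000:6000, n, replace = TRUE)
  rp <- data.frame(scaffold = "s1", start1 = st, end1 = st + 100,
                   start2 = st + fl - 100, end2 = st + fl, orientation = "FR")
  pts <- sample.int(1e5, 50)
  expect_equal(physical_coverage(rp, "s1", pts),
               brute_physical_coverage(rp, "s1", pts))
})

test_that("two reference-adjacent scaffolds chain into one PCF in reference order", {
  sfs <- make_sfs(data.frame(
    target_seq = c("sB", "sA"), t_start = c(0, 0), t_end = c(1e6, 1e6),
    ref_chrom = "chrA", r_start = c(1e6, 0), r_end = c(2e6, 1e6),
    strand = "+", stringsAsFactors = FALSE))
  res <- build_pcfs(sfs, outgroup_sfs = sfs, threshold_c = 5)
  expect_equal(length(unique(res$pcfs$pcf_id)), 1)
  expect_equal(res$pcfs$scaffold, c("sA", "sB"))  # reference order
  expect_equal(nrow(res$joints), 0)
})

test_that("species-specific internal inversions survive when coverage is adequate", {
  sfs <- make_sfs(data.frame(
    target_seq = "s1", t_start = c(0, 1e6, 1.4e6),
    t_end = c(1e6, 1.4e6, 2.4e6),
    ref_chrom = "chrA", r_start = c(0, 1e6, 1.4e6),
    r_end = c(1e6, 1.4e6, 2.4e6),
    strand = c("+", "-", "+"), stringsAsFactors = FALSE))
  rp <- rbind(pairs_at("s1", 1e6), pairs_at("s1", 1.4e6))
  res <- build_pcfs(sfs, outgroup_sfs = sfs, read_pairs = rp, threshold_c = 3)
  expect_equal(nrow(res$joints), 0)
  expect_equal(length(unique(res$pcfs$pcf_id)), 1)
  expect_equal(nrow(res$pcfs), 1)   # one intact member
})

test_that("a zero-coverage reference-conflicting joint splits the scaffold", {
  sfs <- make_sfs(data.frame(
    target_seq = "s1", t_start = c(0, 1e6), t_end = c(1e6, 2e6),
    ref_chrom = c("chrA", "chrB"), r_start = c(0, 5e6), r_end = c(1e6, 6e6),
    strand = "+", stringsAsFactors = FALSE))
  res <- build_pcfs(sfs, outgroup_sfs = sfs, threshold_c = 3)
  expect_equal(nrow(res$joints), 1)
  expect_equal(res$joints$coverage, 0)
  expect_false(res$joints$ref_agree)
  expect_equal(nrow(res$pcfs), 2)
  expect_equal(length(unique(res$pcfs$pcf_id)), 2)
})

test_that("split-joint gaps narrow with fine blocks and gate testability at 6 kb", {
  joints <- data.frame(scaffold = "s1", gap_start = 10e3, gap_end = 30e3,
                       coverage = 0, ref_agree = FALSE, out_agree = FALSE,
                       status = "untested", testable = FALSE,
                       left_ref_chrom = "chrA", left_strand = "+",
                       right_ref_chrom = "chrB", right_strand = "+",
                       stringsAsFactors = FALSE)
  fine <- rbind(
    data.frame(target_seq = "s1", t_start = 12e3, t_end = 24e3,
               ref_chrom = "chrA", r_start = 0, r_end = 12e3, strand = "+"),
    data.frame(target_seq = "s1", t_start = 28e3, t_end = 29e3,
               ref_chrom = "chrB", r_start = 5e6, r_end = 5.001e6, strand = "+"))
  out <- find_split_joints(joints, fine)
  expect_equal(out$gap_start, 24e3)
  expect_equal(out$gap_end, 28e3)
  expect_true(out$testable)       # 4 kb < 6 kb
  # interval oracle: the narrowed gap is the original gap minus the span
  # claimed by the innermost left block end and right block start
  expect_equal(out$gap_end - out$gap_start,
               (30e3 - 10e3) - (24e3 - 10e3) - (30e3 - 28e3))

  # no narrowing possible: gap unchanged, > 6 kb, not testable
  out2 <- find_split_joints(joints, fine[0, ])
  expect_equal(out2$gap_start, 10e3)
  expect_equal(out2$gap_end, 30e3)
  expect_false(out2$testable)

  # abutting SFs: zero-length gap is testable
  j0 <- joints; j0$gap_start <- 5e3; j0$gap_end <- 5e3
  expect_true(find_split_joints(j0, fine[0, ])$testable)
})

test_that("threshold calibration maximizes agreement, smallest c on ties", {
  j <- function(conf, refu) {
    data.frame(status = c(rep("confirmed", length(conf)),
                          rep("refuted", length(refu))),
               coverage = c(conf, refu))
  }
  expect_equal(calibrate_threshold(j(c(5, 6, 7), c(0, 1))), 2)
  expect_equal(calibrate_threshold(j(c(4, 6), integer(0))), 4)  # degenerate
  expect_error(calibrate_threshold(j(integer(0), integer(0))), "cannot calibrate")
  # perfectly interleaved coverages: several maximizers, smallest returned
  ji <- j(c(1, 3, 5), c(0, 2, 4))
  expect_equal(calibrate_threshold(ji), brute_calibrate(c(1, 3, 5), c(0, 2, 4)))
  set.seed(13)
  for (i in 1:300) {
    conf <- sample(0:12, sample(1:8, 1), replace = TRUE)
    refu <- sample(0:12, sample(1:8, 1), replace = TRUE)
    expect_equal(calibrate_threshold(j(conf, refu)),
                 brute_calibrate(conf, refu))
  }
})

test_that("refinement welds confirmed joints and splits refuted ones", {
  # a refuted joint between adjacent members of one PCF splits it in two
  pcfs <- structure(data.frame(
    pcf_id = "PCF_001", member_index = 1:3,
    scaffold = c("s1", "s1", "s2"),
    s_start = c(0, 1e6, 0), s_end = c(1e6, 2e6, 5e5),
    orientation = "+", ref_chrom = "chrA",
    r_start = c(0, 1e6, 2e6), r_end = c(1e6, 2e6, 2.5e6),
    stringsAsFactors = FALSE), class = c("pcf_set", "data.frame"))
  joints <- data.frame(scaffold = "s1", gap_start = 1e6, gap_end = 1e6,
                       gap_start0 = 1e6, gap_end0 = 1e6,
                       coverage = 0, status = "refuted",
                       stringsAsFactors = FALSE)
  out <- refine_pcfs(pcfs, joints)
  expect_equal(length(unique(out$pcf_id)), 2)

  # confirmed: the same joint across two PCFs is welded back together
  pcfs2 <- structure(data.frame(
    pcf_id = c("PCF_001", "PCF_002"), member_index = 1L,
    scaffold = "s1", s_start = c(0, 1e6), s_end = c(1e6, 2e6),
    orientation = "+", ref_chrom = c("chrA", "chrB"),
    r_start = c(0, 4e6), r_end = c(1e6, 5e6),
    stringsAsFactors = FALSE), class = c("pcf_set", "data.frame"))
  joints2 <- joints; joints2$status <- "confirmed"
  out2 <- refine_pcfs(pcfs2, joints2)
  expect_equal(length(unique(out2$pcf_id)), 1)
  expect_equal(nrow(out2), 1)           # welded into one member
  expect_equal(out2$s_start, 0); expect_equal(out2$s_end, 2e6)

  # alternative order: fragments rejoined right-before-left
  joints3 <- joints; joints3$status <- "alternative_confirmed"
  out3 <- refine_pcfs(pcfs2, joints3)
  expect_equal(length(unique(out3$pcf_id)), 1)
  expect_equal(nrow(out3), 2)
  expect_equal(out3$s_start, c(1e6, 0))  # swapped order
})

test_that("map conflicts override confirmation and split at the weakest junction", {
  pcfs <- structure(data.frame(
    pcf_id = "PCF_001", member_index = 1:3,
    scaffold = c("s1", "s2", "s3"),
    s_start = 0, s_end = c(1e6, 2e6, 3e6),
    orientation = "+", ref_chrom = "chrA",
    r_start = c(0, 1e6, 3e6), r_end = c(1e6, 3e6, 6e6),
    stringsAsFactors = FALSE), class = c("pcf_set", "data.frame"))
  joints <- data.frame(scaffold = character(), gap_start = numeric(),
                       gap_end = numeric(), coverage = numeric(),
                       status = character())
  expect_message(out <- refine_pcfs(pcfs, joints, map_conflicts = "PCF_001"),
                 "map conflict")
  expect_equal(length(unique(out$pcf_id)), 2)
})

test_that("assembly stats match hand values and a brute-force N50 oracle", {
  expect_equal(assembly_stats(10)$n50, 10)
  st <- assembly_stats(c(8, 5, 4, 3))
  expect_equal(st$n50, 5)
  expect_equal(st$total_bp, 20)
  expect_equal(assembly_stats(numeric(0))$n50, 0)
  set.seed(14)
  for (i in 1:30) {
    lens <- sample.int(100, sample(1:20, 1), replace = TRUE)
    expect_equal(assembly_stats(lens)$n50, brute_n50(lens))
  }
  st2 <- assembly_stats(c(50, 50), input_total_bp = 200, n_scaffolds = 17,
                        n_sfs = 20)
  expect_equal(st2$pct_of_input, 50)
  expect_equal(st2$sf_scaffold_ratio, 0.85)
})

test_that("raising the coverage threshold never reduces the number of split joints", {
  sim <- small_sim(seed = 71, chimera_rate = 0.2)
  blocks <- sim_alignment_blocks(sim$shred$scaffold_map, sim$des$karyotype,
                                 split_mean_bp = 8e4, gap_bp = 100, seed = 72)
  sfs <- detect_sfs(blocks, 150e3)
  nj <- vapply(c(0, 2, 5, 10, 50, 1e9), function(th) {
    nrow(build_pcfs(sfs, outgroup_sfs = sfs,
                    read_pairs = sim$shred$read_pairs,
                    threshold_c = th)$joints)
  }, numeric(1))
  expect_true(all(diff(nj) >= 0))
})

test_that("no SF bases are lost when building PCFs", {
  sim <- small_sim(seed = 73, chimera_rate = 0.2)
  blocks <- sim_alignment_blocks(sim$shred$scaffold_map, sim$des$karyotype,
                                 split_mean_bp = 8e4, gap_bp = 100, seed = 74)
  sfs <- detect_sfs(blocks, 150e3)
  res <- build_pcfs(sfs, outgroup_sfs = sfs,
                    read_pairs = sim$shred$read_pairs, threshold_c = 5)
  for (k in seq_len(nrow(sfs))) {
    hit <- res$pcfs$scaffold == sfs$target_seq[k] &
      res$pcfs$s_start <= sfs$t_start[k] & res$pcfs$s_end >= sfs$t_end[k]
    expect_true(any(hit))
  }
})
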