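test_that("empty plan leaves the ancestor unchanged", {
  anc <- ancestor_genome(c(chrA = 1000, chrB = 500),
                         data.frame(chrom = "chrA", start = 100, end = 400))
  des <- apply_rearrangements(anc, rearrangement_plan())
  expect_equal(sort(unname(des$chrom_lengths)), c(500, 1000))
  expect_equal(nrow(des$karyotype), 2)
  expect_equal(nrow(des$ebrs), 0)
})

test_that("a single fusion joins two chromosomes and records one fusion EBR", {
  anc <- ancestor_genome(c(chrA = 1000, chrB = 500),
                         data.frame(chrom = character(), start = numeric(),
                                    end = numeric()))
  plan <- rearrangement_plan(list(op_fusion("chrA", "end", "chrB", "start")))
  des <- apply_rearrangements(anc, plan)
  expect_equal(length(des$chrom_lengths), 1)
  expect_equal(unname(des$chrom_lengths), 1500)
  expect_equal(des$ebrs$type, "fusion")
  expect_equal(des$ebrs$der_pos, 1000)
  expect_equal(des$ebrs$ref_chrom, "chrA")
  expect_equal(des$ebrs$ref_chrom2, "chrB")
})

test_that("invalid operation coordinates are rejected with the op index", {
  anc <- ancestor_genome(c(chrA = 1000),
                         data.frame(chrom = character(), start = numeric(),
                                    end = numeric()))
  plan <- rearrangement_plan(list(op_inversion("chrA", 100, 200),
                                  op_fission("chrA", 5000)))
  expect_error(apply_rearrangements(anc, plan), "op 2")
})

test_that("segment bookkeeping matches a per-base replay oracle", {
  # 10 inversions + 2 fissions + 1 fusion on a <= 1 Mb genome, seed 7
  anc <- sim_ancestor(3, 9e5, seed = 7)
  plan <- random_plan(anc, 10, 2, 1, min_event_bp = 2e4, max_event_bp = 6e4,
                      margin_bp = 2e4, min_separation_bp = 1e4,
                      mshsb_buffer_bp = 0, seed = 7)
  des <- apply_rearrangements(anc, plan)
  oracle <- replay_plan_per_base(anc, plan)
  got <- expand_karyotype_per_base(des$karyotype)
  expect_setequal(names(got), names(oracle))
  for (ch in names(oracle)) expect_identical(got[[ch]], oracle[[ch]])
})

test_that("any random plan conserves total genome content", {
  for (s in 1:5) {
    anc <- sim_ancestor(4, 8e6, seed = s)
    plan <- random_plan(anc, 5, 2, 2, seed = s + 100)
    des <- apply_rearrangements(anc, plan)
    expect_equal(sum(des$chrom_lengths), sum(anc$chrom_lengths))
    # segments tile the ancestor exactly once
    by_src <- split(des$karyotype, des$karyotype$src_chrom)
    for (ch in names(by_src)) {
      segs <- by_src[[ch]][order(by_src[[ch]]$src_start), ]
      expect_equal(segs$src_start[1], 0)
      expect_equal(segs$src_end[nrow(segs)],
                   unname(anc$chrom_lengths[ch]))
      if (nrow(segs) > 1) {
        expect_equal(segs$src_start[-1], segs$src_end[-nrow(segs)])
      }
    }
  }
})

test_that("identical seeds reproduce identical simulator output", {
  s1 <- small_sim(seed = 11)
  s2 <- small_sim(seed = 11)
  expect_identical(s1$des, s2$des)
  expect_identical(s1$shred, s2$shred)
  s3 <- small_sim(seed = 12)
  expect_false(identical(s1$shred$read_pairs, s3$shred$read_pairs))
})

test_that("chimera_rate 0 gives contiguous scaffolds; rate 1 gives one joint each", {
  sim <- small_sim(seed = 21, chimera_rate = 0)
  expect_equal(nrow(sim$shred$joints), 0)
  per_scaf <- split(sim$shred$scaffold_map, sim$shred$scaffold_map$scaffold)
  for (m in per_scaf) {
    expect_equal(nrow(m), 1)
  }
  sim1 <- small_sim(seed = 22, chimera_rate = 1)
  n_two <- table(sim1$shred$scaffold_map$scaffold)
  multi <- names(n_two)[n_two == 2]
  expect_setequal(sim1$shred$joints$scaffold, multi)
  expect_equal(anyDuplicated(sim1$shred$joints$scaffold), 0)
})

test_that("mean physical coverage tracks the Lander-Waterman expectation", {
  anc <- sim_ancestor(1, 1e6, seed = 31)
  des <- apply_rearrangements(anc, rearrangement_plan())
  n_pairs <- 5000; insert <- 2000
  shred <- shred_to_scaffolds(des, mean_scaffold_bp = 2.5e5, chimera_rate = 0,
                              coverage = list(n_pairs = n_pairs,
                                              insert_mean = insert,
                                              insert_sd = 100),
                              seed = 32)
  expected <- n_pairs * insert / sum(des$chrom_lengths)
  obs <- numeric(0)
  for (s in shred$scaffolds$scaffold) {
    len <- shred$scaffolds$length[shred$scaffolds$scaffold == s]
    pts <- seq(insert, len - insert, length.out = 20)
    obs <- c(obs, physical_coverage(shred$read_pairs, s, pts))
  }
  expect_lt(abs(mean(obs) - expected) / expected, 0.1)
})

test_that("feature tracks honor densities and carve deserts at breakpoints", {
  sim <- small_sim(seed = 41)
  tracks <- simulate_feature_tracks(sim$anc, sim$des$ebrs, seed = 42)
  # deserts: brute-force per-base CNE count around each planted breakpoint
  hw <- c(intra = 19000, fusion = 23000, fission = 35000)
  for (k in seq_len(nrow(sim$des$ebrs))) {
    e <- sim$des$ebrs[k, ]
    h <- hw[[if (e$type == "fusion") "fusion" else e$type]]
    q <- data.frame(chrom = e$ref_chrom, start = e$ref_pos - h,
                    end = e$ref_pos + h)
    expect_equal(brute_overlap_bases(q, tracks$cne, sim$anc$chrom_lengths), 0)
  }
  # realized densities close to targets, away from deserts
  ms <- sim$anc$mshsb
  ms_bases <- sum(brute_overlap_bases(ms, tracks$cne, sim$anc$chrom_lengths))
  ms_len <- sum(ms$end - ms$start)
  expect_lt(abs(ms_bases / ms_len - 0.11), 0.015)
  # zero densities produce an empty track
  empty <- simulate_feature_tracks(sim$anc, sim$des$ebrs,
                                   cne_density_mshsb = 0,
                                   cne_density_background = 0, seed = 43)
  expect_equal(nrow(empty$cne), 0)
})

test_that("probe planting follows the midpoint counting rule and exact order at zero noise", {
  lens <- c(chr1 = 1e7, chr2 = 3.2e6)
  pp <- plant_probes(lens, spacing_bp = 1e6, position_noise_sd = 0, seed = 51)
  expect_equal(sum(pp$probes$chrom == "chr1"), 10)  # one per window midpoint
  expect_equal(sum(pp$probes$chrom == "chr2"), 3)
  for (ch in names(lens)) {
    m <- pp$map[pp$map$chrom == ch, ]
    truth <- pp$truth[pp$truth$chrom == ch, ]
    expect_identical(m$probe_id[order(m$order_index)],
                     truth$probe_id[order(truth$true_pos)])
    expect_true(all(diff(m$map_position) >= 0))
  }
})

test_that("configured feature distributions hit the intended universal fraction", {
  sampler <- function(n) {
    ok <- seq_len(n) %% 2 == 0  # deterministic half pass, half fail
    data.frame(alignable_fraction = ifelse(ok, 0.95, 0.80),
               max_ce_len = ifelse(ok, 400, 0),
               has_ce_ge_3bp = ok,
               total_repeat_len = 0,
               gene_count = 1, mean_conservation_score = 0.5)
  }
  lens <- c(chr1 = 4e8)
  pp <- plant_probes(lens, spacing_bp = 1e6, feature_sampler = sampler,
                     seed = 3)
  cls <- classify_universal(pp$probes)
  frac <- mean(cls == "universal_candidate")
  expect_equal(frac, 0.5, tolerance = 1e-9)
})
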