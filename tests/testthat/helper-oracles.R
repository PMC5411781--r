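# Independent brute-force oracles. These deliberately use per-base vectors
# and naive enumeration, never the package's interval arithmetic, so that
# agreement is meaningful.

# Per-base replay of a rearrangement plan: every ancestor base carries a
# unique label "<chrom>:<pos>"; descendant chromosomes are label vectors.
replay_plan_per_base <- function(ancestor, plan) {
  state <- lapply(names(ancestor$chrom_lengths), function(ch) {
    n <- ancestor$chrom_lengths[ch]
    paste0(ch, ":", seq_len(n) - 1L)
  })
  names(state) <- names(ancestor$chrom_lengths)
  for (op in plan$ops) {
    if (op$type == "inversion") {
      v <- state[[op$chrom]]
      idx <- (op$start + 1L):op$end
      state[[op$chrom]] <- c(v[seq_len(op$start)], rev(v[idx]),
                             v[seq(op$end + 1L, length.out = length(v) - op$end)])
    } else if (op$type == "fission") {
      v <- state[[op$chrom]]
      state[[paste0(op$chrom, ".1")]] <- v[seq_len(op$pos)]
      state[[paste0(op$chrom, ".2")]] <- v[seq(op$pos + 1L, length(v))]
      state[[op$chrom]] <- NULL
    } else if (op$type == "fusion") {
      a <- state[[op$chrom_a]]; b <- state[[op$chrom_b]]
      if (op$end_a == "start") a <- rev(a)
      if (op$end_b == "end") b <- rev(b)
      state[[paste0(op$chrom_a, "+", op$chrom_b)]] <- c(a, b)
      state[[op$chrom_a]] <- NULL
      state[[op$chrom_b]] <- NULL
    } else if (op$type == "translocation") {
      a <- state[[op$chrom_a]]; b <- state[[op$chrom_b]]
      state[[op$chrom_a]] <- c(a[seq_len(op$pos_a)],
                               b[seq(op$pos_b + 1L, length(b))])
      state[[op$chrom_b]] <- c(b[seq_len(op$pos_b)],
                               a[seq(op$pos_a + 1L, length(a))])
    }
  }
  state
}

# Expand a karyotype segment table into per-base label vectors (reversal is
# plain vector rev(), ignoring strand bookkeeping of the implementation).
expand_karyotype_per_base <- function(karyotype) {
  out <- list()
  for (ch in unique(karyotype$der_chrom)) {
    segs <- karyotype[karyotype$der_chrom == ch, , drop = FALSE]
    segs <- segs[order(segs$der_start), , drop = FALSE]
    v <- character(0)
    for (k in seq_len(nrow(segs))) {
      lab <- paste0(segs$src_chrom[k], ":",
                    seq(segs$src_start[k], segs$src_end[k] - 1L))
      if (segs$strand[k] == "-") lab <- rev(lab)
      v <- c(v, lab)
    }
    out[[ch]] <- v
  }
  out
}

# Per-base membership vector of an interval track on one chromosome.
per_base_mask <- function(track, chrom, len) {
  mask <- logical(len)
  tt <- track[track$chrom == chrom, , drop = FALSE]
  for (k in seq_len(nrow(tt))) {
    lo <- max(0L, tt$start[k]); hi <- min(len, tt$end[k])
    if (hi > lo) mask[(lo + 1L):hi] <- TRUE
  }
  mask
}

# Brute-force overlap base count for arbitrary query intervals.
brute_overlap_bases <- function(queries, track, chrom_len) {
  vapply(seq_len(nrow(queries)), function(k) {
    ch <- queries$chrom[k]
    mask <- per_base_mask(track, ch, chrom_len[[ch]])
    lo <- max(0L, queries$start[k]); hi <- min(chrom_len[[ch]], queries$end[k])
    if (hi <= lo) 0 else sum(mask[(lo + 1L):hi])
  }, numeric(1))
}

# Brute-force N50 by scanning candidate lengths.
brute_n50 <- function(lengths) {
  lengths <- lengths[lengths > 0]
  if (!length(lengths)) return(0)
  best <- 0
  for (L in sort(unique(lengths))) {
    if (sum(lengths[lengths >= L]) >= sum(lengths) / 2) best <- max(best, L)
  }
  best
}

# Brute-force physical coverage: count spanning fragments one by one.
brute_physical_coverage <- function(read_pairs, scaffold, positions) {
  p <- read_pairs[read_pairs$scaffold == scaffold, , drop = FALSE]
  vapply(positions, function(x) {
    n <- 0L
    for (k in seq_len(nrow(p))) {
      fs <- min(p$start1[k], p$start2[k]); fe <- max(p$end1[k], p$end2[k])
      if (fs < x && x < fe) n <- n + 1L
    }
    n
  }, integer(1))
}

# Brute-force threshold calibration: scan every integer threshold.
brute_calibrate <- function(conf, refu) {
  cand <- 0:(max(c(conf, refu)) + 1L)
  agree <- vapply(cand, function(c) sum(conf >= c) + sum(refu < c), numeric(1))
  cand[which(agree == max(agree))[1]]
}

# Independent exact two-sided Mann-Whitney permutation p via rank sums.
brute_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  r <- rank(pooled)
  u_from <- function(sel) sum(r[sel]) - n1 * (n1 + 1) / 2
  u_obs <- u_from(seq_len(n1))
  center <- n1 * (n - n1) / 2
  sels <- utils::combn(n, n1)
  us <- apply(sels, 2, u_from)
  mean(abs(us - center) >= abs(u_obs - center) - 1e-9)
}

# Brute-force nearest qualifying window distances on one chromosome given
# usable-window densities in chromosome order with their window indices.
brute_zero_distances <- function(idx, dens, high) {
  zero <- which(dens == 0)
  qual <- which(dens >= high)
  if (!length(qual)) return(rep(NA_real_, length(zero)))
  vapply(zero, function(i) min(abs(idx[i] - idx[qual])), numeric(1))
}

# A small rearranged genome with every simulator product, reused by tests.
small_sim <- function(seed = 7, n_chrom = 3, total_bp = 6e6,
                      n_inversions = 3, n_fissions = 1, n_fusions = 1, ...) {
  anc <- sim_ancestor(n_chrom, total_bp, seed = seed)
  plan <- random_plan(anc, n_inversions, n_fissions, n_fusions,
                      min_event_bp = 2e5, max_event_bp = 4e5,
                      seed = seed + 1)
  des <- apply_rearrangements(anc, plan)
  shred <- shred_to_scaffolds(des, mean_scaffold_bp = 4e5, seed = seed + 2, ...)
  list(anc = anc, plan = plan, des = des, shred = shred)
}
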