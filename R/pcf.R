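# Predicted chromosome fragment (PCF) construction and refinement.
#
# This is a deliberately simplified reimplementation of reference-assisted
# adjacency scoring: an intra-scaffold SF adjacency is retained iff its
# spanning physical coverage reaches the threshold OR reference and
# outgroup both support it; retained scaffold fragments are then chained
# along the reference into PCFs with a weighted indicator score. The
# probabilistic adjacency model of the original RACA algorithm is out of
# scope; the verification loop and threshold calibration are the point.

#' Physical coverage at positions of a scaffold
#'
#' The physical (fragment) coverage at position p is the number of read-pair
#' fragments — the full interval from the outer end of read 1 to the outer
#' end of read 2 — strictly containing p. Pairs whose ends map to different
#' scaffolds or in invalid orientation contribute nothing.
#'
#' @param read_pairs data.frame (`scaffold`, `start1`, `end1`, `start2`,
#'   `end2`, `orientation`).
#' @param scaffold scaffold id.
#' @param positions numeric vector of positions.
#' @param max_insert ignore pairs whose fragment exceeds this length.
#' @return integer vector of counts, one per position.
#' @export
physical_coverage <- function(read_pairs, scaffold, positions,
                              max_insert = Inf) {
  p <- read_pairs[read_pairs$scaffold == scaffold &
                    read_pairs$orientation == "FR", , drop = FALSE]
  if (!nrow(p)) return(integer(length(positions)))
  fs <- pmin(p$start1, p$start2)
  fe <- pmax(p$end1, p$end2)
  ok <- (fe - fs) <= max_insert
  fs <- fs[ok]; fe <- fe[ok]
  vapply(positions, function(x) sum(fs < x & x < fe), integer(1))
}

joint_coverage <- function(read_pairs, scaffold, gap_start, gap_end,
                           cov_mode = "min", max_insert = Inf) {
  if (cov_mode == "midpoint" || gap_end <= gap_start) {
    return(physical_coverage(read_pairs, scaffold,
                             floor((gap_start + gap_end) / 2), max_insert))
  }
  npt <- min(41, max(3, ceiling((gap_end - gap_start) / 500) + 1))
  pts <- unique(c(round(seq(gap_start, gap_end, length.out = npt)),
                  floor((gap_start + gap_end) / 2)))
  min(physical_coverage(read_pairs, scaffold, pts, max_insert))
}

# majority (by target length) value of `vals` weighted by `len`
wmode <- function(vals, len) {
  names(which.max(tapply(len, vals, sum)))
}

#' Build predicted chromosome fragments
#'
#' Two passes. (1) Intra-scaffold: each adjacency between consecutive SFs of
#' a scaffold is retained iff its spanning physical coverage is at least
#' `threshold_c` OR the adjacency agrees with both reference and outgroup
#' order; otherwise the scaffold is cut there and a SplitJoint is emitted.
#' (2) Inter-scaffold: the resulting scaffold fragments are ordered along
#' each reference chromosome and consecutive fragments are chained into a
#' PCF when the junction score `w_ref * I_ref + w_out * I_out` reaches
#' `join_min` (with default weights this requires reference and outgroup
#' agreement together). PCFs inherit reference orientation: a fragment
#' whose SFs align `-` enters its PCF reversed. Because chaining follows a
#' linear reference ordering, circular adjacency support cannot arise.
#'
#' @param sfs an `sf_set` of target scaffolds against the reference.
#' @param outgroup_sfs optional `sf_set`-like table of the same scaffolds
#'   against the outgroup genome.
#' @param read_pairs read-pair table (see [physical_coverage()]).
#' @param threshold_c physical-coverage retention threshold.
#' @param weights named vector `c(ref=, out=, read=)`.
#' @param join_min minimum junction score to chain two fragments.
#' @param cov_mode `"min"` (default: minimum physical coverage over the
#'   whole gap — a chimeric junction anywhere in a wide gap then shows its
#'   zero-coverage signature) or `"midpoint"` (value at the single gap
#'   midpoint).
#' @param max_insert passed to [physical_coverage()].
#' @return list with `pcfs` (a `pcf_set`: `pcf_id`, `member_index`,
#'   `scaffold`, `s_start`, `s_end`, `orientation`, `ref_chrom`,
#'   `r_start`, `r_end`) and `joints` (SplitJoint table: `scaffold`,
#'   `gap_start`, `gap_end`, `coverage`, `ref_agree`, `out_agree`,
#'   `status`, `testable`, plus flanking-SF columns used for narrowing).
#' @export
build_pcfs <- function(sfs, outgroup_sfs = NULL, read_pairs = NULL,
                       threshold_c = 5, weights = c(ref = 1, out = 1, read = 1),
                       join_min = 2, cov_mode = c("min", "midpoint"),
                       max_insert = Inf) {
  cov_mode <- match.arg(cov_mode)
  stopifnot(threshold_c >= 0)
  resolution <- attr(sfs, "resolution") %||% 150000
  sfs <- as.data.frame(sfs)
  sfs <- sfs[order(sfs$target_seq, sfs$t_start), , drop = FALSE]

  ref_adjacent <- function(L, R) {
    if (L$ref_chrom != R$ref_chrom || L$strand != R$strand) return(FALSE)
    gap <- if (L$strand == "+") R$r_start - L$r_end else L$r_start - R$r_end
    abs(gap) < resolution
  }
  out_lookup <- function(scaf, t0, t1) {
    if (is.null(outgroup_sfs)) return(NULL)
    o <- outgroup_sfs[outgroup_sfs$target_seq == scaf, , drop = FALSE]
    ov <- pmin(o$t_end, t1) - pmax(o$t_start, t0)
    if (!length(ov) || max(ov) <= 0) return(NULL)
    o[which.max(ov), , drop = FALSE]
  }
  out_agree <- function(scaf, L, R) {
    oL <- out_lookup(scaf, L$t_start, L$t_end)
    oR <- out_lookup(scaf, R$t_start, R$t_end)
    if (is.null(oL) || is.null(oR)) return(FALSE)
    if (oL$sf_id == oR$sf_id) return(TRUE)   # one outgroup SF spans the joint
    ref_adjacent(oL, oR)
  }

  joints <- list()
  frags <- list()
  for (scaf in unique(sfs$target_seq)) {
    s <- sfs[sfs$target_seq == scaf, , drop = FALSE]
    cut_after <- logical(max(nrow(s) - 1L, 0))
    for (k in seq_len(nrow(s) - 1L)) {
      L <- s[k, ]; R <- s[k + 1L, ]
      cov <- if (is.null(read_pairs)) 0 else
        joint_coverage(read_pairs, scaf, L$t_end, R$t_start, cov_mode, max_insert)
      ra <- ref_adjacent(L, R)
      oa <- out_agree(scaf, L, R)
      retained <- cov >= threshold_c || (ra && oa)
      if (!retained) {
        cut_after[k] <- TRUE
        joints[[length(joints) + 1L]] <- data.frame(
          scaffold = scaf, gap_start = L$t_end, gap_end = R$t_start,
          coverage = cov, ref_agree = ra, out_agree = oa,
          status = "untested",
          testable = (R$t_start - L$t_end) < 6000,
          left_ref_chrom = L$ref_chrom, left_strand = L$strand,
          right_ref_chrom = R$ref_chrom, right_strand = R$strand,
          stringsAsFactors = FALSE)
      }
    }
    grp <- cumsum(c(0L, as.integer(cut_after))) + 1L
    for (g in unique(grp)) {
      m <- s[grp == g, , drop = FALSE]
      len <- m$t_end - m$t_start
      rc <- wmode(m$ref_chrom, len)
      ori <- wmode(m$strand, len)
      on_rc <- m[m$ref_chrom == rc, , drop = FALSE]
      frags[[length(frags) + 1L]] <- data.frame(
        scaffold = scaf, s_start = min(m$t_start), s_end = max(m$t_end),
        ref_chrom = rc, r_start = min(on_rc$r_start),
        r_end = max(on_rc$r_end), orientation = ori,
        stringsAsFactors = FALSE)
    }
  }
  frags <- do.call(rbind, frags)
  rownames(frags) <- NULL

  # outgroup footprint per fragment, for inter-scaffold junction support
  if (!is.null(outgroup_sfs)) {
    ofoot <- lapply(seq_len(nrow(frags)), function(i) {
      o <- outgroup_sfs[outgroup_sfs$target_seq == frags$scaffold[i], , drop = FALSE]
      ov <- pmin(o$t_end, frags$s_end[i]) - pmax(o$t_start, frags$s_start[i])
      o <- o[ov > 0, , drop = FALSE]
      if (!nrow(o)) return(NULL)
      len <- o$t_end - o$t_start
      oc <- wmode(o$ref_chrom, len)
      o <- o[o$ref_chrom == oc, , drop = FALSE]
      list(chrom = oc, start = min(o$r_start), end = max(o$r_end))
    })
  } else ofoot <- vector("list", nrow(frags))

  # chain fragments along each reference chromosome
  frags$pcf <- NA_integer_
  pcf_counter <- 0L
  for (rc in unique(frags$ref_chrom)) {
    idx <- which(frags$ref_chrom == rc)
    idx <- idx[order(frags$r_start[idx])]
    pcf_counter <- pcf_counter + 1L
    frags$pcf[idx[1]] <- pcf_counter
    if (length(idx) > 1) for (k in 2:length(idx)) {
      i <- idx[k - 1]; j <- idx[k]
      i_ref <- as.integer(frags$scaffold[i] != frags$scaffold[j] &&
                            frags$r_start[j] >= frags$r_end[i] - resolution)
      i_out <- 0L
      fi <- ofoot[[i]]; fj <- ofoot[[j]]
      if (i_ref == 1L && !is.null(fi) && !is.null(fj) &&
          identical(fi$chrom, fj$chrom)) {
        lo <- min(fi$end, fj$end); hi <- max(fi$start, fj$start)
        between <- vapply(seq_len(nrow(frags)), function(q) {
          fq <- ofoot[[q]]
          !is.null(fq) && q != i && q != j && identical(fq$chrom, fi$chrom) &&
            fq$start >= lo && fq$end <= hi
        }, logical(1))
        overlap <- min(fi$end, fj$end) > max(fi$start, fj$start)
        i_out <- as.integer(!any(between) && !overlap)
      }
      score <- weights[["ref"]] * i_ref + weights[["out"]] * i_out
      if (score >= join_min) {
        frags$pcf[j] <- frags$pcf[i]
      } else {
        pcf_counter <- pcf_counter + 1L
        frags$pcf[j] <- pcf_counter
      }
    }
  }

  members <- list()
  for (p in sort(unique(frags$pcf))) {
    m <- frags[frags$pcf == p, , drop = FALSE]
    m <- m[order(m$r_start), , drop = FALSE]
    m$pcf_id <- sprintf("PCF_%03d", p)
    m$member_index <- seq_len(nrow(m))
    members[[length(members) + 1L]] <- m
  }
  pcfs <- do.call(rbind, members)
  pcfs <- pcfs[, c("pcf_id", "member_index", "scaffold", "s_start", "s_end",
                   "orientation", "ref_chrom", "r_start", "r_end")]
  rownames(pcfs) <- NULL
  class(pcfs) <- c("pcf_set", "data.frame")
  joints <- if (length(joints)) do.call(rbind, joints) else
    data.frame(scaffold = character(), gap_start = numeric(),
               gap_end = numeric(), coverage = numeric(),
               ref_agree = logical(), out_agree = logical(),
               status = character(), testable = logical(),
               left_ref_chrom = character(), left_strand = character(),
               right_ref_chrom = character(), right_strand = character())
  rownames(joints) <- NULL
  list(pcfs = pcfs, joints = joints)
}

#' @export
print.pcf_set <- function(x, ...) {
  lens <- pcf_lengths(x)
  cat(sprintf("PCF set: %d PCFs, %d members, total %.2f Mb, N50 %.2f Mb\n",
              length(lens), nrow(x), sum(lens) / 1e6, n50(lens) / 1e6))
  invisible(x)
}

#' Per-PCF lengths (sum of member intervals)
#' @param pcfs a `pcf_set`.
#' @return named numeric vector of lengths.
#' @export
pcf_lengths <- function(pcfs) {
  tapply(pcfs$s_end - pcfs$s_start, pcfs$pcf_id, sum)
}

#' Narrow split-joint gaps with fine alignment blocks
#'
#' Each joint's gap is narrowed to the interval between the innermost fine
#' blocks attributable to the two flanking SFs (same reference chromosome
#' and orientation as the flank). A joint is testable iff the narrowed gap
#' is shorter than `max_testable_bp` (default: amplifiable by PCR).
#'
#' @param joints SplitJoint table from [build_pcfs()].
#' @param fine_blocks alignment blocks at finer granularity than SF
#'   detection (`target_seq` = scaffold).
#' @param max_testable_bp testability cutoff on the narrowed gap (bp).
#' @return `joints` with `gap_start`, `gap_end` narrowed and `testable`
#'   updated; original bounds kept in `gap_start0`, `gap_end0`.
#' @export
find_split_joints <- function(joints, fine_blocks, max_testable_bp = 6000) {
  joints$gap_start0 <- joints$gap_start
  joints$gap_end0 <- joints$gap_end
  if (!nrow(joints)) return(joints)
  for (k in seq_len(nrow(joints))) {
    fb <- fine_blocks[fine_blocks$target_seq == joints$scaffold[k], , drop = FALSE]
    gs <- joints$gap_start[k]; ge <- joints$gap_end[k]
    left <- fb[fb$t_end > gs & fb$t_end <= ge &
                 fb$ref_chrom == joints$left_ref_chrom[k] &
                 fb$strand == joints$left_strand[k], , drop = FALSE]
    right <- fb[fb$t_start >= gs & fb$t_start < ge &
                  fb$ref_chrom == joints$right_ref_chrom[k] &
                  fb$strand == joints$right_strand[k], , drop = FALSE]
    new_s <- if (nrow(left)) max(gs, max(left$t_end)) else gs
    new_e <- if (nrow(right)) min(ge, min(right$t_start)) else ge
    if (new_e < new_s) new_e <- new_s
    joints$gap_start[k] <- new_s
    joints$gap_end[k] <- new_e
  }
  joints$testable <- (joints$gap_end - joints$gap_start) < max_testable_bp
  joints
}

#' Calibrate the physical-coverage threshold from verification outcomes
#'
#' Returns the smallest threshold c maximizing the agreement
#' `A(c) = #(confirmed with coverage >= c) + #(refuted with coverage < c)`,
#' i.e. the genome-wide minimum physical coverage most consistent with the
#' verification results. Ties break toward the smallest c. With only
#' confirmed joints the minimum confirmed coverage is returned (keeps all
#' confirmed); with only refuted joints, one above the maximum refuted
#' coverage.
#'
#' @param joints SplitJoint table with `status` and `coverage` filled
#'   (`alternative_confirmed` counts as refuted: the original order was
#'   wrong).
#' @return the calibrated threshold (numeric scalar).
#' @export
calibrate_threshold <- function(joints) {
  conf <- joints$coverage[joints$status == "confirmed"]
  refu <- joints$coverage[joints$status %in% c("refuted", "alternative_confirmed")]
  if (!length(conf) && !length(refu)) {
    stop("cannot calibrate: no joint has a verification outcome")
  }
  if (!length(refu)) return(min(conf))
  if (!length(conf)) return(max(refu) + 1)
  cand <- sort(unique(c(0, conf, refu, conf + 1, refu + 1)))
  agree <- vapply(cand, function(c) sum(conf >= c) + sum(refu < c), numeric(1))
  cand[which.max(agree)]   # which.max returns the first (smallest) maximum
}

reverse_pcf_members <- function(m) {
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m$orientation <- c("+" = "-", "-" = "+", "?" = "?")[m$orientation]
  m
}

#' Refine PCFs using verification outcomes and map conflicts
#'
#' Confirmed joints are welded permanently (the two flanking fragments are
#' rejoined, merging their PCFs); `alternative_confirmed` joints are
#' rejoined in the swapped fragment order suggested by the chaining
#' evidence; refuted joints stay split. PCFs listed in `map_conflicts`
#' (cytogenetic evidence of a mis-join) are split at their lowest-coverage
#' internal junction — cytogenetic evidence is terminal, so a map conflict
#' overrides a confirmed weld inside the same PCF.
#'
#' @param pcfs a `pcf_set`.
#' @param joints SplitJoint table with statuses.
#' @param map_conflicts character vector of conflicted PCF ids.
#' @return a refined `pcf_set` (ids renumbered).
#' @export
refine_pcfs <- function(pcfs, joints, map_conflicts = NULL) {
  plist <- split(as.data.frame(pcfs), pcfs$pcf_id)
  plist <- lapply(plist, function(m) m[order(m$member_index), , drop = FALSE])

  locate <- function(scaf, pos, side) {
    for (pid in names(plist)) {
      m <- plist[[pid]]
      hit <- if (side == "left") {
        which(m$scaffold == scaf & m$s_end == pos)
      } else {
        which(m$scaffold == scaf & m$s_start == pos)
      }
      if (length(hit)) return(list(pid = pid, row = hit[1]))
    }
    NULL
  }

  for (k in seq_len(nrow(joints))) {
    st <- joints$status[k]
    if (!st %in% c("confirmed", "alternative_confirmed", "refuted")) next
    L <- locate(joints$scaffold[k], joints$gap_start0[k] %||% joints$gap_start[k], "left")
    R <- locate(joints$scaffold[k], joints$gap_end0[k] %||% joints$gap_end[k], "right")
    if (st == "refuted") {
      # a refuted joint still inside one PCF (retained adjacency later
      # shown chimeric) splits that PCF between the flanking members
      if (!is.null(L) && !is.null(R) && L$pid == R$pid && R$row == L$row + 1L) {
        m <- plist[[L$pid]]
        plist[[paste0(L$pid, "a")]] <- m[seq_len(L$row), , drop = FALSE]
        plist[[paste0(L$pid, "b")]] <- m[(L$row + 1L):nrow(m), , drop = FALSE]
        plist[[L$pid]] <- NULL
      }
      next
    }
    if (is.null(L) || is.null(R)) {
      warning("joint ", k, ": flanking fragments not found; left split")
      next
    }
    if (L$pid == R$pid) {
      m <- plist[[L$pid]]
      if (abs(L$row - R$row) != 1L) next
      if (st == "confirmed" && R$row == L$row + 1L &&
          m$orientation[L$row] == m$orientation[R$row]) {
        m$s_end[L$row] <- m$s_end[R$row]
        m$r_end[L$row] <- max(m$r_end[L$row], m$r_end[R$row])
        m <- m[-R$row, , drop = FALSE]
      } else if (st == "alternative_confirmed" && R$row == L$row + 1L) {
        m[c(L$row, R$row), ] <- m[c(R$row, L$row), ]
      }
      plist[[L$pid]] <- m
      next
    }
    mL <- plist[[L$pid]]; mR <- plist[[R$pid]]
    if (L$row != nrow(mL)) mL <- reverse_pcf_members(mL)
    if (R$row != 1L) mR <- reverse_pcf_members(mR)
    ok_L <- mL$scaffold[nrow(mL)] == joints$scaffold[k]
    ok_R <- mR$scaffold[1] == joints$scaffold[k]
    if (!ok_L || !ok_R) {
      warning("joint ", k, ": fragments not terminal in their PCFs; left split")
      next
    }
    if (st == "confirmed") {
      if (mL$orientation[nrow(mL)] == mR$orientation[1]) {
        mL$s_end[nrow(mL)] <- mR$s_end[1]
        mL$r_end[nrow(mL)] <- max(mL$r_end[nrow(mL)], mR$r_end[1])
        mR <- mR[-1, , drop = FALSE]
      }
      merged <- rbind(mL, mR)
    } else {
      # alternative order: right fragment precedes left at the junction
      junction <- rbind(mR[1, , drop = FALSE], mL[nrow(mL), , drop = FALSE])
      merged <- rbind(mL[-nrow(mL), , drop = FALSE], junction,
                      mR[-1, , drop = FALSE])
    }
    plist[[L$pid]] <- merged
    plist[[R$pid]] <- NULL
  }

  # cytogenetic map conflicts: split at the lowest-coverage internal junction
  for (pid in intersect(map_conflicts %||% character(), names(plist))) {
    m <- plist[[pid]]
    if (nrow(m) < 2) next
    jc <- vapply(seq_len(nrow(m) - 1L), function(i) {
      same <- m$scaffold[i] == m$scaffold[i + 1L]
      if (!same) return(0)
      hit <- joints$scaffold == m$scaffold[i] &
        joints$gap_start <= m$s_end[i] & joints$gap_end >= m$s_end[i]
      if (any(hit)) min(joints$coverage[hit]) else 0
    }, numeric(1))
    cut <- which.min(jc)
    message("map conflict: splitting ", pid, " after member ", cut)
    plist[[paste0(pid, "a")]] <- m[seq_len(cut), , drop = FALSE]
    plist[[paste0(pid, "b")]] <- m[(cut + 1L):nrow(m), , drop = FALSE]
    plist[[pid]] <- NULL
  }

  out <- do.call(rbind, lapply(seq_along(plist), function(i) {
    m <- plist[[order(names(plist))[i]]]
    m$pcf_id <- sprintf("PCF_%03d", i)
    m$member_index <- seq_len(nrow(m))
    m
  }))
  rownames(out) <- NULL
  class(out) <- c("pcf_set", "data.frame")
  out
}

#' Assembly summary statistics
#'
#' @param x a `pcf_set` or a numeric vector of member lengths.
#' @param input_total_bp optional total length of the input scaffold
#'   assembly, for `pct_of_input`.
#' @param n_scaffolds,n_sfs optional counts for the SF-per-scaffold
#'   structural accuracy ratio, reported as `n_scaffolds / n_sfs`.
#' @return list with `count`, `n50`, `total_bp`, `pct_of_input`,
#'   `sf_scaffold_ratio`.
#' @export
assembly_stats <- function(x, input_total_bp = NULL, n_scaffolds = NULL,
                           n_sfs = NULL) {
  lens <- if (inherits(x, "pcf_set")) as.numeric(pcf_lengths(x)) else as.numeric(x)
  lens <- lens[!is.na(lens)]
  list(
    count = length(lens),
    n50 = n50(lens),
    total_bp = sum(lens),
    pct_of_input = if (is.null(input_total_bp)) NA_real_ else
      100 * sum(lens) / input_total_bp,
    sf_scaffold_ratio = if (is.null(n_scaffolds) || is.null(n_sfs)) NA_real_ else
      n_scaffolds / n_sfs
  )
}

#' Write a PCF set as AGP v2.1
#'
#' @param pcfs a `pcf_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
pcfs_to_agp <- function(pcfs, path) {
  write_agp(data.frame(object = pcfs$pcf_id, component_id = pcfs$scaffold,
                       component_beg = pcfs$s_start, component_end = pcfs$s_end,
                       orientation = pcfs$orientation), path)
}
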