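# Karyotype rearrangement simulator with complete ground truth.
#
# Coordinates are 0-based half-open throughout. The ancestor plays the role
# of the chromosome-level reference genome (the ancestral proxy); descendant
# chromosomes are ordered lists of ancestor segments with orientation, so
# every downstream stage can be checked against exact truth.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Construct an ancestor genome
#'
#' The ancestor stands in for the chromosome-level reference used as the
#' ancestral proxy. Multispecies homologous synteny blocks (msHSBs) are
#' designated high-CNE regions; rearrangement breakpoints are planted away
#' from them by the plan generator.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param mshsb data.frame (`chrom`, `start`, `end`) of msHSB intervals;
#'   must lie within chromosome bounds and not overlap.
#' @return an `ancestor_genome` object.
#' @export
ancestor_genome <- function(chrom_lengths, mshsb) {
  stopifnot(length(chrom_lengths) > 0, !is.null(names(chrom_lengths)),
            all(chrom_lengths > 0))
  iv_check(mshsb, "mshsb")
  bad <- mshsb$start < 0 | mshsb$end > chrom_lengths[as.character(mshsb$chrom)]
  if (any(bad | is.na(bad))) stop("msHSB interval outside chromosome bounds")
  merged <- iv_merge(mshsb)
  if (nrow(merged) != nrow(mshsb)) stop("msHSB intervals overlap")
  structure(list(chrom_lengths = chrom_lengths,
                 mshsb = mshsb[order(mshsb$chrom, mshsb$start), , drop = FALSE]),
            class = "ancestor_genome")
}

#' Simulate a small avian-like ancestor
#'
#' Chromosome lengths decrease geometrically (macro- to microchromosome
#' spread); each chromosome carries one central msHSB covering
#' `mshsb_frac` of its length (jittered), so the larger chromosomes carry
#' msHSBs exceeding the 1.5 Mb analysis cutoff.
#'
#' @param n_chrom number of chromosomes.
#' @param total_bp total genome size in bp.
#' @param mshsb_frac fraction of each chromosome inside its msHSB.
#' @param seed integer seed.
#' @return an `ancestor_genome`.
#' @export
sim_ancestor <- function(n_chrom = 5, total_bp = 20e6, mshsb_frac = 0.3,
                         seed = NULL) {
  with_seed(seed, {
    w <- 0.65^(seq_len(n_chrom) - 1)
    len <- round(total_bp * w / sum(w))
    names(len) <- paste0("anc", seq_len(n_chrom))
    ms <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
      L <- len[i]
      width <- round(mshsb_frac * L)
      s <- round((L - width) * stats::runif(1, 0.35, 0.65))
      data.frame(chrom = names(len)[i], start = s, end = s + width)
    }))
    ancestor_genome(len, ms)
  })
}

# --- rearrangement plans -----------------------------------------------------

#' Rearrangement operations
#'
#' Constructors for the four operation kinds a plan may contain. Inversion
#' coordinates and fission positions are descendant coordinates valid at the
#' time the operation is applied; fusion joins the chosen ends of two
#' current chromosomes (flipping as needed so the chosen ends meet).
#'
#' @param chrom,chrom_a,chrom_b chromosome names valid at application time.
#' @param start,end,pos,pos_a,pos_b positions (bp).
#' @param end_a,end_b which end of each chromosome to join
#'   (`"start"`/`"end"`).
#' @return an operation descriptor (plain list).
#' @name rearrangement_ops
NULL

#' @rdname rearrangement_ops
#' @export
op_inversion <- function(chrom, start, end) {
  list(type = "inversion", chrom = chrom, start = start, end = end)
}

#' @rdname rearrangement_ops
#' @export
op_fission <- function(chrom, pos) list(type = "fission", chrom = chrom, pos = pos)

#' @rdname rearrangement_ops
#' @export
op_fusion <- function(chrom_a, end_a, chrom_b, end_b) {
  stopifnot(end_a %in% c("start", "end"), end_b %in% c("start", "end"))
  list(type = "fusion", chrom_a = chrom_a, end_a = end_a,
       chrom_b = chrom_b, end_b = end_b)
}

#' @rdname rearrangement_ops
#' @export
op_translocation <- function(chrom_a, pos_a, chrom_b, pos_b) {
  list(type = "translocation", chrom_a = chrom_a, pos_a = pos_a,
       chrom_b = chrom_b, pos_b = pos_b)
}

#' Build a rearrangement plan
#'
#' A plan is an ordered list of operations; each coordinate must be valid at
#' the time its operation is applied. Use the `op_*` helpers
#' ([op_inversion()], [op_fission()], [op_fusion()], [op_translocation()])
#' or [random_plan()].
#'
#' @param ops list of operation descriptors.
#' @return a `rearrangement_plan`.
#' @export
rearrangement_plan <- function(ops = list()) {
  stopifnot(is.list(ops))
  structure(list(ops = ops), class = "rearrangement_plan")
}

#' Sample a random rearrangement plan
#'
#' Inversions are planted first (non-overlapping, away from chromosome ends
#' and msHSBs), then at most one fission per original chromosome, then
#' fusions chaining the current chromosomes end-to-end. Keeping breakpoints
#' clear of msHSBs mirrors the empirical depletion of breakpoints in regions
#' of conserved synteny and keeps the planted CNE structure interpretable.
#'
#' @param ancestor an `ancestor_genome`.
#' @param n_inversions,n_fissions,n_fusions event counts.
#' @param min_event_bp,max_event_bp inversion size range.
#' @param margin_bp keep breakpoints this far from chromosome ends.
#' @param min_separation_bp minimum distance between planted breakpoints.
#' @param mshsb_buffer_bp keep breakpoints this far from msHSB intervals.
#' @param seed integer seed.
#' @return a `rearrangement_plan`.
#' @export
random_plan <- function(ancestor, n_inversions = 10, n_fissions = 2,
                        n_fusions = 3, min_event_bp = 3e5, max_event_bp = 8e5,
                        margin_bp = 2e5, min_separation_bp = 2e5,
                        mshsb_buffer_bp = 5e4, seed = NULL) {
  stopifnot(inherits(ancestor, "ancestor_genome"))
  with_seed(seed, {
    len <- ancestor$chrom_lengths
    # per-chromosome list of forbidden breakpoint positions
    avoid <- lapply(names(len), function(ch) {
      ms <- ancestor$mshsb[ancestor$mshsb$chrom == ch, , drop = FALSE]
      if (!nrow(ms)) return(ms[, c("start", "end")])
      data.frame(start = ms$start - mshsb_buffer_bp, end = ms$end + mshsb_buffer_bp)
    })
    names(avoid) <- names(len)
    ok_pos <- function(ch, p) {
      a <- avoid[[ch]]
      p >= margin_bp && p <= len[ch] - margin_bp &&
        (!nrow(a) || all(p < a$start | p > a$end))
    }
    block <- function(ch, s, e) {
      avoid[[ch]] <<- rbind(avoid[[ch]],
                            data.frame(start = s - min_separation_bp,
                                       end = e + min_separation_bp))
    }
    ops <- list()
    for (i in seq_len(n_inversions)) {
      placed <- FALSE
      for (try in 1:500) {
        ch <- sample(names(len), 1, prob = len)
        w <- round(stats::runif(1, min_event_bp, max_event_bp))
        if (len[ch] < w + 2 * margin_bp) next
        s <- round(stats::runif(1, margin_bp, len[ch] - margin_bp - w))
        if (ok_pos(ch, s) && ok_pos(ch, s + w)) {
          ops[[length(ops) + 1L]] <- op_inversion(ch, s, s + w)
          block(ch, s, s + w)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place inversion ", i, "; relax constraints")
    }
    # fission positions are drawn on the original chromosomes, then
    # converted to sequential cuts (each acting on the right-hand product
    # of the previous cut, in ascending position order)
    fis_pos <- list()
    for (i in seq_len(n_fissions)) {
      placed <- FALSE
      for (try in 1:500) {
        ch <- sample(names(len), 1, prob = len)
        if (len[ch] < 2 * margin_bp + min_separation_bp) next
        p <- round(stats::runif(1, margin_bp, len[ch] - margin_bp))
        if (ok_pos(ch, p)) {
          fis_pos[[length(fis_pos) + 1L]] <- list(chrom = ch, pos = p)
          block(ch, p, p)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place fission ", i, "; relax constraints")
    }
    current <- names(len)
    for (ch in unique(vapply(fis_pos, `[[`, character(1), "chrom"))) {
      pos <- sort(vapply(Filter(function(f) f$chrom == ch, fis_pos),
                         `[[`, numeric(1), "pos"))
      cur <- ch; base <- 0
      for (p in pos) {
        ops[[length(ops) + 1L]] <- op_fission(cur, p - base)
        current <- c(setdiff(current, cur), paste0(cur, ".1"))
        cur <- paste0(cur, ".2"); base <- p
      }
      current <- c(current, cur)
    }
    # never fuse two chromosomes sharing an ancestor root: rejoining pieces
    # of one reference chromosome is not an interchromosomal event relative
    # to the reference, which would blur the planted event counts
    roots <- function(nm) {
      unique(sub("\\.[0-9.]+$", "", strsplit(nm, "+", fixed = TRUE)[[1]]))
    }
    for (i in seq_len(n_fusions)) {
      if (length(current) < 2) stop("not enough chromosomes left to fuse")
      pair <- NULL
      for (try in 1:500) {
        cand <- sample(current, 2)
        if (!length(intersect(roots(cand[1]), roots(cand[2])))) {
          pair <- cand
          break
        }
      }
      if (is.null(pair)) stop("could not place fusion ", i, " without reusing an ancestor root")
      ea <- sample(c("start", "end"), 1)
      eb <- sample(c("start", "end"), 1)
      ops[[length(ops) + 1L]] <- op_fusion(pair[1], ea, pair[2], eb)
      current <- c(setdiff(current, pair), paste0(pair[1], "+", pair[2]))
    }
    rearrangement_plan(ops)
  })
}

# --- applying plans ----------------------------------------------------------

seg_lengths <- function(segs) segs$src_end - segs$src_start

# Split a segment list at descendant coordinate `pos` (0 < pos < length).
split_segments <- function(segs, pos) {
  lens <- seg_lengths(segs)
  cum <- cumsum(lens)
  total <- cum[length(cum)]
  stopifnot(pos > 0, pos < total)
  i <- which(cum >= pos)[1]
  off <- pos - (cum[i] - lens[i])   # offset into segment i
  if (off == 0) {
    return(list(left = segs[seq_len(i - 1L), , drop = FALSE],
                right = segs[i:nrow(segs), , drop = FALSE]))
  }
  s <- segs[i, ]
  if (s$strand == "+") {
    a <- s; a$src_end <- s$src_start + off
    b <- s; b$src_start <- s$src_start + off
  } else {
    a <- s; a$src_start <- s$src_end - off
    b <- s; b$src_end <- s$src_end - off
  }
  list(left = rbind(segs[seq_len(i - 1L), , drop = FALSE], a),
       right = rbind(b, segs[seq(i + 1L, length.out = nrow(segs) - i), , drop = FALSE]))
}

flip_segments <- function(segs) {
  segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  segs$strand <- ifelse(segs$strand == "+", "-", "+")
  segs
}

# Ancestor (chrom, pos) underlying descendant boundary position `pos`.
ancestor_pos_at <- function(segs, pos) {
  lens <- seg_lengths(segs)
  cum <- cumsum(lens)
  if (pos >= cum[length(cum)]) {
    s <- segs[nrow(segs), ]
    return(list(chrom = s$src_chrom,
                pos = if (s$strand == "+") s$src_end else s$src_start))
  }
  i <- which(cum > pos)[1]
  off <- pos - (cum[i] - lens[i])
  s <- segs[i, ]
  list(chrom = s$src_chrom,
       pos = if (s$strand == "+") s$src_start + off else s$src_end - off)
}

#' Apply a rearrangement plan to an ancestor genome
#'
#' Replays the plan deterministically, maintaining each descendant
#' chromosome as an ordered list of oriented ancestor segments, and records
#' a complete truth set: the descendant karyotype (segment tiling of the
#' ancestor) and one record per planted breakpoint with its type.
#' Intrachromosomal events (inversions) produce two breakpoint records
#' sharing an event id; fission breaks are recorded in ancestor coordinates
#' and fusion junctions in the coordinates of the descendant chromosome
#' created by the join (with the two ancestor-side flanks).
#'
#' @param ancestor an `ancestor_genome`.
#' @param plan a `rearrangement_plan`.
#' @return list with `karyotype` (data.frame: `der_chrom`, `der_start`,
#'   `der_end`, `src_chrom`, `src_start`, `src_end`, `strand`),
#'   `chrom_lengths` (named vector of descendant lengths) and `ebrs`
#'   (truth breakpoint table: `event`, `op`, `type`, `der_chrom`, `der_pos`,
#'   `ref_chrom`, `ref_pos`, `ref_chrom2`, `ref_pos2`).
#' @export
apply_rearrangements <- function(ancestor, plan) {
  stopifnot(inherits(ancestor, "ancestor_genome"),
            inherits(plan, "rearrangement_plan"))
  state <- lapply(names(ancestor$chrom_lengths), function(ch) {
    data.frame(src_chrom = ch, src_start = 0,
               src_end = unname(ancestor$chrom_lengths[ch]), strand = "+",
               stringsAsFactors = FALSE)
  })
  names(state) <- names(ancestor$chrom_lengths)
  ebrs <- list()
  event <- 0L
  rec <- function(op, type, der_chrom = NA, der_pos = NA, ref_chrom = NA,
                  ref_pos = NA, ref_chrom2 = NA, ref_pos2 = NA) {
    ebrs[[length(ebrs) + 1L]] <<- data.frame(
      event = event, op = op, type = type, der_chrom = der_chrom,
      der_pos = der_pos, ref_chrom = ref_chrom, ref_pos = ref_pos,
      ref_chrom2 = ref_chrom2, ref_pos2 = ref_pos2, stringsAsFactors = FALSE)
  }
  die <- function(i, msg) stop(sprintf("op %d rejected: %s", i, msg))
  for (i in seq_along(plan$ops)) {
    op <- plan$ops[[i]]
    if (op$type == "inversion") {
      if (!op$chrom %in% names(state)) die(i, paste("unknown chromosome", op$chrom))
      segs <- state[[op$chrom]]
      total <- sum(seg_lengths(segs))
      if (!(op$start > 0 && op$end < total && op$start < op$end)) {
        die(i, "inversion interval outside chromosome")
      }
      event <- event + 1L
      a1 <- ancestor_pos_at(segs, op$start)
      a2 <- ancestor_pos_at(segs, op$end)
      rec(i, "intra", op$chrom, op$start, a1$chrom, a1$pos)
      rec(i, "intra", op$chrom, op$end, a2$chrom, a2$pos)
      sp1 <- split_segments(segs, op$start)
      sp2 <- split_segments(sp1$right, op$end - op$start)
      state[[op$chrom]] <- rbind(sp1$left, flip_segments(sp2$left), sp2$right)
    } else if (op$type == "fission") {
      if (!op$chrom %in% names(state)) die(i, paste("unknown chromosome", op$chrom))
      segs <- state[[op$chrom]]
      total <- sum(seg_lengths(segs))
      if (!(op$pos > 0 && op$pos < total)) die(i, "fission position outside chromosome")
      event <- event + 1L
      a <- ancestor_pos_at(segs, op$pos)
      rec(i, "fission", op$chrom, op$pos, a$chrom, a$pos)
      sp <- split_segments(segs, op$pos)
      nm <- paste0(op$chrom, c(".1", ".2"))
      state[[op$chrom]] <- NULL
      state[[nm[1]]] <- sp$left
      state[[nm[2]]] <- sp$right
    } else if (op$type == "fusion") {
      for (ch in c(op$chrom_a, op$chrom_b)) {
        if (!ch %in% names(state)) die(i, paste("unknown chromosome", ch))
      }
      if (op$chrom_a == op$chrom_b) die(i, "cannot fuse a chromosome to itself")
      a <- state[[op$chrom_a]]
      b <- state[[op$chrom_b]]
      if (op$end_a == "start") a <- flip_segments(a)
      if (op$end_b == "end") b <- flip_segments(b)
      len_a <- sum(seg_lengths(a))
      event <- event + 1L
      fa <- ancestor_pos_at(a, len_a)           # right edge of A side
      fb <- ancestor_pos_at(b, 0)               # left edge of B side
      nm <- paste0(op$chrom_a, "+", op$chrom_b)
      rec(i, "fusion", nm, len_a, fa$chrom, fa$pos, fb$chrom, fb$pos)
      state[[op$chrom_a]] <- NULL
      state[[op$chrom_b]] <- NULL
      state[[nm]] <- rbind(a, b)
    } else if (op$type == "translocation") {
      for (ch in c(op$chrom_a, op$chrom_b)) {
        if (!ch %in% names(state)) die(i, paste("unknown chromosome", ch))
      }
      a <- state[[op$chrom_a]]; b <- state[[op$chrom_b]]
      la <- sum(seg_lengths(a)); lb <- sum(seg_lengths(b))
      if (!(op$pos_a > 0 && op$pos_a < la)) die(i, "pos_a outside chromosome")
      if (!(op$pos_b > 0 && op$pos_b < lb)) die(i, "pos_b outside chromosome")
      event <- event + 1L
      pa <- ancestor_pos_at(a, op$pos_a); pb <- ancestor_pos_at(b, op$pos_b)
      rec(i, "translocation", op$chrom_a, op$pos_a, pa$chrom, pa$pos,
          pb$chrom, pb$pos)
      sa <- split_segments(a, op$pos_a); sb <- split_segments(b, op$pos_b)
      state[[op$chrom_a]] <- rbind(sa$left, sb$right)
      state[[op$chrom_b]] <- rbind(sb$left, sa$right)
    } else {
      die(i, paste("unknown op type", op$type))
    }
  }
  kar <- do.call(rbind, lapply(names(state), function(ch) {
    segs <- state[[ch]]
    lens <- seg_lengths(segs)
    data.frame(der_chrom = ch, der_start = cumsum(lens) - lens,
               der_end = cumsum(lens), src_chrom = segs$src_chrom,
               src_start = segs$src_start, src_end = segs$src_end,
               strand = segs$strand, stringsAsFactors = FALSE)
  }))
  rownames(kar) <- NULL
  # conservation invariant: segments tile the ancestor exactly once
  tiled <- iv_merge(data.frame(chrom = kar$src_chrom, start = kar$src_start,
                               end = kar$src_end))
  anc <- data.frame(chrom = names(ancestor$chrom_lengths), start = 0,
                    end = unname(ancestor$chrom_lengths))
  anc <- anc[order(anc$chrom), ]
  if (!isTRUE(all.equal(sum(tiled$end - tiled$start), sum(anc$end))) ||
      nrow(tiled) != nrow(anc)) {
    stop("internal error: descendant segments do not tile the ancestor")
  }
  ebrs <- if (length(ebrs)) do.call(rbind, ebrs) else
    data.frame(event = integer(), op = integer(), type = character(),
               der_chrom = character(), der_pos = numeric(),
               ref_chrom = character(), ref_pos = numeric(),
               ref_chrom2 = character(), ref_pos2 = numeric())
  list(karyotype = kar,
       chrom_lengths = vapply(state, function(s) sum(seg_lengths(s)), numeric(1)),
       ebrs = ebrs)
}

# --- scaffolds, chimeras, read pairs ----------------------------------------

#' Shred a descendant genome into scaffolds with chimeras and read pairs
#'
#' Descendant chromosomes are cut into pieces with roughly exponential
#' lengths; scaffolds are single pieces or, with probability
#' `chimera_rate`, concatenations of two non-adjacent pieces (a planted
#' chimeric joint). Read pairs emulate a long-insert library: pairs are
#' placed uniformly within each scaffold, then pairs spanning a chimeric
#' joint are removed entirely with probability `p_chim_zero` (the joined
#' molecule never existed) or thinned to half rate otherwise.
#'
#' @param descendant result of [apply_rearrangements()].
#' @param mean_scaffold_bp,min_scaffold_bp scaffold piece length model.
#' @param chimera_rate probability a scaffold is a two-piece chimera.
#' @param coverage list: `n_pairs` (genome total; default targets ~15x
#'   physical coverage), `insert_mean`, `insert_sd`, `read_len`.
#' @param p_chim_zero probability a chimeric joint has zero spanning pairs.
#' @param p_reverse probability a piece enters its scaffold reversed.
#' @param seed integer seed.
#' @return list with `scaffolds` (id, length), `scaffold_map` (scaffold
#'   fragment to descendant interval, with strand), `read_pairs`
#'   (scaffold, start1, end1, start2, end2, orientation) and `joints`
#'   (planted chimeric joints: scaffold, pos, zeroed).
#' @export
shred_to_scaffolds <- function(descendant, mean_scaffold_bp = 5e5,
                               min_scaffold_bp = 5e4, chimera_rate = 0.05,
                               coverage = list(), p_chim_zero = 0.9,
                               p_reverse = 0.25, seed = NULL) {
  stopifnot(chimera_rate >= 0, chimera_rate <= 1)
  cov <- utils::modifyList(list(n_pairs = NULL, insert_mean = 3000,
                                insert_sd = 300, read_len = 100), coverage)
  stopifnot(cov$insert_mean > 0)
  if (mean_scaffold_bp < cov$insert_mean) {
    warning("mean scaffold length below insert size: coverage calibration unreliable")
  }
  lens <- descendant$chrom_lengths
  genome <- sum(lens)
  if (is.null(cov$n_pairs)) cov$n_pairs <- round(15 * genome / cov$insert_mean)
  with_seed(seed, {
    pieces <- list()
    for (ch in names(lens)) {
      pos <- 0
      while (pos < lens[ch]) {
        w <- max(min_scaffold_bp, round(stats::rexp(1, 1 / mean_scaffold_bp)))
        if (lens[ch] - (pos + w) < min_scaffold_bp) w <- lens[ch] - pos
        pieces[[length(pieces) + 1L]] <- data.frame(
          der_chrom = ch, der_start = pos, der_end = pos + w)
        pos <- pos + w
      }
    }
    pieces <- do.call(rbind, pieces)
    pieces <- pieces[sample.int(nrow(pieces)), , drop = FALSE]
    # ancestor coordinates of both ends of each piece: a planted chimera
    # must not join pieces that are ancestrally near-adjacent, because such
    # a join is supported by comparative evidence and is not a detectable
    # mis-join (it reconstitutes the ancestral configuration)
    kar <- descendant$karyotype
    anc_of <- function(chrom, pos) {
      sg <- kar[kar$der_chrom == chrom & kar$der_start <= pos &
                  kar$der_end >= pos, , drop = FALSE]
      sg <- sg[1, ]
      p <- if (sg$strand == "+") sg$src_start + (pos - sg$der_start)
           else sg$src_end - (pos - sg$der_start)
      c(chrom = sg$src_chrom, pos = p)
    }
    # must exceed the synteny resolution downstream tools use, otherwise a
    # planted "chimera" can reconstitute an adjacency that comparative
    # evidence legitimately supports
    guard_bp <- 2.5e5
    adjacent <- function(p, q) {
      if (p$der_chrom == q$der_chrom &&
          (p$der_end == q$der_start || q$der_end == p$der_start)) {
        return(TRUE)
      }
      ends_p <- list(anc_of(p$der_chrom, p$der_start), anc_of(p$der_chrom, p$der_end))
      ends_q <- list(anc_of(q$der_chrom, q$der_start), anc_of(q$der_chrom, q$der_end))
      for (a in ends_p) for (b in ends_q) {
        if (identical(a[["chrom"]], b[["chrom"]]) &&
            abs(as.numeric(a[["pos"]]) - as.numeric(b[["pos"]])) < guard_bp) {
          return(TRUE)
        }
      }
      FALSE
    }
    map <- list(); joints <- list(); scaf_id <- 0L; i <- 1L
    while (i <= nrow(pieces)) {
      scaf_id <- scaf_id + 1L
      sid <- sprintf("scaffold_%03d", scaf_id)
      chim <- stats::runif(1) < chimera_rate && i < nrow(pieces)
      if (chim) {
        j <- i + 1L
        # avoid pairing pieces that are truly adjacent (that join is real)
        if (adjacent(pieces[i, ], pieces[j, ])) {
          alt <- which(seq_len(nrow(pieces)) > j &
                         !vapply(seq_len(nrow(pieces)),
                                 function(k) k <= j || adjacent(pieces[i, ], pieces[k, ]),
                                 logical(1)))
          if (length(alt)) {
            k <- alt[1]
            tmp <- pieces[j, ]; pieces[j, ] <- pieces[k, ]; pieces[k, ] <- tmp
          } else chim <- FALSE
        }
      }
      take <- if (chim) pieces[c(i, i + 1L), , drop = FALSE] else pieces[i, , drop = FALSE]
      i <- i + nrow(take)
      offs <- cumsum(take$der_end - take$der_start)
      take$scaffold <- sid
      take$frag <- seq_len(nrow(take))
      take$scaf_start <- offs - (take$der_end - take$der_start)
      take$scaf_end <- offs
      take$strand <- ifelse(stats::runif(nrow(take)) < p_reverse, "-", "+")
      map[[length(map) + 1L]] <- take
      if (nrow(take) == 2L) {
        joints[[length(joints) + 1L]] <- data.frame(
          scaffold = sid, pos = take$scaf_end[1], stringsAsFactors = FALSE)
      }
    }
    map <- do.call(rbind, map)
    rownames(map) <- NULL
    scaffolds <- stats::aggregate(list(length = map$scaf_end), list(scaffold = map$scaffold), max)
    # read pairs
    n_by_scaf <- stats::rmultinom(1, cov$n_pairs,
                                  prob = scaffolds$length / sum(scaffolds$length))[, 1]
    pair_list <- vector("list", nrow(scaffolds))
    for (s in seq_len(nrow(scaffolds))) {
      n <- n_by_scaf[s]
      if (n == 0) next
      L <- scaffolds$length[s]
      fl <- pmin(pmax(round(stats::rnorm(n, cov$insert_mean, cov$insert_sd)),
                      2 * cov$read_len), L)
      st <- floor(stats::runif(n, 0, L - fl + 1))
      pair_list[[s]] <- data.frame(
        scaffold = scaffolds$scaffold[s],
        start1 = st, end1 = st + cov$read_len,
        start2 = st + fl - cov$read_len, end2 = st + fl,
        orientation = "FR", stringsAsFactors = FALSE)
    }
    pairs <- do.call(rbind, pair_list)
    joints <- if (length(joints)) do.call(rbind, joints) else
      data.frame(scaffold = character(), pos = numeric())
    joints$zeroed <- logical(nrow(joints))
    if (nrow(joints)) {
      drop <- rep(FALSE, nrow(pairs))
      for (k in seq_len(nrow(joints))) {
        span <- pairs$scaffold == joints$scaffold[k] &
          pairs$start1 < joints$pos[k] & pairs$end2 > joints$pos[k]
        if (stats::runif(1) < p_chim_zero) {
          joints$zeroed[k] <- TRUE
          drop <- drop | span
        } else {
          drop <- drop | (span & stats::runif(nrow(pairs)) < 0.5)
        }
      }
      pairs <- pairs[!drop, , drop = FALSE]
    }
    rownames(pairs) <- NULL
    list(scaffolds = scaffolds, scaffold_map = map, read_pairs = pairs,
         joints = joints)
  })
}

# --- feature tracks ----------------------------------------------------------

# Non-overlapping elements by an alternating renewal process: element
# lengths are geometric around `len_mean`, gaps exponential with mean set so
# the expected covered fraction equals `density`.
sample_elements <- function(chrom, start, end, density, len_mean, len_min = 10) {
  if (density <= 0 || end <= start) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  gap_mean <- len_mean * (1 - density) / density
  out_s <- numeric(0); out_e <- numeric(0)
  pos <- start + stats::rexp(1, 1 / gap_mean)
  while (pos < end) {
    len <- len_min + stats::rgeom(1, 1 / max(len_mean - len_min, 1))
    e <- min(pos + len, end)
    out_s <- c(out_s, pos); out_e <- c(out_e, e)
    pos <- e + stats::rexp(1, 1 / gap_mean)
  }
  if (!length(out_s)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  data.frame(chrom = chrom, start = round(out_s), end = round(out_e))
}

#' Simulate CNE, conserved-element and TE tracks on the reference
#'
#' CNE density is high inside msHSB intervals and low elsewhere; planted
#' breakpoints carve CNE "deserts" (intervals guaranteed free of CNE bases)
#' whose half-width depends on the breakpoint type, so the simulated genome
#' reproduces the qualitative structure in which fission sites sit in the
#' widest deserts, fusions in intermediate ones, and intrachromosomal
#' breakpoints in the narrowest. The conserved-element (CE) track is a
#' superset of the CNE track with additional longer elements; the TE track
#' carries per-family elements, with one family enriched around
#' intrachromosomal breakpoints.
#'
#' @param ancestor an `ancestor_genome`.
#' @param ebrs truth breakpoint table from [apply_rearrangements()].
#' @param cne_density_mshsb,cne_density_background CNE base fractions.
#' @param desert_halfwidth_bp named vector `c(intra=, fusion=, fission=)`
#'   of desert half-widths; a single unnamed value applies to fissions only.
#' @param cne_len_mean mean CNE element length (bp).
#' @param te_params list: `families`, `density` (per family), `len_mean`
#'   (per family), `enrich_family`, `enrich_factor`, `enrich_halfwidth`.
#' @param seed integer seed.
#' @return list of tracks (`cne`, `ce`, `te`, `deserts`), all in ancestor
#'   (reference) coordinates; `te` carries the family in `name`.
#' @export
simulate_feature_tracks <- function(ancestor, ebrs,
                                    cne_density_mshsb = 0.11,
                                    cne_density_background = 0.02,
                                    desert_halfwidth_bp = c(intra = 19000,
                                                            fusion = 23000,
                                                            fission = 35000),
                                    cne_len_mean = 80,
                                    te_params = list(), seed = NULL) {
  stopifnot(cne_density_mshsb >= 0, cne_density_mshsb <= 1,
            cne_density_background >= 0, cne_density_background <= 1,
            all(desert_halfwidth_bp >= 0))
  if (is.null(names(desert_halfwidth_bp))) {
    stopifnot(length(desert_halfwidth_bp) == 1)
    desert_halfwidth_bp <- c(intra = 0, fusion = 0,
                             fission = unname(desert_halfwidth_bp))
  }
  tp <- utils::modifyList(list(
    families = c("LTR-ERV1", "CR1", "SINE"),
    density = c(0.02, 0.04, 0.01),
    len_mean = c(350, 500, 150),
    enrich_family = "LTR-ERV1", enrich_factor = 2,
    enrich_halfwidth = 20000), te_params)
  lens <- ancestor$chrom_lengths
  with_seed(seed, {
    cne <- list(); ce_extra <- list()
    for (ch in names(lens)) {
      ms <- ancestor$mshsb[ancestor$mshsb$chrom == ch, , drop = FALSE]
      bg <- iv_subtract(data.frame(chrom = ch, start = 0, end = unname(lens[ch])), ms)
      for (k in seq_len(nrow(ms))) {
        cne[[length(cne) + 1L]] <- sample_elements(ch, ms$start[k], ms$end[k],
                                                   cne_density_mshsb, cne_len_mean)
      }
      for (k in seq_len(nrow(bg))) {
        cne[[length(cne) + 1L]] <- sample_elements(ch, bg$start[k], bg$end[k],
                                                   cne_density_background, cne_len_mean)
      }
      ce_extra[[length(ce_extra) + 1L]] <-
        sample_elements(ch, 0, unname(lens[ch]), 0.03, 300, len_min = 50)
    }
    cne <- iv_merge(do.call(rbind, cne))
    # deserts around planted breakpoints, by type
    ds <- list()
    add_desert <- function(chrom, pos, hw) {
      if (is.na(chrom) || hw <= 0) return()
      ds[[length(ds) + 1L]] <<- data.frame(chrom = chrom, start = pos - hw,
                                           end = pos + hw)
    }
    for (k in seq_len(nrow(ebrs))) {
      ty <- ebrs$type[k]
      hw <- switch(ty, intra = desert_halfwidth_bp[["intra"]],
                   fission = desert_halfwidth_bp[["fission"]],
                   fusion = , translocation = desert_halfwidth_bp[["fusion"]])
      add_desert(ebrs$ref_chrom[k], ebrs$ref_pos[k], hw)
      if (ty %in% c("fusion", "translocation")) {
        add_desert(ebrs$ref_chrom2[k], ebrs$ref_pos2[k], hw)
      }
    }
    deserts <- if (length(ds)) {
      iv_clip(iv_merge(do.call(rbind, ds)), lens)
    } else {
      data.frame(chrom = character(), start = numeric(), end = numeric())
    }
    if (nrow(deserts)) cne <- iv_subtract(cne, deserts)
    ce <- iv_merge(rbind(cne, do.call(rbind, ce_extra)))
    # TE families (reference coordinates), enriched near intra breakpoints
    te <- list()
    intra_pos <- ebrs[ebrs$type == "intra", , drop = FALSE]
    for (f in seq_along(tp$families)) {
      fam <- tp$families[f]
      for (ch in names(lens)) {
        el <- sample_elements(ch, 0, unname(lens[ch]), tp$density[f],
                              tp$len_mean[f], len_min = 50)
        if (nrow(el)) el$name <- fam
        te[[length(te) + 1L]] <- el
      }
      if (identical(fam, tp$enrich_family) && tp$enrich_factor > 1) {
        for (k in seq_len(nrow(intra_pos))) {
          ch <- intra_pos$ref_chrom[k]
          s <- max(0, intra_pos$ref_pos[k] - tp$enrich_halfwidth)
          e <- min(unname(lens[ch]), intra_pos$ref_pos[k] + tp$enrich_halfwidth)
          el <- sample_elements(ch, s, e, tp$density[f] * (tp$enrich_factor - 1),
                                tp$len_mean[f], len_min = 50)
          if (nrow(el)) el$name <- fam
          te[[length(te) + 1L]] <- el
        }
      }
    }
    te <- do.call(rbind, te)
    te <- te[order(te$chrom, te$start), , drop = FALSE]
    rownames(te) <- NULL
    list(cne = cne, ce = ce, te = te, deserts = deserts)
  })
}

# --- probes ------------------------------------------------------------------

default_feature_sampler <- function(n) {
  data.frame(
    alignable_fraction = pmin(1, stats::rbeta(n, 18, 1.4)),
    max_ce_len = round(stats::rexp(n, 1 / 250)),
    has_ce_ge_3bp = stats::runif(n) < 0.95,
    total_repeat_len = round(stats::rexp(n, 1 / 900)),
    gene_count = stats::rpois(n, 4),
    mean_conservation_score = stats::runif(n, 0.2, 0.8)
  )
}

#' Plant probes and a cytogenetic map
#'
#' Places one BAC-like probe at the midpoint of each `spacing_bp` window of
#' every chromosome. The cytogenetic map orders probes per chromosome by
#' their true position perturbed with Gaussian noise, mirroring the relative
#' (not metric) ordering information FISH provides. A companion placement
#' table with end-sequence strands and an estimated insert length supports
#' the concordance filter; features for the universality rule are drawn
#' from `feature_sampler`.
#'
#' @param chrom_lengths named vector of chromosome lengths (descendant
#'   chromosomes for anchoring; reference chromosomes for panel design).
#' @param spacing_bp probe spacing; a chromosome of length `L` receives
#'   `floor(L / spacing_bp)` probes (one per window midpoint).
#' @param probe_len_bp probe interval length.
#' @param position_noise_sd Gaussian map-position noise (bp; 0 = exact order).
#' @param feature_sampler function(n) returning a data.frame of probe
#'   features; defaults to a broad avian-like mix.
#' @param discordant_rate fraction of placements made discordant (wrong
#'   strand pattern or out-of-range insert length).
#' @param library_mean_bp,library_sd_bp BAC library insert length model.
#' @param seed integer seed.
#' @return list with `probes` (intervals + features), `placements`
#'   (with `strand1`, `strand2` and truth flag `concordant_truth`),
#'   `map` (chrom, order_index, probe_id, map_position) and `truth`
#'   (true probe positions).
#' @export
plant_probes <- function(chrom_lengths, spacing_bp = 1e6, probe_len_bp = 1.5e5,
                         position_noise_sd = 0, feature_sampler = NULL,
                         discordant_rate = 0, library_mean_bp = 1.5e5,
                         library_sd_bp = 1e4, seed = NULL) {
  stopifnot(spacing_bp > 0)
  sampler <- feature_sampler %||% default_feature_sampler
  with_seed(seed, {
    probes <- list()
    for (ch in names(chrom_lengths)) {
      n <- floor(chrom_lengths[ch] / spacing_bp)
      if (n == 0) next
      centers <- (seq_len(n) - 0.5) * spacing_bp
      probes[[length(probes) + 1L]] <- data.frame(
        probe_id = sprintf("%s_p%03d", ch, seq_len(n)),
        chrom = ch,
        start = pmax(0, round(centers - probe_len_bp / 2)),
        end = pmin(unname(chrom_lengths[ch]), round(centers + probe_len_bp / 2)),
        center = centers, stringsAsFactors = FALSE)
    }
    probes <- do.call(rbind, probes)
    rownames(probes) <- NULL
    feats <- sampler(nrow(probes))
    probes <- cbind(probes, feats)
    # placements with end-sequence strands
    n <- nrow(probes)
    est_len <- round(stats::rnorm(n, library_mean_bp, library_sd_bp))
    s1 <- rep("+", n); s2 <- rep("-", n)
    disc <- stats::runif(n) < discordant_rate
    flavor <- stats::runif(n) < 0.5
    s2[disc & flavor] <- "+"
    est_len[disc & !flavor] <- round(library_mean_bp + 4.5 * library_sd_bp)
    placements <- data.frame(
      probe_id = probes$probe_id, library_id = "simlib",
      ref_chrom = probes$chrom, start = probes$start,
      end = probes$start + pmax(est_len, 1),
      strand1 = s1, strand2 = s2,
      concordant_truth = !disc, stringsAsFactors = FALSE)
    # cytogenetic map: order by noisy position
    map <- list()
    for (ch in unique(probes$chrom)) {
      p <- probes[probes$chrom == ch, , drop = FALSE]
      noisy <- p$center + stats::rnorm(nrow(p), 0, position_noise_sd)
      o <- order(noisy)
      map[[length(map) + 1L]] <- data.frame(
        chrom = ch, order_index = seq_len(nrow(p)),
        probe_id = p$probe_id[o],
        map_position = pmin(pmax(sort(noisy) / chrom_lengths[ch], 0), 1),
        stringsAsFactors = FALSE)
    }
    map <- do.call(rbind, map)
    rownames(map) <- NULL
    list(probes = probes, placements = placements, map = map,
         truth = data.frame(probe_id = probes$probe_id, chrom = probes$chrom,
                            true_pos = probes$center))
  })
}

# --- derived inputs for downstream modules ----------------------------------

#' Alignment blocks implied by the simulated truth
#'
#' Composes the scaffold-to-descendant map with the descendant-to-ancestor
#' karyotype, yielding the pairwise alignment-block table a whole-genome
#' aligner would produce between target scaffolds and the reference. Blocks
#' can be split into smaller sub-blocks separated by unaligned gaps to
#' exercise syntenic-fragment chaining.
#'
#' @param scaffold_map from [shred_to_scaffolds()].
#' @param karyotype from [apply_rearrangements()].
#' @param split_mean_bp mean sub-block length (`Inf` = no splitting).
#' @param gap_bp unaligned gap carved around each internal split boundary.
#' @param edge_erosion_bp maximum alignment erosion (uniform, per edge) at
#'   block edges abutting a rearrangement breakpoint or chromosome end —
#'   breakpoint neighborhoods are repeat-rich and align poorly, so the
#'   detected EBR interval is wider than the planted breakpoint.
#' @param seed integer seed.
#' @return alignment-block data.frame (`target_seq`, `t_start`, `t_end`,
#'   `ref_chrom`, `r_start`, `r_end`, `strand`, `identity`).
#' @export
sim_alignment_blocks <- function(scaffold_map, karyotype, split_mean_bp = Inf,
                                 gap_bp = 0, edge_erosion_bp = 0, seed = NULL) {
  with_seed(seed, {
  blocks <- list()
  for (k in seq_len(nrow(scaffold_map))) {
    fr <- scaffold_map[k, ]
    segs <- karyotype[karyotype$der_chrom == fr$der_chrom, , drop = FALSE]
    for (j in seq_len(nrow(segs))) {
      sg <- segs[j, ]
      i0 <- max(fr$der_start, sg$der_start)
      i1 <- min(fr$der_end, sg$der_end)
      if (i1 <= i0) next
      if (edge_erosion_bp > 0) {
        # erode only edges that coincide with a karyotype segment boundary
        if (i0 == sg$der_start) {
          i0 <- i0 + round(stats::runif(1, 0, edge_erosion_bp))
        }
        if (i1 == sg$der_end) {
          i1 <- i1 - round(stats::runif(1, 0, edge_erosion_bp))
        }
        if (i1 <= i0) next
      }
      # scaffold coordinates of the der interval [i0, i1)
      if (fr$strand == "+") {
        ts <- fr$scaf_start + (i0 - fr$der_start)
        te <- fr$scaf_start + (i1 - fr$der_start)
      } else {
        ts <- fr$scaf_start + (fr$der_end - i1)
        te <- fr$scaf_start + (fr$der_end - i0)
      }
      # ancestor coordinates of the same der interval
      if (sg$strand == "+") {
        rs <- sg$src_start + (i0 - sg$der_start)
        re <- sg$src_start + (i1 - sg$der_start)
      } else {
        rs <- sg$src_end - (i1 - sg$der_start)
        re <- sg$src_end - (i0 - sg$der_start)
      }
      strand <- if (fr$strand == sg$strand) "+" else "-"
      blocks[[length(blocks) + 1L]] <- data.frame(
        target_seq = fr$scaffold, t_start = ts, t_end = te,
        ref_chrom = sg$src_chrom, r_start = rs, r_end = re,
        strand = strand, identity = 1, stringsAsFactors = FALSE)
    }
  }
  blocks <- do.call(rbind, blocks)
  rownames(blocks) <- NULL
  if (!is.finite(split_mean_bp)) return(blocks)
    out <- list()
    for (k in seq_len(nrow(blocks))) {
      b <- blocks[k, ]
      L <- b$t_end - b$t_start
      cuts <- numeric(0)
      pos <- 0
      repeat {
        pos <- pos + max(gap_bp * 2, round(stats::rexp(1, 1 / split_mean_bp)))
        if (pos >= L) break
        cuts <- c(cuts, pos)
      }
      bounds <- c(0, cuts, L)
      for (p in seq_len(length(bounds) - 1L)) {
        a0 <- bounds[p] + if (p > 1) gap_bp / 2 else 0
        a1 <- bounds[p + 1] - if (p < length(bounds) - 1L) gap_bp / 2 else 0
        if (a1 - a0 < 1) next
        piece <- b
        piece$t_start <- b$t_start + a0
        piece$t_end <- b$t_start + a1
        if (b$strand == "+") {
          piece$r_start <- b$r_start + a0
          piece$r_end <- b$r_start + a1
        } else {
          piece$r_start <- b$r_end - a1
          piece$r_end <- b$r_end - a0
        }
        out[[length(out) + 1L]] <- piece
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Chromosome-level alignment blocks from a karyotype
#'
#' One block per karyotype segment, target = descendant chromosomes,
#' reference = ancestor. Feed to [build_homeology_map()].
#'
#' @param karyotype from [apply_rearrangements()].
#' @return alignment-block data.frame.
#' @export
karyotype_to_blocks <- function(karyotype) {
  data.frame(target_seq = karyotype$der_chrom, t_start = karyotype$der_start,
             t_end = karyotype$der_end, ref_chrom = karyotype$src_chrom,
             r_start = karyotype$src_start, r_end = karyotype$src_end,
             strand = karyotype$strand, identity = 1, stringsAsFactors = FALSE)
}

#' Simulated verification outcomes for split joints
#'
#' Emulates the PCR verification loop against the planted truth: a testable
#' joint coinciding with a planted chimeric joint is refuted (or, with
#' probability `p_alternative`, confirmed in the alternative fragment
#' order); all other testable joints are confirmed. `error_rate` flips the
#' outcome to model assay failure.
#'
#' @param joints SplitJoint table from [build_pcfs()]/[find_split_joints()].
#' @param truth_joints planted chimeric joints from [shred_to_scaffolds()].
#' @param p_alternative probability a true chimera resolves as
#'   `alternative_confirmed` instead of `refuted`.
#' @param error_rate probability of a flipped outcome.
#' @param tol_bp positional tolerance for matching a joint to truth.
#' @param seed integer seed.
#' @return `joints` with `status` filled for testable joints.
#' @export
simulate_verification <- function(joints, truth_joints, p_alternative = 0,
                                  error_rate = 0, tol_bp = 1e4, seed = NULL) {
  with_seed(seed, {
    for (k in seq_len(nrow(joints))) {
      if (!isTRUE(joints$testable[k])) next
      hit <- any(truth_joints$scaffold == joints$scaffold[k] &
                   truth_joints$pos >= joints$gap_start[k] - tol_bp &
                   truth_joints$pos <= joints$gap_end[k] + tol_bp)
      if (stats::runif(1) < error_rate) hit <- !hit
      joints$status[k] <- if (hit) {
        if (stats::runif(1) < p_alternative) "alternative_confirmed" else "refuted"
      } else "confirmed"
    }
    joints
  })
}
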