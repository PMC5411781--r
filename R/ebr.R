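# Evolutionary breakpoint region (EBR) detection and classification.
#
# The reference genome is treated as the ancestral proxy: a junction of two
# reference chromosomes inside one target chromosome is a fusion; a
# reference chromosome whose blocks split across target chromosomes marks a
# fission; breaks that stay within one chromosome pair are
# intrachromosomal. One biological event may legitimately emit one fusion
# and one fission record; records carry an event-group id so event counting
# stays unambiguous.

#' Detect EBRs from a homeology map
#'
#' One EBR per gap between adjacent HSBs on a reference chromosome where
#' target continuity breaks: a different target chromosome, an orientation
#' flip, or a target-side order jump of at least the map resolution. The
#' EBR interval is the reference-coordinate gap between the flanking HSBs;
#' intervals shorter than `min_ebr_bp` are extended by `extend_bp` on both
#' sides, and intervals longer than `max_ebr_bp` are flagged excluded
#' (extension applies before the size filter).
#'
#' @param map a `homeology_map`.
#' @param min_ebr_bp,extend_bp,max_ebr_bp interval post-processing rules.
#' @param chrom_lengths optional named reference chromosome lengths used to
#'   clip extended intervals.
#' @return an `ebr_set`: data.frame (`ref_chrom`, `start`, `end`, `type`
#'   (`NA` until classified), `excluded`, `well_defined`, `event_group`,
#'   plus flanking-HSB context columns).
#' @export
detect_ebrs <- function(map, min_ebr_bp = 1000, extend_bp = 1000,
                        max_ebr_bp = 100000, chrom_lengths = NULL) {
  resolution <- attr(map, "resolution") %||% 0
  m <- as.data.frame(map)
  m <- m[order(m$ref_chrom, m$r_start), , drop = FALSE]
  if (nrow(m) > 1) {
    ov <- m$ref_chrom[-1] == m$ref_chrom[-nrow(m)] &
      m$r_start[-1] < m$r_end[-nrow(m)]
    if (any(ov)) stop("overlapping HSBs on the reference")
  }
  out <- list()
  for (ch in unique(m$ref_chrom)) {
    h <- m[m$ref_chrom == ch, , drop = FALSE]
    if (nrow(h) < 2) next
    for (k in seq_len(nrow(h) - 1L)) {
      L <- h[k, ]; R <- h[k + 1L, ]
      broken <- L$target_chrom != R$target_chrom ||
        L$orientation != R$orientation
      if (!broken) {
        tgap <- if (L$orientation == "+") R$t_start - L$t_end
                else L$t_start - R$t_end
        broken <- abs(tgap) >= max(resolution, 1)
      }
      if (!broken) next
      out[[length(out) + 1L]] <- data.frame(
        ref_chrom = ch, start = L$r_end, end = R$r_start,
        type = NA_character_,
        left_target = L$target_chrom, right_target = R$target_chrom,
        left_orientation = L$orientation, right_orientation = R$orientation,
        stringsAsFactors = FALSE)
    }
  }
  ebrs <- if (length(out)) do.call(rbind, out) else
    data.frame(ref_chrom = character(), start = numeric(), end = numeric(),
               type = character(), left_target = character(),
               right_target = character(), left_orientation = character(),
               right_orientation = character())
  short <- (ebrs$end - ebrs$start) < min_ebr_bp
  ebrs$start[short] <- ebrs$start[short] - extend_bp
  ebrs$end[short] <- ebrs$end[short] + extend_bp
  ebrs$start <- pmax(ebrs$start, 0)
  if (!is.null(chrom_lengths) && nrow(ebrs)) {
    ebrs$end <- pmin(ebrs$end, chrom_lengths[ebrs$ref_chrom])
  }
  ebrs$excluded <- (ebrs$end - ebrs$start) > max_ebr_bp
  ebrs$well_defined <- rep(TRUE, nrow(ebrs))
  ebrs$event_group <- rep(NA_integer_, nrow(ebrs))
  rownames(ebrs) <- NULL
  class(ebrs) <- c("ebr_set", "data.frame")
  ebrs
}

#' Classify EBRs as intrachromosomal, fusion or fission
#'
#' Reference-side records from [detect_ebrs()] are typed by the target
#' chromosomes of the flanking HSBs: same target chromosome means an
#' intrachromosomal EBR; different target chromosomes mean the reference
#' chromosome is split in the target — a fission breakpoint. Additionally,
#' every target-chromosome junction between blocks of different reference
#' chromosomes emits one fusion record whose reference flanks are the
#' 10 kb (`terminal_flank_bp`) intervals of the two blocks adjacent to the
#' junction. A record is well defined iff both flanking blocks are oriented
#' (orientation not `?`). Intrachromosomal breakpoint pairs flanking an
#' inverted block run share an event group, so planted inversions can be
#' counted as single events.
#'
#' @param ebrs an `ebr_set` from [detect_ebrs()].
#' @param map the `homeology_map` the EBRs came from.
#' @param terminal_flank_bp width of the fusion reference-flank intervals.
#' @return an `ebr_set` with `type` set and fusion rows appended (fusion
#'   rows carry `partner_chrom`, `partner_start`, `partner_end`,
#'   `target_chrom`, `target_pos`).
#' @export
classify_ebrs <- function(ebrs, map, terminal_flank_bp = 10000) {
  m <- as.data.frame(map)
  ebrs <- as.data.frame(ebrs)
  if (nrow(ebrs)) {
    ebrs$type <- ifelse(ebrs$left_target == ebrs$right_target,
                        "intra", "fission")
    ebrs$well_defined <- ebrs$left_orientation != "?" &
      ebrs$right_orientation != "?"
  }
  ebrs$partner_chrom <- rep(NA_character_, nrow(ebrs))
  ebrs$partner_start <- rep(NA_real_, nrow(ebrs))
  ebrs$partner_end <- rep(NA_real_, nrow(ebrs))
  ebrs$target_chrom <- rep(NA_character_, nrow(ebrs))
  ebrs$target_pos <- rep(NA_real_, nrow(ebrs))

  # event groups: breakpoint pairs flanking one inverted run are one event
  grp <- 0L
  if (nrow(ebrs)) {
    m_ref <- m[order(m$ref_chrom, m$r_start), , drop = FALSE]
    used <- rep(FALSE, nrow(ebrs))
    for (ch in unique(m_ref$ref_chrom)) {
      h <- m_ref[m_ref$ref_chrom == ch, , drop = FALSE]
      if (nrow(h) < 3) next
      # maximal runs of constant orientation; an inverted run is one whose
      # orientation differs from both (equal-orientation) neighbor runs
      r <- rle(h$orientation)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      if (length(r$values) < 3) next
      for (q in 2:(length(r$values) - 1L)) {
        if (r$values[q - 1L] != r$values[q + 1L] ||
            r$values[q] == r$values[q - 1L]) next
        run_start <- starts[q]; run_end <- ends[q]
        if (h$target_chrom[run_start] != h$target_chrom[run_start - 1L] ||
            h$target_chrom[run_end] != h$target_chrom[run_end + 1L]) next
        e1 <- which(ebrs$ref_chrom == ch & !used & ebrs$type == "intra" &
                      ebrs$start <= h$r_start[run_start] &
                      ebrs$end >= h$r_end[run_start - 1L])
        e2 <- which(ebrs$ref_chrom == ch & !used & ebrs$type == "intra" &
                      ebrs$start <= h$r_start[run_end + 1L] &
                      ebrs$end >= h$r_end[run_end])
        if (length(e1) && length(e2) && e1[1] != e2[1]) {
          grp <- grp + 1L
          ebrs$event_group[c(e1[1], e2[1])] <- grp
          used[c(e1[1], e2[1])] <- TRUE
        }
      }
    }
    solo <- is.na(ebrs$event_group)
    if (any(solo)) {
      ebrs$event_group[solo] <- grp + seq_len(sum(solo))
      grp <- grp + sum(solo)
    }
  }

  # fusion records from target-side junctions of different ref chromosomes
  m_t <- m[order(m$target_chrom, m$t_start), , drop = FALSE]
  fus <- list()
  for (ch in unique(m_t$target_chrom)) {
    h <- m_t[m_t$target_chrom == ch, , drop = FALSE]
    if (nrow(h) < 2) next
    for (k in seq_len(nrow(h) - 1L)) {
      A <- h[k, ]; B <- h[k + 1L, ]
      if (A$ref_chrom == B$ref_chrom) next
      grp <- grp + 1L
      a_edge <- if (A$orientation == "+") A$r_end else A$r_start
      a_int <- if (A$orientation == "+") {
        c(max(A$r_start, a_edge - terminal_flank_bp), a_edge)
      } else c(a_edge, min(A$r_end, a_edge + terminal_flank_bp))
      b_edge <- if (B$orientation == "+") B$r_start else B$r_end
      b_int <- if (B$orientation == "+") {
        c(b_edge, min(B$r_end, b_edge + terminal_flank_bp))
      } else c(max(B$r_start, b_edge - terminal_flank_bp), b_edge)
      fus[[length(fus) + 1L]] <- data.frame(
        ref_chrom = A$ref_chrom, start = a_int[1], end = a_int[2],
        type = "fusion", left_target = ch, right_target = ch,
        left_orientation = A$orientation, right_orientation = B$orientation,
        excluded = FALSE,
        well_defined = A$orientation != "?" && B$orientation != "?",
        event_group = grp,
        partner_chrom = B$ref_chrom, partner_start = b_int[1],
        partner_end = b_int[2], target_chrom = ch, target_pos = A$t_end,
        stringsAsFactors = FALSE)
    }
  }
  if (length(fus)) ebrs <- rbind(ebrs, do.call(rbind, fus))
  rownames(ebrs) <- NULL
  class(ebrs) <- c("ebr_set", "data.frame")
  ebrs
}

#' @export
print.ebr_set <- function(x, ...) {
  tb <- table(factor(x$type, levels = c("intra", "fusion", "fission")))
  cat(sprintf("EBR set: %d records (%d intra, %d fusion, %d fission; %d excluded >100 kb)\n",
              nrow(x), tb[["intra"]], tb[["fusion"]], tb[["fission"]],
              sum(x$excluded %||% FALSE)))
  invisible(x)
}

#' Count rearrangement events in a classified EBR set
#'
#' Fusions and fissions are one record per event; intrachromosomal
#' breakpoints are counted by event group (an inversion contributes two
#' breakpoint records but one event).
#'
#' @param ebrs a classified `ebr_set`.
#' @return named vector (`intra_events`, `intra_breakpoints`, `fusion`,
#'   `fission`).
#' @export
ebr_event_counts <- function(ebrs) {
  intra <- ebrs[ebrs$type == "intra", , drop = FALSE]
  c(intra_events = length(unique(intra$event_group)),
    intra_breakpoints = nrow(intra),
    fusion = sum(ebrs$type == "fusion"),
    fission = sum(ebrs$type == "fission"))
}

#' Assign lineage specificity to EBRs across species
#'
#' An EBR is lineage-specific to species S iff its reference interval
#' (widened by `slack_bp`) overlaps no EBR in any other species mapped
#' against the same reference. Shared EBRs are labeled with the smallest
#' clade of the supplied tree containing all disrupted species (maximum
#' parsimony on the given topology).
#'
#' @param ebr_sets named list of classified `ebr_set` tables, one per
#'   target species (names = species).
#' @param tree an `ape` `phylo` object or a Newick string containing the
#'   species names as tips.
#' @param slack_bp positional slack when matching EBRs across species.
#' @return one data.frame combining all species' EBRs with `species` and
#'   `lineage` columns (`lineage` = species name or `+`-joined clade tips).
#' @export
assign_lineage <- function(ebr_sets, tree, slack_bp = 100000) {
  stopifnot(is.list(ebr_sets), !is.null(names(ebr_sets)))
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  missing_sp <- setdiff(names(ebr_sets), tree$tip.label)
  if (length(missing_sp)) {
    stop("species absent from tree: ", paste(missing_sp, collapse = ", "))
  }
  combined <- do.call(rbind, lapply(names(ebr_sets), function(sp) {
    e <- as.data.frame(ebr_sets[[sp]])
    if (!nrow(e)) return(NULL)
    e$species <- sp
    e
  }))
  if (is.null(combined)) return(combined)
  combined$lineage <- NA_character_
  for (k in seq_len(nrow(combined))) {
    sp <- combined$species[k]
    hit <- vapply(names(ebr_sets), function(other) {
      e <- ebr_sets[[other]]
      any(e$ref_chrom == combined$ref_chrom[k] &
            e$start - slack_bp < combined$end[k] &
            e$end + slack_bp > combined$start[k])
    }, logical(1))
    disrupted <- names(ebr_sets)[hit]
    if (length(disrupted) == 1) {
      combined$lineage[k] <- disrupted
    } else {
      node <- ape::getMRCA(tree, disrupted)
      tips <- ape::extract.clade(tree, node)$tip.label
      combined$lineage[k] <- paste(sort(tips), collapse = "+")
    }
  }
  rownames(combined) <- NULL
  combined
}
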