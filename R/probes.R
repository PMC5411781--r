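# Universal-probe (BAC clone) selection: concordance filtering, feature
# extraction over genomic tracks, the universality decision rule, and
# evenly spaced panel selection.

#' Filter concordant probe placements
#'
#' A placement is concordant iff the estimated insert length lies within
#' the library mean +/- 3 standard deviations AND the two end sequences map
#' to opposite DNA strands.
#'
#' @param placements data.frame with `start`, `end`, `strand1`, `strand2`.
#' @param library_mean_bp,library_sd_bp library insert length statistics.
#' @return the concordant subset of `placements`.
#' @export
filter_concordant <- function(placements, library_mean_bp, library_sd_bp) {
  stopifnot(library_mean_bp > 0, library_sd_bp > 0)
  len <- placements$end - placements$start
  ok <- len >= library_mean_bp - 3 * library_sd_bp &
    len <= library_mean_bp + 3 * library_sd_bp &
    placements$strand1 != placements$strand2
  placements[ok, , drop = FALSE]
}

#' Extract per-probe genomic features
#'
#' Computes, for each probe interval, the inputs of the universality rule:
#' the alignable base fraction, the longest conserved element (CE)
#' overlapping the probe (clipped to the probe), a flag for any CE of at
#' least `ce_min_bp`, the total clipped repeat length, the overlapping gene
#' count, and the mean conservation score over scored bases.
#'
#' @param probes data.frame (`probe_id`, `chrom`, `start`, `end`).
#' @param alignable,ce,repeats,genes interval tracks (`chrom`, `start`,
#'   `end`); any may be empty.
#' @param conservation optional scored track (`chrom`, `start`, `end`,
#'   `score`).
#' @param ce_min_bp minimum CE length for the presence flag.
#' @return data.frame of `ProbeFeatures` (one row per probe).
#' @export
extract_features <- function(probes, alignable, ce, repeats, genes = NULL,
                             conservation = NULL, ce_min_bp = 3) {
  if (any(probes$end <= probes$start)) stop("zero-length probe interval")
  q <- data.frame(chrom = probes$chrom, start = probes$start, end = probes$end)
  len <- probes$end - probes$start
  align_bp <- iv_overlap_bases(q, alignable)
  rep_bp <- iv_overlap_bases(q, repeats)
  ce <- iv_merge(ce)
  max_ce <- numeric(nrow(probes))
  has_ce <- logical(nrow(probes))
  for (k in seq_len(nrow(probes))) {
    cc <- ce[ce$chrom == probes$chrom[k] & ce$end > probes$start[k] &
               ce$start < probes$end[k], , drop = FALSE]
    if (nrow(cc)) {
      clipped <- pmin(cc$end, probes$end[k]) - pmax(cc$start, probes$start[k])
      max_ce[k] <- max(clipped)
      has_ce[k] <- any(clipped >= ce_min_bp)
    }
  }
  gene_count <- if (is.null(genes) || !nrow(genes)) integer(nrow(probes)) else
    vapply(seq_len(nrow(probes)), function(k) {
      sum(genes$chrom == probes$chrom[k] & genes$end > probes$start[k] &
            genes$start < probes$end[k])
    }, integer(1))
  cons <- rep(NA_real_, nrow(probes))
  if (!is.null(conservation) && nrow(conservation)) {
    for (k in seq_len(nrow(probes))) {
      cc <- conservation[conservation$chrom == probes$chrom[k] &
                           conservation$end > probes$start[k] &
                           conservation$start < probes$end[k], , drop = FALSE]
      if (nrow(cc)) {
        w <- pmin(cc$end, probes$end[k]) - pmax(cc$start, probes$start[k])
        cons[k] <- sum(w * cc$score) / sum(w)
      }
    }
  }
  data.frame(probe_id = probes$probe_id,
             alignable_fraction = align_bp / len,
             max_ce_len = max_ce,
             has_ce_ge_3bp = has_ce,
             total_repeat_len = rep_bp,
             gene_count = gene_count,
             mean_conservation_score = cons,
             stringsAsFactors = FALSE)
}

#' Classify probes as universal candidates
#'
#' The decision rule for probes likely to hybridize across distantly
#' related species: at least `min_alignable` of the probe sequence
#' alignable across genomes AND either one conserved element of at least
#' `min_ce_bp`, or — lacking a long CE — only short repetitive content
#' (strictly less than `max_repeat_bp` in total) together with at least one
#' CE of >= 3 bp. The alignability condition applies to both branches.
#'
#' @param features data.frame from [extract_features()] (or any table with
#'   `alignable_fraction`, `max_ce_len`, `total_repeat_len`,
#'   `has_ce_ge_3bp`).
#' @param min_alignable,min_ce_bp,max_repeat_bp rule thresholds.
#' @return factor with levels `universal_candidate`, `restricted`.
#' @export
classify_universal <- function(features, min_alignable = 0.93,
                               min_ce_bp = 300, max_repeat_bp = 1290) {
  ok <- features$alignable_fraction >= min_alignable &
    (features$max_ce_len >= min_ce_bp |
       (features$total_repeat_len < max_repeat_bp & features$has_ce_ge_3bp))
  factor(ifelse(ok, "universal_candidate", "restricted"),
         levels = c("universal_candidate", "restricted"))
}

#' Select an evenly spaced probe panel
#'
#' Greedy sweep per chromosome: the first candidate is always accepted;
#' each subsequent candidate is accepted iff its position is at least
#' `target_spacing_bp` beyond the last accepted one. Chromosomes present in
#' `chrom_levels` but lacking candidates are reported uncovered.
#'
#' @param candidates data.frame (`probe_id`, `chrom`, `start`, `end`);
#'   positions are interval midpoints.
#' @param target_spacing_bp minimum spacing between accepted probes.
#' @param chrom_levels optional chromosome universe for coverage reporting.
#' @return list with `panel` (accepted rows, plus `pos`), `spacing`
#'   (data.frame of within-chromosome gaps) and `uncovered` (chromosomes
#'   without any candidate).
#' @export
select_spaced_panel <- function(candidates, target_spacing_bp,
                                chrom_levels = NULL) {
  stopifnot(target_spacing_bp > 0)
  candidates$pos <- (candidates$start + candidates$end) / 2
  candidates <- candidates[order(candidates$chrom, candidates$pos), , drop = FALSE]
  keep <- logical(nrow(candidates))
  for (ch in unique(candidates$chrom)) {
    idx <- which(candidates$chrom == ch)
    last <- -Inf
    for (i in idx) {
      if (candidates$pos[i] - last >= target_spacing_bp || !is.finite(last)) {
        keep[i] <- TRUE
        last <- candidates$pos[i]
      }
    }
  }
  panel <- candidates[keep, , drop = FALSE]
  spacing <- do.call(rbind, lapply(unique(panel$chrom), function(ch) {
    p <- panel$pos[panel$chrom == ch]
    if (length(p) < 2) return(NULL)
    data.frame(chrom = ch, gap = diff(p))
  }))
  uncovered <- setdiff(chrom_levels %||% character(), unique(candidates$chrom))
  list(panel = panel,
       spacing = spacing %||% data.frame(chrom = character(), gap = numeric()),
       uncovered = uncovered)
}
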