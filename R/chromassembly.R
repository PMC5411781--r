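# Anchoring PCFs to chromosomes with a cytogenetic probe map: assignment,
# ordering, orientation and conflict detection.

#' Assign PCFs to chromosomes by probe majority
#'
#' Each PCF is assigned to the chromosome carrying a strict majority of its
#' mapped probes. Any PCF whose probes fall on two or more chromosomes is
#' additionally emitted as an interchromosomal conflict (a candidate
#' mis-join to be split and re-assigned); with no strict majority the
#' assignment is `NA`. Probes absent from the map are ignored and counted.
#'
#' @param probe_to_pcf data.frame (`probe_id`, `pcf_id`, `pcf_pos`): probe
#'   alignments to PCFs (position within the PCF in bp).
#' @param map cytogenetic map (`chrom`, `order_index`, `probe_id`,
#'   `map_position`).
#' @return list with `assignments` (data.frame `pcf_id`, `chrom`,
#'   `n_probes`, `conflict`), `conflicts` (conflicted PCF ids) and
#'   `unmapped_probes`.
#' @export
assign_pcfs <- function(probe_to_pcf, map) {
  stopifnot(!anyDuplicated(probe_to_pcf$probe_id))
  m <- merge(probe_to_pcf, map, by = "probe_id")
  unmapped <- setdiff(probe_to_pcf$probe_id, m$probe_id)
  if (length(unmapped)) {
    message(length(unmapped), " probe(s) absent from the cytogenetic map; ignored")
  }
  rows <- lapply(unique(m$pcf_id), function(pid) {
    mm <- m[m$pcf_id == pid, , drop = FALSE]
    tab <- sort(table(mm$chrom), decreasing = TRUE)
    conflict <- length(tab) >= 2
    chrom <- if (length(tab) == 1 || tab[1] > sum(tab) - tab[1]) names(tab)[1]
             else NA_character_
    data.frame(pcf_id = pid, chrom = chrom, n_probes = nrow(mm),
               conflict = conflict, stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  list(assignments = assignments,
       conflicts = assignments$pcf_id[assignments$conflict],
       unmapped_probes = unmapped)
}

# sign of the Kendall-style concordance between within-PCF probe positions
# and the map order: +1 concordant, -1 reversed, 0 tied/undecidable
concordance_sign <- function(pcf_pos, order_index) {
  n <- length(pcf_pos)
  if (n < 2) return(0)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- s + sign(pcf_pos[j] - pcf_pos[i]) * sign(order_index[j] - order_index[i])
  }
  sign(s)
}

#' Order and orient PCFs along chromosomes
#'
#' PCFs are ordered along each chromosome by the mean map position of their
#' probes (ties broken by PCF length, longer first). Orientation for a PCF
#' with two or more probes is the sign of the rank correlation between the
#' probe coordinates within the PCF and the map order: `+` if concordant,
#' `-` if reversed; single-probe or exactly tied PCFs get `?`. Interleaved
#' probe ranges of two PCFs (map reads A, B, A) violate monotonicity and
#' raise an error by default, naming the offending probes.
#'
#' @param assignment result of [assign_pcfs()] (or its `assignments`
#'   element); conflicted PCFs must have been resolved.
#' @param probe_to_pcf probe alignments to PCFs (`probe_id`, `pcf_id`,
#'   `pcf_pos`).
#' @param map cytogenetic map.
#' @param pcf_len named vector of PCF lengths (bp), used for tie-breaks
#'   and placement statistics.
#' @param on_interleave `"error"` (default) or `"warn"`.
#' @return a `chromosome_build_set`: data.frame (`chrom`, `position`,
#'   `pcf_id`, `orientation`, `length`, `mean_order`).
#' @export
order_and_orient <- function(assignment, probe_to_pcf, map, pcf_len,
                             on_interleave = c("error", "warn")) {
  on_interleave <- match.arg(on_interleave)
  if (is.list(assignment) && !is.data.frame(assignment)) {
    assignment <- assignment$assignments
  }
  if (any(assignment$conflict & !is.na(assignment$chrom))) {
    stop("resolve interchromosomal conflicts before ordering")
  }
  assignment <- assignment[!is.na(assignment$chrom), , drop = FALSE]
  m <- merge(probe_to_pcf, map, by = "probe_id")
  out <- list()
  for (ch in unique(assignment$chrom)) {
    pids <- assignment$pcf_id[assignment$chrom == ch]
    mm <- m[m$pcf_id %in% pids & m$chrom == ch, , drop = FALSE]
    info <- do.call(rbind, lapply(pids, function(pid) {
      p <- mm[mm$pcf_id == pid, , drop = FALSE]
      data.frame(pcf_id = pid,
                 mean_order = mean(p$order_index),
                 min_order = min(p$order_index),
                 max_order = max(p$order_index),
                 length = unname(pcf_len[pid]),
                 stringsAsFactors = FALSE)
    }))
    # monotonicity: probe order ranges of distinct PCFs must not interleave
    if (nrow(info) > 1) {
      for (i in seq_len(nrow(info) - 1)) for (j in (i + 1):nrow(info)) {
        if (info$min_order[i] < info$max_order[j] &&
            info$min_order[j] < info$max_order[i]) {
          bad <- mm$probe_id[mm$pcf_id %in% info$pcf_id[c(i, j)]]
          msg <- sprintf("map order interleaves PCFs %s and %s (probes: %s)",
                         info$pcf_id[i], info$pcf_id[j],
                         paste(bad, collapse = ", "))
          if (on_interleave == "error") stop(msg) else warning(msg)
        }
      }
    }
    info <- info[order(info$mean_order, -info$length), , drop = FALSE]
    ori <- vapply(info$pcf_id, function(pid) {
      p <- mm[mm$pcf_id == pid, , drop = FALSE]
      s <- concordance_sign(p$pcf_pos, p$order_index)
      if (s > 0) "+" else if (s < 0) "-" else "?"
    }, character(1))
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, position = seq_len(nrow(info)), pcf_id = info$pcf_id,
      orientation = unname(ori), length = info$length,
      mean_order = info$mean_order, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("chromosome_build_set", "data.frame")
  res
}

#' @export
print.chromosome_build_set <- function(x, ...) {
  cat(sprintf("Chromosome builds: %d chromosome(s), %d PCFs placed (%.2f Mb, %.2f Mb oriented)\n",
              length(unique(x$chrom)), nrow(x), sum(x$length) / 1e6,
              sum(x$length[x$orientation != "?"]) / 1e6))
  invisible(x)
}

#' Placement statistics for chromosome builds
#'
#' @param builds a `chromosome_build_set`.
#' @param total_assembly_bp total input assembly length.
#' @return list with `placed_bp`, `placed_fraction`, `oriented_bp` and a
#'   `per_chromosome` table.
#' @export
placement_stats <- function(builds, total_assembly_bp) {
  if (is.null(builds) || !nrow(builds)) {
    return(list(placed_bp = 0, placed_fraction = 0, oriented_bp = 0,
                per_chromosome = data.frame(chrom = character(),
                                            n_pcfs = integer(),
                                            placed_bp = numeric(),
                                            oriented_bp = numeric())))
  }
  per <- do.call(rbind, lapply(unique(builds$chrom), function(ch) {
    b <- builds[builds$chrom == ch, , drop = FALSE]
    data.frame(chrom = ch, n_pcfs = nrow(b), placed_bp = sum(b$length),
               oriented_bp = sum(b$length[b$orientation != "?"]))
  }))
  list(placed_bp = sum(per$placed_bp),
       placed_fraction = sum(per$placed_bp) / total_assembly_bp,
       oriented_bp = sum(per$oriented_bp),
       per_chromosome = per)
}

#' Write chromosome builds as AGP v2.1
#'
#' Components are whole PCFs; unknown orientation is encoded as AGP `na`.
#'
#' @param builds a `chromosome_build_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
builds_to_agp <- function(builds, path) {
  write_agp(data.frame(object = builds$chrom, component_id = builds$pcf_id,
                       component_beg = 0, component_end = builds$length,
                       orientation = builds$orientation), path)
}
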