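# Syntenic fragment (SF) detection and homeology maps.
#
# An SF is a maximal chain of colinear alignment blocks between one target
# sequence and one reference chromosome. Chaining is resolution-bounded on
# BOTH genomes: the target-side and reference-side inter-block gaps must
# each be below the stated resolution. One-sided gap rules admit spurious
# merges across insertions, so the dual-gap rule is deliberate.

validate_blocks <- function(blocks) {
  need <- c("target_seq", "t_start", "t_end", "ref_chrom", "r_start",
            "r_end", "strand")
  if (!all(need %in% names(blocks))) {
    stop("alignment blocks need columns: ", paste(need, collapse = ", "))
  }
  if (nrow(blocks) &&
      (any(blocks$t_end <= blocks$t_start) || any(blocks$r_end <= blocks$r_start))) {
    stop("alignment blocks must have start < end on both genomes")
  }
  if (nrow(blocks) && !all(blocks$strand %in% c("+", "-"))) {
    stop("block strand must be '+' or '-'")
  }
  blocks
}

#' Detect syntenic fragments from pairwise alignment blocks
#'
#' Blocks shorter than `min_block_bp` on the target are discarded; blocks
#' overlapping on the target are resolved by keeping the longer one (the
#' conflict is reported via the `conflicts` attribute). Two consecutive
#' blocks merge into one SF iff they share target sequence, reference
#' chromosome and orientation, are colinear (reference coordinates advance
#' with the orientation), and both the target-side and reference-side gaps
#' are smaller than `resolution`.
#'
#' @param blocks alignment-block data.frame (`target_seq`, `t_start`,
#'   `t_end`, `ref_chrom`, `r_start`, `r_end`, `strand`, optional
#'   `identity`).
#' @param resolution chaining resolution (bp).
#' @param min_block_bp minimum target-side block length retained.
#' @return an `sf_set`: data.frame of SFs (`sf_id`, `target_seq`,
#'   `t_start`, `t_end`, `ref_chrom`, `r_start`, `r_end`, `strand`,
#'   `n_blocks`), sorted by target coordinate, with attributes
#'   `resolution` and `conflicts`.
#' @export
detect_sfs <- function(blocks, resolution, min_block_bp = 5000) {
  stopifnot(resolution > 0)
  validate_blocks(blocks)
  blocks <- blocks[blocks$t_end - blocks$t_start >= min_block_bp, , drop = FALSE]
  blocks <- blocks[order(blocks$target_seq, blocks$t_start, -(blocks$t_end)), ,
                   drop = FALSE]
  # resolve target-side overlaps: keep the longer block
  keep <- rep(TRUE, nrow(blocks))
  conflicts <- 0L
  for (ts in unique(blocks$target_seq)) {
    idx <- which(blocks$target_seq == ts)
    hi <- -Inf; hi_i <- NA_integer_
    for (i in idx) {
      if (blocks$t_start[i] < hi) {
        conflicts <- conflicts + 1L
        li <- blocks$t_end[i] - blocks$t_start[i]
        lh <- blocks$t_end[hi_i] - blocks$t_start[hi_i]
        if (li > lh) { keep[hi_i] <- FALSE; hi <- blocks$t_end[i]; hi_i <- i }
        else keep[i] <- FALSE
      } else {
        hi <- blocks$t_end[i]; hi_i <- i
      }
    }
  }
  blocks <- blocks[keep, , drop = FALSE]
  out <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) out[[length(out) + 1L]] <<- cur
  }
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    if (!is.null(cur) &&
        cur$target_seq == b$target_seq &&
        cur$ref_chrom == b$ref_chrom &&
        cur$strand == b$strand &&
        (b$t_start - cur$t_end) < resolution &&
        {
          rgap <- if (b$strand == "+") b$r_start - cur$r_end
                  else cur$r_start - b$r_end
          abs(rgap) < resolution
        }) {
      cur$t_end <- b$t_end
      cur$r_start <- min(cur$r_start, b$r_start)
      cur$r_end <- max(cur$r_end, b$r_end)
      cur$n_blocks <- cur$n_blocks + 1L
    } else {
      flush()
      cur <- data.frame(target_seq = b$target_seq, t_start = b$t_start,
                        t_end = b$t_end, ref_chrom = b$ref_chrom,
                        r_start = b$r_start, r_end = b$r_end,
                        strand = b$strand, n_blocks = 1L,
                        stringsAsFactors = FALSE)
    }
  }
  flush()
  sfs <- if (length(out)) do.call(rbind, out) else
    data.frame(target_seq = character(), t_start = numeric(),
               t_end = numeric(), ref_chrom = character(),
               r_start = numeric(), r_end = numeric(), strand = character(),
               n_blocks = integer())
  sfs <- sfs[order(sfs$target_seq, sfs$t_start), , drop = FALSE]
  sfs <- cbind(sf_id = sprintf("SF%04d", seq_len(nrow(sfs))), sfs,
               stringsAsFactors = FALSE)
  rownames(sfs) <- NULL
  structure(sfs, resolution = resolution, conflicts = conflicts,
            class = c("sf_set", "data.frame"))
}

#' @export
print.sf_set <- function(x, ...) {
  cat(sprintf("Syntenic fragments: %d SFs on %d target sequence(s), resolution %g bp\n",
              nrow(x), length(unique(x$target_seq)), attr(x, "resolution")))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Build a chromosome-scale homeology map
#'
#' Chains chromosome-level alignment blocks into homologous synteny blocks
#' (HSBs) at the stated resolution. Chaining happens at fine granularity
#' first (so HSB boundaries stay precise to the underlying alignment),
#' then chains shorter than the resolution are suppressed and the
#' survivors re-chained: an event smaller than the resolution is invisible
#' and does not break an HSB. The result is sorted by reference
#' coordinate.
#'
#' @param blocks alignment blocks with target chromosome coordinates (e.g.
#'   from [karyotype_to_blocks()]).
#' @param resolution map resolution in bp (minimum HSB size and maximum
#'   bridged gap).
#' @param min_block_bp minimum alignment-block size entering the first
#'   chaining pass.
#' @return a `homeology_map`: data.frame (`ref_chrom`, `r_start`, `r_end`,
#'   `target_chrom`, `t_start`, `t_end`, `orientation`, `n_blocks`) sorted
#'   by reference coordinate, with attribute `resolution`.
#' @export
build_homeology_map <- function(blocks, resolution, min_block_bp = 5000) {
  fine <- detect_sfs(blocks, resolution, min_block_bp = min(min_block_bp, resolution))
  fine <- fine[fine$t_end - fine$t_start >= resolution, , drop = FALSE]
  sfs <- detect_sfs(sfs_to_blocks(fine), resolution, min_block_bp = 0)
  map <- data.frame(ref_chrom = sfs$ref_chrom, r_start = sfs$r_start,
                    r_end = sfs$r_end, target_chrom = sfs$target_seq,
                    t_start = sfs$t_start, t_end = sfs$t_end,
                    orientation = sfs$strand, n_blocks = sfs$n_blocks,
                    stringsAsFactors = FALSE)
  map <- map[order(map$ref_chrom, map$r_start), , drop = FALSE]
  rownames(map) <- NULL
  # HSBs must not overlap on either genome
  for (side in list(c("ref_chrom", "r_start", "r_end"),
                    c("target_chrom", "t_start", "t_end"))) {
    d <- data.frame(chrom = map[[side[1]]], start = map[[side[2]]],
                    end = map[[side[3]]])
    d <- d[order(d$chrom, d$start), ]
    ov <- d$chrom[-1] == d$chrom[-nrow(d)] & d$start[-1] < d$end[-nrow(d)]
    if (nrow(d) > 1 && any(ov)) stop("overlapping HSBs in homeology map")
  }
  structure(map, resolution = resolution,
            class = c("homeology_map", "data.frame"))
}

#' @export
print.homeology_map <- function(x, ...) {
  cat(sprintf("Homeology map: %d HSBs, %d reference chromosome(s), resolution %g bp\n",
              nrow(x), length(unique(x$ref_chrom)), attr(x, "resolution")))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Convert an SF set back to an alignment-block table
#'
#' Each SF becomes a single block; useful for idempotence checks and for
#' feeding SF output into block-consuming steps.
#'
#' @param sfs an `sf_set`.
#' @return alignment-block data.frame.
#' @export
sfs_to_blocks <- function(sfs) {
  data.frame(target_seq = sfs$target_seq, t_start = sfs$t_start,
             t_end = sfs$t_end, ref_chrom = sfs$ref_chrom,
             r_start = sfs$r_start, r_end = sfs$r_end, strand = sfs$strand,
             identity = 1, stringsAsFactors = FALSE)
}
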