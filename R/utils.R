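# Interval arithmetic on 0-based half-open [start, end) tables with columns
# chrom, start, end. All genomic tracks in the package use this convention
# (identical to BED), so readers/writers never shift coordinates.

iv_check <- function(x, name = "track") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    stop(sprintf("%s must have columns chrom, start, end", name))
  }
  if (nrow(x) && any(x$end < x$start)) {
    stop(sprintf("%s has intervals with end < start", name))
  }
  invisible(x)
}

# Sort by (chrom, start) and merge overlapping or touching intervals.
# Extra columns are dropped: a merged track is a pure base-set.
iv_merge <- function(x) {
  iv_check(x)
  x <- x[x$end > x$start, c("chrom", "start", "end"), drop = FALSE]
  if (!nrow(x)) return(x)
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  out <- vector("list", length(unique(x$chrom)))
  i <- 0L
  for (ch in unique(x$chrom)) {
    s <- x[x$chrom == ch, , drop = FALSE]
    new_grp <- c(TRUE, s$start[-1] > cummax(s$end[-nrow(s)]))
    grp <- cumsum(new_grp)
    i <- i + 1L
    out[[i]] <- data.frame(
      chrom = ch,
      start = tapply(s$start, grp, min),
      end = tapply(s$end, grp, max),
      row.names = NULL
    )
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Subtract base-set `b` from base-set `a` (both interval tables).
iv_subtract <- function(a, b) {
  iv_check(a, "a"); iv_check(b, "b")
  a <- iv_merge(a)
  b <- iv_merge(b)
  if (!nrow(a) || !nrow(b)) return(a)
  pieces <- list()
  for (ch in unique(a$chrom)) {
    aa <- a[a$chrom == ch, , drop = FALSE]
    bb <- b[b$chrom == ch, , drop = FALSE]
    if (!nrow(bb)) { pieces[[length(pieces) + 1L]] <- aa; next }
    for (k in seq_len(nrow(aa))) {
      cur_s <- aa$start[k]; cur_e <- aa$end[k]
      hits <- bb[bb$end > cur_s & bb$start < cur_e, , drop = FALSE]
      if (!nrow(hits)) {
        pieces[[length(pieces) + 1L]] <- data.frame(chrom = ch, start = cur_s, end = cur_e)
        next
      }
      pos <- cur_s
      for (j in seq_len(nrow(hits))) {
        if (hits$start[j] > pos) {
          pieces[[length(pieces) + 1L]] <- data.frame(chrom = ch, start = pos, end = hits$start[j])
        }
        pos <- max(pos, hits$end[j])
      }
      if (pos < cur_e) {
        pieces[[length(pieces) + 1L]] <- data.frame(chrom = ch, start = pos, end = cur_e)
      }
    }
  }
  if (!length(pieces)) return(a[0, , drop = FALSE])
  res <- do.call(rbind, pieces)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Number of track bases falling inside each query interval. `track` need not
# be pre-merged. Prefix-sum implementation; exactness against a per-base
# oracle is asserted in the test suite.
iv_overlap_bases <- function(queries, track) {
  iv_check(queries, "queries")
  track <- iv_merge(track)
  out <- numeric(nrow(queries))
  if (!nrow(track) || !nrow(queries)) return(out)
  for (ch in unique(queries$chrom)) {
    qi <- which(queries$chrom == ch)
    tt <- track[track$chrom == ch, , drop = FALSE]
    if (!nrow(tt)) next
    lens <- tt$end - tt$start
    cum <- cumsum(lens)
    # bases of the track strictly before position x
    pre <- function(x) {
      i <- findInterval(x, tt$start)        # intervals with start <= x
      base <- ifelse(i > 1L, cum[pmax(i - 1L, 1L)], 0)
      base[i == 0L] <- 0
      inside <- i >= 1L
      extra <- numeric(length(x))
      extra[inside] <- pmin(pmax(x[inside] - tt$start[i[inside]], 0), lens[i[inside]])
      base + extra
    }
    out[qi] <- pre(queries$end[qi]) - pre(queries$start[qi])
  }
  out
}

# Clip intervals to chromosome bounds given a named length vector.
iv_clip <- function(x, chrom_len) {
  iv_check(x)
  if (!nrow(x)) return(x)
  lim <- chrom_len[as.character(x$chrom)]
  if (anyNA(lim)) stop("interval on unknown chromosome")
  x$start <- pmax(x$start, 0)
  x$end <- pmin(x$end, unname(lim))
  x[x$end > x$start, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# N50: largest L such that members of length >= L sum to at least half of
# the total length.
n50 <- function(lengths) {
  lengths <- lengths[lengths > 0]
  if (!length(lengths)) return(0)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}
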