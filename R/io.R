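#' Write an AGP v2.1 file
#'
#' Serializes an ordered set of placed components (scaffold fragments in a
#' PCF, or PCFs on a chromosome) as AGP v2.1. Component coordinates in the
#' input are 0-based half-open; AGP is written 1-based inclusive as the
#' format requires. Adjacent components are separated by a fixed-length
#' `contig` gap with `linkage no`.
#'
#' @param members data.frame with columns `object`, `component_id`,
#'   `component_beg`, `component_end` (0-based half-open) and `orientation`
#'   (`+`, `-` or `?`; `?` is encoded as AGP `na`). Rows must be ordered
#'   along each object.
#' @param path output file path.
#' @param gap_length,gap_type,linkage,linkage_evidence gap-row fields placed
#'   between adjacent components of the same object.
#' @return `path`, invisibly.
#' @export
write_agp <- function(members, path, gap_length = 100, gap_type = "contig",
                      linkage = "no", linkage_evidence = "align_genus") {
  stopifnot(all(c("object", "component_id", "component_beg", "component_end",
                  "orientation") %in% names(members)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  for (obj in unique(members$object)) {
    m <- members[members$object == obj, , drop = FALSE]
    pos <- 0L   # 0-based running coordinate on the object
    part <- 0L
    for (k in seq_len(nrow(m))) {
      if (k > 1L) {
        part <- part + 1L
        writeLines(paste(obj, pos + 1L, pos + gap_length, part, "N",
                         gap_length, gap_type, linkage, linkage_evidence,
                         sep = "\t"), con)
        pos <- pos + gap_length
      }
      len <- m$component_end[k] - m$component_beg[k]
      part <- part + 1L
      ori <- as.character(m$orientation[k])
      if (ori == "?") ori <- "na"
      writeLines(paste(obj, pos + 1L, pos + len, part, "W",
                       m$component_id[k], m$component_beg[k] + 1L,
                       m$component_end[k], ori, sep = "\t"), con)
      pos <- pos + len
    }
  }
  invisible(path)
}

#' Read an AGP file written by [write_agp()]
#'
#' Gap rows are dropped; component coordinates are returned 0-based
#' half-open, with AGP orientation `na` mapped back to `?`.
#'
#' @param path AGP file path.
#' @return data.frame with columns `object`, `object_beg`, `object_end`,
#'   `component_id`, `component_beg`, `component_end`, `orientation`.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  f <- f[vapply(f, function(x) x[5] == "W", logical(1))]
  if (!length(f)) {
    return(data.frame(object = character(), object_beg = numeric(),
                      object_end = numeric(), component_id = character(),
                      component_beg = numeric(), component_end = numeric(),
                      orientation = character()))
  }
  m <- do.call(rbind, f)
  ori <- m[, 9]
  ori[ori %in% c("na", "0")] <- "?"
  data.frame(
    object = m[, 1],
    object_beg = as.numeric(m[, 2]) - 1,
    object_end = as.numeric(m[, 3]),
    component_id = m[, 6],
    component_beg = as.numeric(m[, 7]) - 1,
    component_end = as.numeric(m[, 8]),
    orientation = ori
  )
}

#' Read/write BED3 interval tracks
#'
#' BED uses the same 0-based half-open convention as all in-memory tracks in
#' this package, so no coordinate shift is applied. An optional fourth
#' column (e.g. a transposable-element family) is preserved as `name`.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`.
#' @param path file path.
#' @return `read_bed()` returns a data.frame; `write_bed()` returns `path`
#'   invisibly.
#' @export
write_bed <- function(x, path) {
  iv_check(x)
  cols <- intersect(c("chrom", "start", "end", "name"), names(x))
  utils::write.table(x[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(x) <- c("chrom", "start", "end", "name")[seq_len(ncol(x))]
  x
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
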