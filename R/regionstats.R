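# CNE density profiles around EBRs, the genome-wide 1-kb window scan,
# zero-CNE-window distance statistics, nonparametric group comparisons and
# TE enrichment in EBR-containing windows.

#' CNE density profile in an EBR and four flanking windows
#'
#' Five equal-size windows: two downstream (lower coordinate, labeled `-2`
#' and `-1`), the EBR itself, and two upstream (`+1`, `+2`), each the size
#' of the EBR. Windows extending past the chromosome are unavailable (NA).
#' Window labels follow genomic coordinates: `-` is the lower-coordinate
#' side.
#'
#' @param ebr one-row EBR record (`ref_chrom`, `start`, `end`).
#' @param cne CNE track (`chrom`, `start`, `end`).
#' @param chrom_len length of the EBR's reference chromosome (bp).
#' @return named numeric vector of densities
#'   (`-2`, `-1`, `EBR`, `+1`, `+2`).
#' @export
flank_density_profile <- function(ebr, cne, chrom_len) {
  w <- ebr$end - ebr$start
  if (w <= 0) stop("EBR length 0: extend before profiling")
  starts <- ebr$start + w * (-2:2)
  ends <- starts + w
  dens <- rep(NA_real_, 5)
  ok <- starts >= 0 & ends <= chrom_len
  if (any(ok)) {
    q <- data.frame(chrom = ebr$ref_chrom, start = starts[ok], end = ends[ok])
    dens[ok] <- iv_overlap_bases(q, cne) / w
  }
  names(dens) <- c("-2", "-1", "EBR", "+1", "+2")
  dens
}

#' Genome-wide fixed-width window scan with class labels
#'
#' Chromosomes are tiled with nonoverlapping windows of width `w`
#' (terminal short windows dropped). Each window carries covered, CNE and
#' TE base counts and a class label: `fission_EBR`, `fusion_EBR` or
#' `intra_EBR` if it overlaps an EBR of that type (EBR labels take
#' precedence over msHSB, and interchromosomal labels over `intra`),
#' `msHSB` if it overlaps an msHSB longer than `min_mshsb_bp`, otherwise
#' `rest`. A window is usable iff more than half its bases are covered by
#' sequence data.
#'
#' @param chrom_lengths named reference chromosome lengths.
#' @param cne CNE track; `te` optional TE track; `covered` optional
#'   sequence-coverage track (default: everything covered).
#' @param mshsb msHSB intervals; filtered to `> min_mshsb_bp` before
#'   labeling.
#' @param ebrs classified `ebr_set` (excluded records are ignored; fusion
#'   rows label both their flank and their partner flank).
#' @param w window width (bp).
#' @param min_mshsb_bp msHSB size filter.
#' @return a `window_track`: data.frame (`chrom`, `start`, `end`,
#'   `covered`, `cne_bases`, `te_bases`, `class`, `usable`).
#' @export
window_scan <- function(chrom_lengths, cne, mshsb, ebrs, te = NULL,
                        covered = NULL, w = 1000, min_mshsb_bp = 1.5e6) {
  wins <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    n <- floor(chrom_lengths[ch] / w)
    if (n == 0) return(NULL)
    data.frame(chrom = ch, start = (seq_len(n) - 1) * w, end = seq_len(n) * w)
  }))
  rownames(wins) <- NULL
  wins$covered <- if (is.null(covered)) wins$end - wins$start else
    iv_overlap_bases(wins, covered)
  wins$cne_bases <- iv_overlap_bases(wins, cne)
  wins$te_bases <- if (is.null(te)) 0 else iv_overlap_bases(wins, te)
  wins$class <- "rest"
  ms <- mshsb[(mshsb$end - mshsb$start) > min_mshsb_bp, , drop = FALSE]
  if (nrow(ms)) {
    wins$class[iv_overlap_bases(wins, ms) > 0] <- "msHSB"
  }
  e <- ebrs[!ebrs$excluded, , drop = FALSE]
  lab <- function(sub, label) {
    if (!nrow(sub)) return()
    tr <- data.frame(chrom = sub$ref_chrom, start = sub$start, end = sub$end)
    wins$class[iv_overlap_bases(wins, tr) > 0] <<- label
  }
  # precedence: intra < fusion < fission (interchromosomal labels win)
  lab(e[e$type == "intra", , drop = FALSE], "intra_EBR")
  fus <- e[e$type == "fusion", , drop = FALSE]
  lab(fus, "fusion_EBR")
  if (nrow(fus)) {
    partner <- data.frame(ref_chrom = fus$partner_chrom,
                          start = fus$partner_start, end = fus$partner_end)
    partner <- partner[!is.na(partner$ref_chrom), , drop = FALSE]
    lab(partner, "fusion_EBR")
  }
  lab(e[e$type == "fission", , drop = FALSE], "fission_EBR")
  wins$usable <- wins$covered > w / 2
  class(wins) <- c("window_track", "data.frame")
  wins
}

#' Distances from zero-CNE windows to the nearest high-density window
#'
#' For every usable window with zero CNE bases, the distance (in number of
#' windows, bidirectional minimum within the chromosome) to the nearest
#' usable window whose CNE density reaches `high_density` (typically the
#' mean msHSB density). Zero-windows on chromosomes without any qualifying
#' window are excluded and tallied.
#'
#' @param track a `window_track`.
#' @param high_density qualifying density threshold.
#' @return list with `distances` (data.frame `chrom`, `start`, `class`,
#'   `distance`) and `excluded` (count of zero-windows with no qualifying
#'   window on their chromosome).
#' @export
zero_window_distances <- function(track, high_density) {
  u <- track[track$usable, , drop = FALSE]
  res <- list(); excluded <- 0L
  for (ch in unique(u$chrom)) {
    s <- u[u$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    idx <- s$start / (s$end - s$start)     # window index on the chromosome
    dens <- s$cne_bases / (s$end - s$start)
    zero <- which(s$cne_bases == 0)
    qual <- which(dens >= high_density)
    if (!length(zero)) next
    if (!length(qual)) { excluded <- excluded + length(zero); next }
    d <- vapply(zero, function(i) min(abs(idx[i] - idx[qual])), numeric(1))
    res[[length(res) + 1L]] <- data.frame(
      chrom = ch, start = s$start[zero], class = s$class[zero], distance = d)
  }
  dist <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), start = numeric(), class = character(),
               distance = numeric())
  rownames(dist) <- NULL
  list(distances = dist, excluded = excluded)
}

#' Mean CNE density per window class
#'
#' @param track a `window_track`.
#' @return data.frame (`class`, `n`, `mean_density`).
#' @export
class_densities <- function(track) {
  u <- track[track$usable, , drop = FALSE]
  dens <- u$cne_bases / (u$end - u$start)
  out <- do.call(rbind, lapply(unique(u$class), function(cl) {
    data.frame(class = cl, n = sum(u$class == cl),
               mean_density = mean(dens[u$class == cl]))
  }))
  out[order(out$class), , drop = FALSE]
}

# Exact two-sided Mann-Whitney p by complete enumeration of group
# assignments. U counts pairs (x, y) with x > y, plus 0.5 per tie; the
# two-sided p is the permutation mass at least as far from n1*n2/2 as the
# observed U.
mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  u_of <- function(sel) {
    xs <- pooled[sel]; ys <- pooled[-sel]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  center <- n1 * (n - n1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - center) >= abs(u_obs - center) - 1e-9)
}

#' Compare distance or density samples between window classes
#'
#' Omnibus Kruskal-Wallis test across all groups, followed by all pairwise
#' two-sided Mann-Whitney tests (only when the omnibus p is below `alpha`).
#' Pairwise p-values are exact permutation probabilities (complete
#' enumeration) whenever the enumeration is small enough, and the standard
#' large-sample approximation otherwise; raw and Benjamini-Hochberg
#' adjusted p-values are both reported. Groups with fewer than 2
#' observations are excluded with a warning.
#'
#' @param samples named list of numeric vectors (one per group).
#' @param alpha omnibus significance gate for pairwise testing.
#' @param adjust p-adjustment method (see [stats::p.adjust()]).
#' @param max_enum largest number of enumerated group assignments for the
#'   exact pairwise p.
#' @return a `group_comparison`: list with `groups` (n, median, mean),
#'   `omnibus` (statistic, df, p) and `pairwise` (data.frame with raw and
#'   adjusted p).
#' @export
compare_groups <- function(samples, alpha = 0.05, adjust = "BH",
                           max_enum = 2e5) {
  small <- vapply(samples, length, integer(1)) < 2
  if (any(small)) {
    warning("excluding groups with n < 2: ",
            paste(names(samples)[small], collapse = ", "))
    samples <- samples[!small]
  }
  if (length(samples) < 2) stop("need at least two non-empty groups")
  groups <- data.frame(
    group = names(samples),
    n = vapply(samples, length, integer(1)),
    median = vapply(samples, stats::median, numeric(1)),
    mean = vapply(samples, mean, numeric(1)), row.names = NULL)
  kw <- stats::kruskal.test(samples)
  pairwise <- NULL
  if (kw$p.value < alpha) {
    cmb <- utils::combn(names(samples), 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      a <- samples[[cmb[1, i]]]; b <- samples[[cmb[2, i]]]
      exact <- choose(length(a) + length(b), length(a)) <= max_enum
      p <- if (exact) mw_exact_p(a, b) else
        suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
      data.frame(group1 = cmb[1, i], group2 = cmb[2, i],
                 U = suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$statistic),
                 exact = exact, p = p, row.names = NULL)
    }))
    pairwise$p_adj <- stats::p.adjust(pairwise$p, method = adjust)
  }
  structure(list(groups = groups,
                 omnibus = list(statistic = unname(kw$statistic),
                                df = unname(kw$parameter),
                                p = kw$p.value),
                 pairwise = pairwise, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (Kruskal-Wallis + pairwise Mann-Whitney)\n")
  print(x$groups)
  cat(sprintf("Omnibus: chi-squared = %.3f, df = %d, p = %.3g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p))
  if (!is.null(x$pairwise)) print(x$pairwise)
  else cat(sprintf("(omnibus p >= %.3g: pairwise tests not run)\n", x$alpha))
  invisible(x)
}

#' TE enrichment in EBR-containing windows
#'
#' Tiles the reference with nonoverlapping `window_bp` windows (terminal
#' short windows dropped) and, for each TE family whose elements average
#' more than `min_te_bp`, compares per-window TE density between
#' EBR-containing and EBR-free windows with a Welch t-test, separately for
#' each EBR class present. Raw and BH-adjusted p-values are reported.
#'
#' @param te TE track with family in `name`.
#' @param ebrs classified `ebr_set`.
#' @param chrom_lengths named reference chromosome lengths.
#' @param window_bp window width (bp).
#' @param min_te_bp minimum mean element length per family.
#' @param alpha significance level used for the `significant` flag
#'   (on adjusted p).
#' @return data.frame (`class`, `family`, `n_ebr`, `n_rest`, `mean_ebr`,
#'   `mean_rest`, `t`, `p`, `p_adj`, `significant`).
#' @export
te_enrichment <- function(te, ebrs, chrom_lengths, window_bp = 10000,
                          min_te_bp = 100, alpha = 0.05) {
  wins <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    n <- floor(chrom_lengths[ch] / window_bp)
    if (n == 0) return(NULL)
    data.frame(chrom = ch, start = (seq_len(n) - 1) * window_bp,
               end = seq_len(n) * window_bp)
  }))
  e <- ebrs[!ebrs$excluded, , drop = FALSE]
  classes <- intersect(c("intra", "fusion", "fission"), unique(e$type))
  fams <- unique(te$name)
  out <- list()
  for (fam in fams) {
    el <- te[te$name == fam, , drop = FALSE]
    if (!nrow(el) || mean(el$end - el$start) <= min_te_bp) next
    dens <- iv_overlap_bases(wins, el) / window_bp
    for (cl in classes) {
      sub <- e[e$type == cl, , drop = FALSE]
      tr <- data.frame(chrom = sub$ref_chrom, start = sub$start, end = sub$end)
      if (cl == "fusion") {
        partner <- data.frame(chrom = sub$partner_chrom,
                              start = sub$partner_start,
                              end = sub$partner_end)
        tr <- rbind(tr, partner[!is.na(partner$chrom), , drop = FALSE])
      }
      in_ebr <- iv_overlap_bases(wins, tr) > 0
      if (sum(in_ebr) < 2 || sum(!in_ebr) < 2) next
      tt <- stats::t.test(dens[in_ebr], dens[!in_ebr])
      out[[length(out) + 1L]] <- data.frame(
        class = cl, family = fam, n_ebr = sum(in_ebr), n_rest = sum(!in_ebr),
        mean_ebr = mean(dens[in_ebr]), mean_rest = mean(dens[!in_ebr]),
        t = unname(tt$statistic), p = tt$p.value, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(class = character(), family = character(),
                      n_ebr = integer(), n_rest = integer(),
                      mean_ebr = numeric(), mean_rest = numeric(),
                      t = numeric(), p = numeric(), p_adj = numeric(),
                      significant = logical()))
  }
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj < alpha
  rownames(res) <- NULL
  res
}
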