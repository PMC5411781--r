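# End-to-end orchestration: simulate -> SFs -> PCFs -> verify -> anchor ->
# EBRs -> statistics, driven by one flat config. Every stage consumes only
# files in the output directory and writes its own outputs there, so stages
# are individually re-runnable and the CLI subcommands map 1:1 onto them.

pipeline_defaults <- function() {
  list(
    seed = 42L, mode = "simulate",
    n_chrom = 5L, total_bp = 20e6, mshsb_frac = 0.3,
    n_inversions = 10L, n_fissions = 2L, n_fusions = 3L,
    mean_scaffold_bp = 5e5, min_scaffold_bp = 5e4,
    chimera_rate = 0.05, p_chim_zero = 0.9,
    n_pairs = NA, insert_mean = 3000, insert_sd = 300,
    cne_density_msHSB = 0.11, cne_density_background = 0.02,
    desert_halfwidth_intra = 19000, desert_halfwidth_fusion = 23000,
    desert_halfwidth_fission = 35000,
    spacing_bp = 4e5, position_noise_sd = 0,
    resolution = 150000, min_block_bp = 5000,
    split_mean_bp = 60000, gap_bp = 200, edge_erosion_bp = 15000,
    threshold_c = "calibrate", initial_threshold = 5,
    w_ref = 1, w_out = 1, w_read = 1, join_min = 2,
    window_bp = 1000, te_window_bp = 10000, min_mshsb_bp = 1.5e6,
    alpha = 0.05
  )
}

config_domains <- function() {
  num <- function(lo = -Inf, hi = Inf) list(kind = "numeric", lo = lo, hi = hi)
  list(
    seed = num(), mode = list(kind = "choice", values = c("simulate", "real")),
    n_chrom = num(1), total_bp = num(1), mshsb_frac = num(0, 1),
    n_inversions = num(0), n_fissions = num(0), n_fusions = num(0),
    mean_scaffold_bp = num(1), min_scaffold_bp = num(1),
    chimera_rate = num(0, 1), p_chim_zero = num(0, 1),
    n_pairs = num(0), insert_mean = num(1), insert_sd = num(0),
    cne_density_msHSB = num(0, 1), cne_density_background = num(0, 1),
    desert_halfwidth_intra = num(0), desert_halfwidth_fusion = num(0),
    desert_halfwidth_fission = num(0),
    spacing_bp = num(1), position_noise_sd = num(0),
    resolution = num(1), min_block_bp = num(0),
    split_mean_bp = num(1), gap_bp = num(0), edge_erosion_bp = num(0),
    threshold_c = list(kind = "threshold"), initial_threshold = num(0),
    w_ref = num(0), w_out = num(0), w_read = num(0), join_min = num(0),
    window_bp = num(1), te_window_bp = num(1), min_mshsb_bp = num(0),
    alpha = num(0, 1)
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list, fills in defaults, and checks
#' every key against its documented domain. All violations are collected
#' and reported together (never fail-fast on the first).
#'
#' @param config file path or named list.
#' @param action `"error"` (stop listing all violations) or `"list"`
#'   (return the character vector of violations).
#' @return a validated `run_config` list (or, with `action = "list"`, a
#'   character vector of violations, empty if valid).
#' @export
validate_config <- function(config = list(), action = c("error", "list")) {
  action <- match.arg(action)
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  domains <- config_domains()
  bad <- character()
  unknown <- setdiff(names(config), names(domains))
  if (length(unknown)) {
    bad <- c(bad, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(pipeline_defaults(),
                           config[intersect(names(config), names(domains))])
  for (key in names(domains)) {
    d <- domains[[key]]
    v <- cfg[[key]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) next
    ok <- switch(d$kind,
      numeric = is.numeric(v) && length(v) == 1 && v >= d$lo && v <= d$hi,
      choice = is.character(v) && v %in% d$values,
      threshold = (is.numeric(v) && v >= 0) || identical(v, "calibrate"))
    if (!ok) {
      dom <- switch(d$kind,
        numeric = sprintf("numeric in [%g, %g]", d$lo, d$hi),
        choice = paste(d$values, collapse = "|"),
        threshold = "non-negative number or \"calibrate\"")
      bad <- c(bad, sprintf("%s: value %s outside domain (%s)", key,
                            paste(format(v), collapse = ","), dom))
    }
  }
  if (action == "list") return(bad)
  if (length(bad)) {
    stop("invalid configuration:\n  ", paste(bad, collapse = "\n  "))
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

stage_seed <- function(cfg, k) (as.integer(cfg$seed) + k) %% .Machine$integer.max

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Pipeline stage: simulate all inputs
#'
#' Generates the ancestor, the rearranged descendant with truth, shredded
#' scaffolds with chimeras and read pairs, feature tracks, probes and the
#' cytogenetic map, plus the alignment-block tables downstream stages
#' consume. All outputs are plain-text files in `outdir`.
#'
#' @param cfg a validated `run_config`.
#' @param outdir output directory (created if needed).
#' @return named list of per-output record counts, invisibly.
#' @export
stage_simulate <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  anc <- sim_ancestor(cfg$n_chrom, cfg$total_bp, cfg$mshsb_frac,
                      seed = stage_seed(cfg, 1))
  plan <- random_plan(anc, cfg$n_inversions, cfg$n_fissions, cfg$n_fusions,
                      seed = stage_seed(cfg, 2))
  des <- apply_rearrangements(anc, plan)
  shred <- shred_to_scaffolds(
    des, mean_scaffold_bp = cfg$mean_scaffold_bp,
    min_scaffold_bp = cfg$min_scaffold_bp, chimera_rate = cfg$chimera_rate,
    coverage = list(n_pairs = if (is.na(cfg$n_pairs)) NULL else cfg$n_pairs,
                    insert_mean = cfg$insert_mean, insert_sd = cfg$insert_sd),
    p_chim_zero = cfg$p_chim_zero, seed = stage_seed(cfg, 3))
  tracks <- simulate_feature_tracks(
    anc, des$ebrs, cfg$cne_density_msHSB, cfg$cne_density_background,
    desert_halfwidth_bp = c(intra = cfg$desert_halfwidth_intra,
                            fusion = cfg$desert_halfwidth_fusion,
                            fission = cfg$desert_halfwidth_fission),
    seed = stage_seed(cfg, 4))
  probes <- plant_probes(des$chrom_lengths, spacing_bp = cfg$spacing_bp,
                         position_noise_sd = cfg$position_noise_sd,
                         seed = stage_seed(cfg, 5))
  blocks <- sim_alignment_blocks(shred$scaffold_map, des$karyotype,
                                 split_mean_bp = cfg$split_mean_bp,
                                 gap_bp = cfg$gap_bp,
                                 edge_erosion_bp = cfg$edge_erosion_bp,
                                 seed = stage_seed(cfg, 6))

  write_tsv(data.frame(chrom = names(anc$chrom_lengths),
                       length = unname(anc$chrom_lengths)),
            file.path(outdir, "ancestor_lengths.tsv"))
  write_bed(anc$mshsb, file.path(outdir, "mshsb.bed"))
  write_tsv(des$karyotype, file.path(outdir, "karyotype.tsv"))
  write_tsv(data.frame(chrom = names(des$chrom_lengths),
                       length = unname(des$chrom_lengths)),
            file.path(outdir, "descendant_lengths.tsv"))
  write_tsv(des$ebrs, file.path(outdir, "truth_ebrs.tsv"))
  write_tsv(shred$scaffolds, file.path(outdir, "scaffolds.tsv"))
  write_tsv(shred$scaffold_map, file.path(outdir, "scaffold_map.tsv"))
  write_tsv(shred$read_pairs, file.path(outdir, "read_pairs.tsv"))
  write_tsv(shred$joints, file.path(outdir, "truth_joints.tsv"))
  write_bed(tracks$cne, file.path(outdir, "cne.bed"))
  write_bed(tracks$ce, file.path(outdir, "ce.bed"))
  write_bed(tracks$te, file.path(outdir, "te.bed"))
  write_tsv(probes$probes[, c("probe_id", "chrom", "start", "end", "center")],
            file.path(outdir, "probes.tsv"))
  write_tsv(probes$map, file.path(outdir, "probe_map.tsv"))
  write_tsv(probes$truth, file.path(outdir, "probe_truth.tsv"))
  write_tsv(blocks, file.path(outdir, "blocks.tsv"))
  log_stage("simulate", "%d descendant chromosomes, %d scaffolds, %d read pairs, %d planted breakpoint records",
            length(des$chrom_lengths), nrow(shred$scaffolds),
            nrow(shred$read_pairs), nrow(des$ebrs))
  invisible(list(chromosomes = length(des$chrom_lengths),
                 scaffolds = nrow(shred$scaffolds),
                 read_pairs = nrow(shred$read_pairs),
                 truth_breakpoints = nrow(des$ebrs),
                 chimeric_joints = nrow(shred$joints)))
}

#' Pipeline stage: syntenic fragment detection
#'
#' @inheritParams stage_simulate
#' @return counts, invisibly.
#' @export
stage_sf <- function(cfg, outdir) {
  blocks <- read_tsv(file.path(outdir, "blocks.tsv"))
  sfs <- detect_sfs(blocks, cfg$resolution, cfg$min_block_bp)
  write_tsv(as.data.frame(sfs), file.path(outdir, "sfs.tsv"))
  log_stage("sf", "%d SFs from %d blocks on %d scaffolds",
            nrow(sfs), nrow(blocks), length(unique(sfs$target_seq)))
  invisible(list(blocks = nrow(blocks), sfs = nrow(sfs)))
}

read_sfs <- function(outdir, cfg) {
  sfs <- read_tsv(file.path(outdir, "sfs.tsv"))
  structure(sfs, resolution = cfg$resolution, class = c("sf_set", "data.frame"))
}

#' Pipeline stage: initial PCF construction
#'
#' The simulated outgroup shares the ancestral chromosome order, so the
#' reference-side SF table doubles as the outgroup evidence.
#'
#' @inheritParams stage_simulate
#' @return counts, invisibly.
#' @export
stage_pcf <- function(cfg, outdir) {
  sfs <- read_sfs(outdir, cfg)
  pairs <- read_tsv(file.path(outdir, "read_pairs.tsv"))
  thr <- if (identical(cfg$threshold_c, "calibrate")) cfg$initial_threshold
         else cfg$threshold_c
  res <- build_pcfs(sfs, outgroup_sfs = sfs, read_pairs = pairs,
                    threshold_c = thr,
                    weights = c(ref = cfg$w_ref, out = cfg$w_out,
                                read = cfg$w_read),
                    join_min = cfg$join_min)
  write_tsv(as.data.frame(res$pcfs), file.path(outdir, "pcfs_initial.tsv"))
  write_tsv(res$joints, file.path(outdir, "joints.tsv"))
  pcfs_to_agp(res$pcfs, file.path(outdir, "pcfs_initial.agp"))
  st <- assembly_stats(res$pcfs)
  log_stage("pcf", "%d PCFs (N50 %.2f Mb), %d split joints at threshold %g",
            st$count, st$n50 / 1e6, nrow(res$joints), thr)
  invisible(list(pcfs = st$count, n50 = st$n50, joints = nrow(res$joints)))
}

#' Pipeline stage: joint verification and threshold calibration
#'
#' Narrows split-joint gaps with the fine block table, obtains verification
#' outcomes (simulated against truth in simulate mode), calibrates the
#' physical-coverage threshold from them, rebuilds PCFs at the calibrated
#' threshold and refines them with the verification statuses.
#'
#' @inheritParams stage_simulate
#' @return counts, invisibly.
#' @export
stage_verify <- function(cfg, outdir) {
  joints <- read_tsv(file.path(outdir, "joints.tsv"))
  blocks <- read_tsv(file.path(outdir, "blocks.tsv"))
  joints <- find_split_joints(joints, blocks)
  truth <- read_tsv(file.path(outdir, "truth_joints.tsv"))
  joints <- simulate_verification(joints, truth, seed = stage_seed(cfg, 7))
  thr <- if (identical(cfg$threshold_c, "calibrate")) {
    tested <- joints[joints$status != "untested", , drop = FALSE]
    if (nrow(tested)) calibrate_threshold(tested) else cfg$initial_threshold
  } else cfg$threshold_c
  writeLines(format(thr), file.path(outdir, "calibrated_threshold.txt"))
  sfs <- read_sfs(outdir, cfg)
  pairs <- read_tsv(file.path(outdir, "read_pairs.tsv"))
  res <- build_pcfs(sfs, outgroup_sfs = sfs, read_pairs = pairs,
                    threshold_c = thr,
                    weights = c(ref = cfg$w_ref, out = cfg$w_out,
                                read = cfg$w_read),
                    join_min = cfg$join_min)
  # carry verification outcomes over to the rebuilt joints
  res$joints <- find_split_joints(res$joints, blocks)
  res$joints$status <- rep("untested", nrow(res$joints))
  for (k in seq_len(nrow(res$joints))) {
    hit <- joints$scaffold == res$joints$scaffold[k] &
      joints$gap_start0 <= res$joints$gap_end0[k] &
      joints$gap_end0 >= res$joints$gap_start0[k] &
      joints$status != "untested"
    if (any(hit)) res$joints$status[k] <- joints$status[which(hit)[1]]
  }
  refined <- refine_pcfs(res$pcfs, res$joints)
  write_tsv(as.data.frame(refined), file.path(outdir, "pcfs_refined.tsv"))
  write_tsv(res$joints, file.path(outdir, "joints_verified.tsv"))
  pcfs_to_agp(refined, file.path(outdir, "pcfs_refined.agp"))
  st <- assembly_stats(refined)
  log_stage("verify", "threshold %g; %d refined PCFs (N50 %.2f Mb)",
            thr, st$count, st$n50 / 1e6)
  invisible(list(threshold = thr, pcfs = st$count, n50 = st$n50,
                 tested = sum(joints$status != "untested"),
                 confirmed = sum(joints$status == "confirmed"),
                 refuted = sum(joints$status %in%
                                 c("refuted", "alternative_confirmed"))))
}

read_pcfs <- function(path) {
  p <- read_tsv(path)
  class(p) <- c("pcf_set", "data.frame")
  p
}

#' Map probes to positions within PCFs
#'
#' Composes true probe positions on descendant chromosomes with the
#' scaffold map and PCF membership (in real-input mode this table would
#' come from aligning probe sequences to the PCFs).
#'
#' @param probe_truth data.frame (`probe_id`, `chrom`, `true_pos`).
#' @param scaffold_map scaffold-fragment table from [shred_to_scaffolds()].
#' @param pcfs a `pcf_set`.
#' @return data.frame (`probe_id`, `pcf_id`, `pcf_pos`).
#' @export
probe_pcf_alignments <- function(probe_truth, scaffold_map, pcfs) {
  offs <- do.call(rbind, lapply(unique(pcfs$pcf_id), function(pid) {
    m <- pcfs[pcfs$pcf_id == pid, , drop = FALSE]
    m <- m[order(m$member_index), , drop = FALSE]
    len <- m$s_end - m$s_start
    m$offset <- cumsum(len) - len
    m
  }))
  out <- list()
  for (k in seq_len(nrow(probe_truth))) {
    pos <- probe_truth$true_pos[k]
    fr <- scaffold_map[scaffold_map$der_chrom == probe_truth$chrom[k] &
                         scaffold_map$der_start <= pos &
                         scaffold_map$der_end > pos, , drop = FALSE]
    if (!nrow(fr)) next
    fr <- fr[1, ]
    s_pos <- if (fr$strand == "+") fr$scaf_start + (pos - fr$der_start)
             else fr$scaf_start + (fr$der_end - pos)
    mem <- offs[offs$scaffold == fr$scaffold & offs$s_start <= s_pos &
                  offs$s_end > s_pos, , drop = FALSE]
    if (!nrow(mem)) next
    mem <- mem[1, ]
    pcf_pos <- if (mem$orientation == "-") mem$offset + (mem$s_end - s_pos)
               else mem$offset + (s_pos - mem$s_start)
    out[[length(out) + 1L]] <- data.frame(
      probe_id = probe_truth$probe_id[k], pcf_id = mem$pcf_id,
      pcf_pos = pcf_pos, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pipeline stage: anchor PCFs to chromosomes
#'
#' Assigns PCFs to chromosomes by probe majority, splits interchromosomal
#' conflicts at their weakest internal junction, re-assigns, then orders
#' and orients along each chromosome.
#'
#' @inheritParams stage_simulate
#' @return counts, invisibly.
#' @export
stage_anchor <- function(cfg, outdir) {
  map_path <- file.path(outdir, "probe_map.tsv")
  if (!file.exists(map_path)) {
    log_stage("anchor", "no probe map found; anchoring skipped")
    return(invisible(list(skipped = TRUE)))
  }
  pcfs <- read_pcfs(file.path(outdir, "pcfs_refined.tsv"))
  smap <- read_tsv(file.path(outdir, "scaffold_map.tsv"))
  ptruth <- read_tsv(file.path(outdir, "probe_truth.tsv"))
  cmap <- read_tsv(map_path)
  joints <- read_tsv(file.path(outdir, "joints_verified.tsv"))

  align <- probe_pcf_alignments(ptruth, smap, pcfs)
  asg <- assign_pcfs(align, cmap)
  if (length(asg$conflicts)) {
    log_stage("anchor", "%d interchromosomal conflict(s): splitting",
              length(asg$conflicts))
    pcfs <- refine_pcfs(pcfs, joints, map_conflicts = asg$conflicts)
    align <- probe_pcf_alignments(ptruth, smap, pcfs)
    asg <- assign_pcfs(align, cmap)
  }
  ok <- asg$assignments[!asg$assignments$conflict & !is.na(asg$assignments$chrom), ,
                        drop = FALSE]
  builds <- order_and_orient(ok, align, cmap, pcf_lengths(pcfs),
                             on_interleave = "warn")
  write_tsv(as.data.frame(pcfs), file.path(outdir, "pcfs_final.tsv"))
  write_tsv(as.data.frame(builds), file.path(outdir, "chromosome_builds.tsv"))
  builds_to_agp(builds, file.path(outdir, "chromosomes.agp"))
  total <- sum(pcf_lengths(pcfs))
  st <- placement_stats(builds, total)
  write_tsv(st$per_chromosome, file.path(outdir, "placement_stats.tsv"))
  log_stage("anchor", "%d PCFs placed on %d chromosomes (%.1f%% of assembly, %.2f Mb oriented)",
            nrow(builds), length(unique(builds$chrom)),
            100 * st$placed_fraction, st$oriented_bp / 1e6)
  invisible(list(placed = nrow(builds), placed_fraction = st$placed_fraction,
                 oriented_bp = st$oriented_bp,
                 conflicts = length(asg$conflicts)))
}

# Chromosome-level alignment blocks implied by the anchored builds:
# compose build order/orientation with member scaffold intervals and the
# scaffold-level alignment blocks.
build_chrom_blocks <- function(builds, pcfs, blocks) {
  out <- list()
  for (ch in unique(builds$chrom)) {
    b <- builds[builds$chrom == ch, , drop = FALSE]
    b <- b[order(b$position), , drop = FALSE]
    offset <- 0
    for (i in seq_len(nrow(b))) {
      m <- pcfs[pcfs$pcf_id == b$pcf_id[i], , drop = FALSE]
      m <- m[order(m$member_index), , drop = FALSE]
      flip <- identical(b$orientation[i], "-")
      if (flip) {
        m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
        m$orientation <- c("+" = "-", "-" = "+", "?" = "?")[m$orientation]
      }
      len <- m$s_end - m$s_start
      moff <- offset + cumsum(len) - len
      for (j in seq_len(nrow(m))) {
        bl <- blocks[blocks$target_seq == m$scaffold[j] &
                       blocks$t_start < m$s_end[j] &
                       blocks$t_end > m$s_start[j], , drop = FALSE]
        if (!nrow(bl)) next
        bl$t_start <- pmax(bl$t_start, m$s_start[j])
        bl$t_end <- pmin(bl$t_end, m$s_end[j])
        fwd <- m$orientation[j] != "-"
        if (fwd) {
          cs <- moff[j] + (bl$t_start - m$s_start[j])
          ce <- moff[j] + (bl$t_end - m$s_start[j])
          strand <- bl$strand
        } else {
          cs <- moff[j] + (m$s_end[j] - bl$t_end)
          ce <- moff[j] + (m$s_end[j] - bl$t_start)
          strand <- ifelse(bl$strand == "+", "-", "+")
        }
        out[[length(out) + 1L]] <- data.frame(
          target_seq = ch, t_start = cs, t_end = ce,
          ref_chrom = bl$ref_chrom, r_start = bl$r_start, r_end = bl$r_end,
          strand = strand, identity = 1, stringsAsFactors = FALSE)
      }
      offset <- offset + sum(len)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pipeline stage: EBR detection and classification
#'
#' Builds the homeology map between the anchored chromosomes and the
#' reference, then detects and classifies EBRs. Falls back to the refined
#' PCFs as pseudo-chromosomes when no anchoring is available.
#'
#' @inheritParams stage_simulate
#' @return counts, invisibly.
#' @export
stage_ebr <- function(cfg, outdir) {
  blocks <- read_tsv(file.path(outdir, "blocks.tsv"))
  builds_path <- file.path(outdir, "chromosome_builds.tsv")
  pcfs_path <- if (file.exists(file.path(outdir, "pcfs_final.tsv"))) {
    file.path(outdir, "pcfs_final.tsv")
  } else file.path(outdir, "pcfs_refined.tsv")
  pcfs <- read_pcfs(pcfs_path)
  if (file.exists(builds_path)) {
    builds <- read_tsv(builds_path)
    cblocks <- build_chrom_blocks(builds, pcfs, blocks)
  } else {
    log_stage("ebr", "no chromosome builds; using PCFs as pseudo-chromosomes")
    fake <- data.frame(chrom = unique(pcfs$pcf_id),
                       position = 1, pcf_id = unique(pcfs$pcf_id),
                       orientation = "+")
    cblocks <- build_chrom_blocks(fake, pcfs, blocks)
  }
  anc_len <- read_tsv(file.path(outdir, "ancestor_lengths.tsv"))
  lens <- stats::setNames(anc_len$length, anc_len$chrom)
  map <- build_homeology_map(cblocks, cfg$resolution)
  ebrs <- detect_ebrs(map, chrom_lengths = lens)
  ebrs <- classify_ebrs(ebrs, map)
  write_tsv(as.data.frame(map), file.path(outdir, "homeology_map.tsv"))
  write_tsv(as.data.frame(ebrs), file.path(outdir, "ebrs.tsv"))
  counts <- ebr_event_counts(ebrs)
  log_stage("ebr", "%d EBR records: %d intra events, %d fusions, %d fissions",
            nrow(ebrs), counts[["intra_events"]], counts[["fusion"]],
            counts[["fission"]])
  invisible(as.list(counts))
}

#' Pipeline stage: CNE/TE density statistics
#'
#' Runs the 1-kb window scan, per-class CNE densities, zero-CNE-window
#' distance statistics with group comparisons, and TE enrichment.
#'
#' @inheritParams stage_simulate
#' @return summary list, invisibly.
#' @export
stage_stats <- function(cfg, outdir) {
  anc_len <- read_tsv(file.path(outdir, "ancestor_lengths.tsv"))
  lens <- stats::setNames(anc_len$length, anc_len$chrom)
  cne <- read_bed(file.path(outdir, "cne.bed"))
  te <- read_bed(file.path(outdir, "te.bed"))
  mshsb <- read_bed(file.path(outdir, "mshsb.bed"))
  ebrs <- read_tsv(file.path(outdir, "ebrs.tsv"))
  class(ebrs) <- c("ebr_set", "data.frame")
  track <- window_scan(lens, cne, mshsb, ebrs, te = te, w = cfg$window_bp,
                       min_mshsb_bp = cfg$min_mshsb_bp)
  dens <- class_densities(track)
  u <- track[track$usable & track$class == "msHSB", , drop = FALSE]
  ms_mean <- mean(u$cne_bases / (u$end - u$start))
  zw <- zero_window_distances(track, ms_mean)
  cls <- split(zw$distances$distance, zw$distances$class)
  cmp <- if (sum(vapply(cls, length, integer(1)) >= 2) >= 2) {
    compare_groups(cls[vapply(cls, length, integer(1)) >= 2], alpha = cfg$alpha)
  } else NULL
  tee <- te_enrichment(te, ebrs, lens, window_bp = cfg$te_window_bp,
                       alpha = cfg$alpha)
  write_tsv(as.data.frame(track), file.path(outdir, "windows.tsv"))
  write_tsv(dens, file.path(outdir, "class_densities.tsv"))
  write_tsv(zw$distances, file.path(outdir, "zero_window_distances.tsv"))
  write_tsv(tee, file.path(outdir, "te_enrichment.tsv"))
  if (!is.null(cmp)) {
    write_tsv(cmp$pairwise %||% data.frame(), file.path(outdir, "distance_tests.tsv"))
  }
  med <- vapply(cls, stats::median, numeric(1))
  log_stage("stats", "msHSB mean CNE density %.3f; median zero-window distances: %s",
            ms_mean, paste(sprintf("%s=%.1f", names(med), med), collapse = " "))
  invisible(list(class_densities = dens, mshsb_mean_density = ms_mean,
                 median_distances = as.list(med),
                 omnibus_p = if (!is.null(cmp)) cmp$omnibus$p else NA,
                 te = tee, excluded_zero_windows = zw$excluded))
}

#' Run the whole pipeline
#'
#' Executes simulate, sf, pcf, verify, anchor, ebr and stats in order.
#' A stage failure marks the stage in the report and skips downstream
#' stages. With a fixed seed the run is deterministic: identical configs
#' reproduce identical artifacts.
#'
#' @param config a `run_config`, a named list, or a YAML path (validated
#'   with [validate_config()]).
#' @param outdir output directory.
#' @return a `run_report` (also written to `run_report.json`).
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  stages <- if (identical(cfg$mode, "simulate")) {
    c("simulate", "sf", "pcf", "verify", "anchor", "ebr", "stats")
  } else c("sf", "pcf", "verify", "anchor", "ebr", "stats")
  t0 <- Sys.time()
  report <- list(seed = cfg$seed, config = unclass(cfg), stages = list(),
                 package_version = as.character(utils::packageVersion("chromforge")),
                 r_version = R.version.string)
  failed <- FALSE
  for (st in stages) {
    if (failed) {
      report$stages[[st]] <- list(status = "skipped")
      next
    }
    fn <- switch(st, simulate = stage_simulate, sf = stage_sf,
                 pcf = stage_pcf, verify = stage_verify,
                 anchor = stage_anchor, ebr = stage_ebr, stats = stage_stats)
    res <- tryCatch(fn(cfg, outdir), error = function(e) e)
    if (inherits(res, "error")) {
      log_stage(st, "FAILED: %s", conditionMessage(res))
      report$stages[[st]] <- list(status = "failed",
                                  error = conditionMessage(res))
      failed <- TRUE
    } else {
      report$stages[[st]] <- c(list(status = "ok"), res)
    }
  }
  report$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(report) <- c("run_report", "list")
  writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, force = TRUE),
             file.path(outdir, "run_report.json"))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("chromforge run (seed %s, %.1f s)\n", x$seed, x$wall_time_s))
  for (st in names(x$stages)) {
    s <- x$stages[[st]]
    extra <- setdiff(names(s), "status")
    cat(sprintf("  %-9s %s", st, s$status))
    if (length(extra)) {
      vals <- vapply(extra, function(k) {
        v <- s[[k]]
        if (is.numeric(v) && length(v) == 1) sprintf("%s=%g", k, v) else ""
      }, character(1))
      cat(" ", paste(vals[nzchar(vals)], collapse = " "))
    }
    cat("\n")
  }
  invisible(x)
}
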