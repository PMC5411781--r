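# Builds a synthetic anchoring scenario: chromosomes carrying ordered,
# oriented PCFs; probes at known positions inside each PCF; a noise-free
# cytogenetic map listing probes in true chromosomal order.
make_anchor_case <- function(n_chrom = 5, seed = 1, probes_per_pcf = 3,
                             single_probe_pcfs = 0) {
  set.seed(seed)
  align <- list(); map <- list(); truth <- list()
  pid <- 0
  for (c_i in seq_len(n_chrom)) {
    ch <- sprintf("chr%02d", c_i)
    n_pcf <- sample(2:4, 1)
    order_idx <- 0
    for (p_i in seq_len(n_pcf)) {
      pid <- pid + 1
      pcf <- sprintf("PCF_%03d", pid)
      len <- sample(2e6:6e6, 1)
      ori <- sample(c("+", "-"), 1)
      np <- if (single_probe_pcfs > 0 && p_i == 1) 1 else probes_per_pcf
      pos <- sort(sample.int(len - 1, np))
      for (q in seq_len(np)) {
        order_idx <- order_idx + 1
        probe <- sprintf("%s_%02d_%02d", ch, p_i, q)
        # map order follows chromosome direction; a '-' PCF contributes its
        # probes in reversed internal order
        align[[length(align) + 1L]] <- data.frame(
          probe_id = probe, pcf_id = pcf,
          pcf_pos = if (ori == "+") pos[q] else len - pos[q],
          stringsAsFactors = FALSE)
        map[[length(map) + 1L]] <- data.frame(
          chrom = ch, order_index = order_idx, probe_id = probe,
          map_position = order_idx, stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = ch, position = p_i, pcf_id = pcf, orientation = ori,
        length = len, n_probes = np, stringsAsFactors = FALSE)
    }
  }
  map <- do.call(rbind, map)
  map$map_position <- stats::ave(map$map_position, map$chrom,
                                 FUN = function(x) x / max(x))
  list(align = do.call(rbind, align), map = map,
       truth = do.call(rbind, truth))
}

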