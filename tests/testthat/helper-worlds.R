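# Shared simulated worlds for the test suite. Heavy worlds are built once
# per test run and memoised here.

.world_cache <- new.env(parent = emptyenv())

# Full 1,000-clone world: simulate, fingerprint, filter, net, Q-removal,
# adaptive clustering, plus the ground-truth partition.
build_world <- function(seed, noisy, coverage) {
  key <- paste(seed, noisy, coverage)
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  cfg <- desk_config(seed = seed, noisy = noisy, coverage = coverage)
  arm <- do.call(simulate_arm, c(cfg$arm, list(seed = cfg$seed)))
  clones <- do.call(sample_clone_library,
                    c(list(arm = arm), cfg$library, list(seed = cfg$seed + 1)))
  noise <- do.call(noise_model, c(cfg$noise, list(seed = cfg$seed + 2)))
  filt <- filter_bands(fingerprint_library(clones, arm, noise))
  acfg <- do.call(assembly_config, cfg$assembly)
  net <- build_net(filt$fingerprints, acfg)
  q <- remove_q_elements(net, acfg)
  asm <- adaptive_cluster(q$net, acfg)
  part <- assembly_partition(asm, all_clones = clones$clone_id)
  truth <- true_partition(clones, detectable_overlap_kb(arm, noise, acfg))
  res <- list(cfg = cfg, arm = arm, clones = clones, noise = noise,
              filt = filt, acfg = acfg, net = net, q = q, asm = asm,
              part = part, truth = truth)
  .world_cache[[key]] <- res
  res
}

# Canonical single-contig world: 50 clones tiling one island at ~12.6x.
build_contig50 <- function(seed) {
  arm <- simulate_arm(arm_length_kb = 710, mean_fragment_kb = 2, seed = seed)
  clones <- sample_clone_library(arm, 50, purity = 1, seed = seed + 100)
  filt <- filter_bands(fingerprint_library(clones, arm, no_noise(seed = seed + 200)))
  acfg <- assembly_config()
  net <- build_net(filt$fingerprints, acfg)
  asm <- adaptive_cluster(net, acfg)
  list(arm = arm, clones = clones, net = net, asm = asm, acfg = acfg)
}

# Noise-free world with planted chimeric clones bridging distinct,
# well-separated region pairs (one chimera per region pair; shared region
# pairs would hide each other from bridge detection).
build_chimera_world <- function(seed, n_chim = 10) {
  cfg <- desk_config(seed = seed, noisy = FALSE, coverage = "standard")
  arm <- do.call(simulate_arm, c(cfg$arm, list(seed = cfg$seed)))
  clones <- do.call(sample_clone_library,
                    c(list(arm = arm), cfg$library, list(seed = cfg$seed + 1)))
  fps <- fingerprint_library(clones, arm, no_noise(seed = cfg$seed + 2))
  # two region slots per clonable segment, at 1/4 and 3/4 of the segment
  gz <- arm$gap_zones
  bounds <- c(0, as.vector(t(gz)), arm$arm_length_kb)
  segs <- matrix(bounds, ncol = 2, byrow = TRUE)
  slots <- c(segs[, 1] + (segs[, 2] - segs[, 1]) / 4,
             segs[, 1] + 3 * (segs[, 2] - segs[, 1]) / 4)
  set.seed(seed + 500)
  pick <- sample(slots, 2 * n_chim)
  chim_ids <- sprintf("CHIM%02d", seq_len(n_chim))
  profs <- fps$profiles
  for (k in seq_len(n_chim)) {
    h1 <- fragments_in_interval(arm, pick[2 * k - 1], pick[2 * k - 1] + 71.5)
    h2 <- fragments_in_interval(arm, pick[2 * k], pick[2 * k] + 71.5)
    profs[[chim_ids[k]]] <- sort(arm$band_codes[c(h1, h2)])
  }
  filt <- filter_bands(fingerprint_set(profs, "chimera world"))
  acfg <- do.call(assembly_config, cfg$assembly)
  net <- build_net(filt$fingerprints, acfg)
  q <- remove_q_elements(net, acfg)
  list(chim_ids = chim_ids, q = q, net = net)
}

# Build a synthetic laid-out contig + net directly from clone spans, for
# interval-cover tests: band counts proportional to span lengths.
layout_from_spans <- function(starts, ends, net_edges_all = TRUE) {
  n <- length(starts)
  ids <- sprintf("SP%02d", seq_len(n))
  len <- ends - starts
  nb <- setNames(as.integer(round(len)), ids)
  edges <- NULL
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      ov <- min(ends[i], ends[j]) - max(starts[i], starts[j])
      if (ov > 0) {
        edges <- rbind(edges, data.frame(
          a = ids[i], b = ids[j], shared = as.integer(round(ov)),
          sulston_p = 1e-20, stringsAsFactors = FALSE))
      }
    }
  }
  cfg <- assembly_config(insert_mean_kb = mean(len))
  net <- structure(list(clones = ids, n_bands = nb,
                        edges = edges, sub_edges = edges[0, ],
                        retention = 1, cutoff = cfg$net_cutoff, cfg = cfg),
                   class = "overlap_net")
  layout <- structure(list(contig_id = "SYN1", clones = ids[order(starts)],
                           coord_kb = setNames(starts[order(starts)] - min(starts),
                                               ids[order(starts)]),
                           length_kb = max(ends) - min(starts),
                           depth = n * mean(len) / (max(ends) - min(starts)),
                           linear = TRUE, branching_clones = character(0)),
                      class = "contig_layout")
  list(layout = layout, net = net, ids = ids, cfg = cfg)
}

# Table of printed per-bin gene content used by the gene-space tests
# (counts, densities and cumulative mapped lengths of the four deletion
# bins, centromere outward).
printed_gene_table <- function() {
  data.frame(
    bin = c("0-0.63", "0.63-0.67", "0.67-0.78", "0.78-1.00"),
    syntenic_n = c(131, 44, 13, 20),
    syntenic_density = c(1.80, 1.48, 1.64, 0.75),
    nonsyntenic_n = c(100, 61, 28, 75),
    nonsyntenic_density = c(1.37, 2.05, 3.53, 2.83),
    total_n = c(231, 105, 41, 95),
    total_density = c(3.17, 3.53, 5.17, 3.58),
    islands_n = c(192, 83, 33, 79),
    islands_density = c(2.63, 2.79, 4.16, 2.98),
    isolated_n = c(39, 22, 8, 16),
    isolated_density = c(0.53, 0.74, 1.01, 0.60),
    length_mb = c(72.92, 29.71, 7.93, 26.54),
    stringsAsFactors = FALSE
  )
}
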