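#' Map-level assembly statistics
#'
#' N50 is the length of the contig at which the cumulative sum of contig
#' lengths, taken in descending order, first reaches half the total; L50 is
#' the number of contigs needed to do so.
#'
#' @param contig_lengths_kb numeric vector of contig lengths (kb).
#' @param arm_length_kb optional arm length for the coverage fraction.
#' @param n_markers optional marker count for marker density.
#' @param anchored_lengths_kb optional lengths of anchored contigs.
#' @return object of class `map_stats`: `n_contigs`, `total_kb`,
#'   `average_kb`, `longest_kb`, `n_over_1mb`, `n50_kb`, `l50`,
#'   `coverage_fraction`, `markers_per_mb`, `anchored_fraction`.
#' @export
compute_map_stats <- function(contig_lengths_kb, arm_length_kb = NULL,
                              n_markers = NULL, anchored_lengths_kb = NULL) {
  if (!length(contig_lengths_kb)) stop("no contigs", call. = FALSE)
  len <- sort(contig_lengths_kb, decreasing = TRUE)
  total <- sum(len)
  cum <- cumsum(len)
  l50 <- which(cum >= total / 2)[1]
  structure(list(
    n_contigs = length(len),
    total_kb = total,
    average_kb = total / length(len),
    longest_kb = len[1],
    n_over_1mb = sum(len > 1000),
    n50_kb = len[l50],
    l50 = l50,
    coverage_fraction = if (is.null(arm_length_kb)) NA_real_ else total / arm_length_kb,
    markers_per_mb = if (is.null(n_markers)) NA_real_ else n_markers / (total / 1000),
    anchored_fraction = if (is.null(anchored_lengths_kb)) NA_real_ else
      sum(anchored_lengths_kb) / total
  ), class = "map_stats")
}

#' @export
print.map_stats <- function(x, ...) {
  cat(sprintf("map_stats: %d contigs, %.0f kb total (avg %.0f kb, longest %.0f kb)\n",
              x$n_contigs, x$total_kb, x$average_kb, x$longest_kb))
  cat(sprintf("  N50 %.0f kb (L50 %d); %d contigs > 1 Mb\n",
              x$n50_kb, x$l50, x$n_over_1mb))
  if (!is.na(x$coverage_fraction))
    cat(sprintf("  arm coverage %.1f%%\n", 100 * x$coverage_fraction))
  if (!is.na(x$markers_per_mb))
    cat(sprintf("  marker density %.1f/Mb\n", x$markers_per_mb))
  if (!is.na(x$anchored_fraction))
    cat(sprintf("  anchored fraction of length %.1f%%\n", 100 * x$anchored_fraction))
  invisible(x)
}

#' Desk-scale pipeline configuration
#'
#' A scaled-down stated world preserving the statistical regime of a
#' chromosome-arm project: 1,000 clones of 143 +- 25 kb at 88 % purity over
#' a 12.25 Mb arm with 15 unclonable zones of 150 kb (clonable 10 Mb,
#' target coverage 12.6x). `coverage = "ample"` shrinks the arm to 6.83 Mb
#' with 12 zones (25x), the regime for noise-free recovery checks.
#'
#' @param seed integer master seed.
#' @param noisy use the default band noise (TRUE) or a noise-free world.
#' @param coverage "standard" (12.6x) or "ample" (25x).
#' @param n_clones number of clones (default 1000).
#' @return nested configuration list understood by [run_pipeline()].
#' @export
desk_config <- function(seed = 1, noisy = TRUE, coverage = c("standard", "ample"),
                        n_clones = 1000) {
  coverage <- match.arg(coverage)
  arm <- if (coverage == "standard") {
    list(arm_length_kb = 12250, mean_fragment_kb = 2, n_dyes = 4,
         bin_boundaries = c(0.63, 0.67, 0.78), n_gap_zones = 15,
         gap_width_kb = 150)
  } else {
    list(arm_length_kb = 6834, mean_fragment_kb = 2, n_dyes = 4,
         bin_boundaries = c(0.63, 0.67, 0.78), n_gap_zones = 12,
         gap_width_kb = 150)
  }
  list(
    seed = as.integer(seed),
    arm = arm,
    library = list(n_clones = n_clones, insert_mean_kb = 143,
                   insert_sd_kb = 25, purity = 0.88),
    noise = if (noisy) list(band_miss_rate = 0.05, spurious_rate = 2, size_jitter = 1)
            else list(band_miss_rate = 0, spurious_rate = 0, size_jitter = 0),
    filter = list(min_size = 50, max_size = 500, min_band_count = 5),
    assembly = list(net_cutoff = 1e-15, q_clone_cutoff = 1e-15,
                    q_overlap_cutoff = 1e-25, final_cutoff = 1e-33,
                    n_steps = 6, min_contig_clones = 6, tolerance = 1,
                    gellen = 1804, insert_mean_kb = 143),
    markers = list(per_bin_density = c(3.17, 3.53, 5.17, 3.58) * 8,
                   island_fraction = 0.82, island_span_kb = 100),
    pools = list(plate_rows = 8, plate_cols = 12),
    screen = list(method = "array", baseline = 10, shift = 2, sd = 0.3,
                  n_replicates = 10, fp_rate = 0.01, fn_rate = 0.05),
    deconv = list(alpha = 0.01)
  )
}

#' Validate a pipeline configuration
#'
#' @param config nested configuration list.
#' @return `config`, invisibly; missing required keys raise an error naming
#'   the key.
#' @export
validate_config <- function(config) {
  need <- c("seed", "arm", "library", "noise", "filter", "assembly",
            "markers", "pools", "screen")
  for (k in need) {
    if (is.null(config[[k]])) stop("config is missing key: ", k, call. = FALSE)
  }
  if (is.null(config$arm$arm_length_kb)) {
    stop("config is missing key: arm$arm_length_kb", call. = FALSE)
  }
  invisible(config)
}

#' Run the full simulate-assemble-anchor pipeline
#'
#' Executes simulate -> fingerprint -> filter -> net -> Q-removal ->
#' adaptive clustering -> MTP -> 3D pools -> screen -> deconvolve -> bin
#' mapping -> ordering -> supercontig elongation -> gene space -> map
#' statistics. Every stage writes a TSV into `outdir` together with a log
#' carrying the parameters and seed; a rerun with the same config is
#' bit-identical.
#'
#' @param config configuration list, see [desk_config()].
#' @param outdir output directory (created if missing); NULL skips writing.
#' @return list with every stage product (see names).
#' @export
run_pipeline <- function(config = desk_config(), outdir = NULL) {
  validate_config(config)
  seed <- config$seed
  log_lines <- c(sprintf("fingermap pipeline; master seed %d", seed),
                 sprintf("config: %s", jsonlite::toJSON(config, auto_unbox = TRUE)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  arm <- stage("simulate_arm", do.call(simulate_arm, c(config$arm, list(seed = seed))))
  clones <- stage("sample_clone_library",
                  do.call(sample_clone_library,
                          c(list(arm = arm), config$library, list(seed = seed + 1))))
  noise <- do.call(noise_model, c(config$noise, list(seed = seed + 2)))
  fps <- stage("fingerprint", fingerprint_library(clones, arm, noise))
  filt <- stage("filter", do.call(filter_bands, c(list(set = fps), config$filter)))
  cfg <- do.call(assembly_config, config$assembly)
  net <- stage("build_net", build_net(filt$fingerprints, cfg))
  q <- stage("remove_q_elements", remove_q_elements(net, cfg))
  asm <- stage("adaptive_cluster", adaptive_cluster(q$net, cfg))

  layouts <- c(asm$contigs, asm$short_contigs)
  names(layouts) <- vapply(layouts, `[[`, character(1), "contig_id")
  map <- do.call(rbind, lapply(layouts, function(l) data.frame(
    clone_id = l$clones, contig_id = l$contig_id,
    coord_kb = unname(l$coord_kb), order_index = seq_along(l$clones),
    stringsAsFactors = FALSE)))
  rownames(map) <- NULL

  mtp_by_contig <- stage("select_mtp", {
    out <- lapply(asm$contigs, function(l) select_mtp(l, net, cfg))
    names(out) <- vapply(asm$contigs, `[[`, character(1), "contig_id")
    out
  })
  mtp <- stage("reinforce_mtp",
               reinforce_mtp(mtp_by_contig, layouts, net, cfg,
                             q_clones = q$q_clones))
  pools <- stage("design_3d_pools",
                 design_3d_pools(unique(mtp$clones$clone_id),
                                 plate_rows = config$pools$plate_rows,
                                 plate_cols = config$pools$plate_cols))

  markers <- stage("plant_markers",
                   do.call(plant_markers,
                           c(list(arm = arm), config$markers, list(seed = seed + 3))))
  carriers_all <- true_marker_clones(markers, clones)
  mtp_ids <- pools$wells$clone_id
  carriers <- lapply(carriers_all, intersect, x = mtp_ids)
  names(carriers) <- names(carriers_all)

  sm <- signal_model(baseline = config$screen$baseline, shift = config$screen$shift,
                     sd = config$screen$sd, n_replicates = config$screen$n_replicates)
  dcfg <- deconv_config(alpha = if (is.null(config$deconv$alpha)) 0.01 else config$deconv$alpha)
  assignments <- stage("screen_and_deconvolve",
                       screen_and_deconvolve(carriers, pools, map,
                                             method = config$screen$method,
                                             seed = seed + 4, model = sm,
                                             fp_rate = config$screen$fp_rate,
                                             fn_rate = config$screen$fn_rate,
                                             cfg = dcfg))

  marker_bins <- setNames(markers$bin, markers$marker_id)
  bin_assign <- stage("assign_contigs_to_bins",
                      assign_contigs_to_bins(assignments, marker_bins))
  contig_lengths <- vapply(layouts, `[[`, numeric(1), "length_kb")
  mapped <- bin_assign$contig_id
  bins <- deletion_bins(arm$bin_boundaries)
  bin_lengths <- vapply(bins$label, function(b)
    sum(contig_lengths[bin_assign$contig_id[bin_assign$bin == b]]), numeric(1))
  bin_sizes <- stage("estimate_bin_sizes",
                     estimate_bin_sizes(bin_lengths, arm$arm_length_kb))

  ranked <- markers[markers$syntenic & !is.na(markers$ortholog_rank), , drop = FALSE]
  rank_table <- rbind(
    data.frame(marker_id = ranked$marker_id, reference = "tauschii",
               rank = ranked$ortholog_rank, stringsAsFactors = FALSE),
    data.frame(marker_id = ranked$marker_id, reference = "zipper",
               rank = ranked$ortholog_rank, stringsAsFactors = FALSE))
  marker_contigs <- assignments[assignments$status == "assigned" &
                                  !is.na(assignments$contig_id),
                                c("marker_id", "contig_id")]
  ordering <- stage("order_contigs_within_bins",
                    order_contigs_within_bins(bin_assign, marker_contigs, rank_table))

  sc <- stage("elongate_supercontigs",
              elongate_supercontigs(layouts, net, cfg = cfg))

  genes <- stage("genespace", {
    isl <- classify_island_genes(assignments, net = net)
    tabulate_bin_gene_stats(isl$labels, marker_bins,
                            setNames(markers$syntenic, markers$marker_id),
                            setNames(bin_lengths, bins$label))
  })

  anchored <- unique(assignments$contig_id[assignments$status == "assigned" &
                                             !is.na(assignments$contig_id)])
  stats <- stage("compute_map_stats",
                 compute_map_stats(contig_lengths, arm$arm_length_kb,
                                   n_markers = sum(assignments$status == "assigned"),
                                   anchored_lengths_kb = contig_lengths[
                                     names(contig_lengths) %in% anchored]))

  out <- list(config = config, arm = arm, clones = clones, markers = markers,
              fingerprints = fps, filtered = filt, net = net, q = q,
              assembly = asm, layouts = layouts, map = map,
              mtp = mtp, pools = pools, assignments = assignments,
              bin_assignments = bin_assign, bin_sizes = bin_sizes,
              ordering = ordering, supercontigs = sc, genespace = genes,
              stats = stats)
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir, log_lines)
  out
}

write_pipeline_outputs <- function(out, outdir, log_lines) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_tsv(out$clones, p("clones.tsv"))
  write_tsv(out$markers, p("markers.tsv"))
  write_band_file(out$fingerprints, p("bands.txt"))
  write_tsv(out$filtered$report, p("filter_report.tsv"))
  write_tsv(out$net$edges, p("net_edges.tsv"))
  write_tsv(out$map, p("contigs.tsv"))
  write_tsv(out$mtp$clones, p("mtp.tsv"))
  write_tsv(out$pools$wells, p("pools.tsv"))
  write_tsv(out$assignments, p("assignments.tsv"))
  write_tsv(out$bin_assignments, p("bin_map.tsv"))
  write_tsv(out$bin_sizes, p("bin_sizes.tsv"))
  write_tsv(as.data.frame(out$genespace), p("genespace.tsv"))
  stats_df <- data.frame(stat = names(unclass(out$stats)),
                         value = unlist(unclass(out$stats)))
  write_tsv(stats_df, p("stats.tsv"))
  lens <- vapply(out$layouts, `[[`, numeric(1), "length_kb")
  if (nrow(out$ordering$ordered)) {
    write_agp(out$ordering$ordered, lens, p("map.agp"))
  }
  writeLines(log_lines, p("log.txt"))
  invisible(outdir)
}
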