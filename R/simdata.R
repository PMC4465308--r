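#' Simulated chromosome arm for fingerprint mapping
#'
#' Generates a linear chromosome arm carrying band-producing restriction
#' fragments. Fragment cut positions follow a Poisson process with the given
#' mean fragment length, so the fragment count is approximately
#' `arm_length_kb / mean_fragment_kb`. Each fragment is assigned one band:
#' an integer size on the 50--500 grid and a dye channel (SNaPshot-style
#' HICF labels fragments in several dye channels; bands only match within a
#' channel). Optional unclonable zones model regions that cannot be
#' propagated in a BAC library; clones never sample from them, which is what
#' fragments real physical maps into many contigs.
#'
#' @param arm_length_kb arm length in kb (default 258000, a 258 Mb arm).
#' @param mean_fragment_kb mean restriction fragment length in kb (default 2,
#'   giving ~70 complete fragments per 143 kb insert, a typical HICF band
#'   count).
#' @param seed integer seed; the arm is a pure function of its arguments.
#' @param n_dyes number of dye channels (default 4).
#' @param bin_boundaries deletion-bin fraction-length boundaries measured
#'   from the centromere, strictly increasing in (0,1).
#' @param n_gap_zones,gap_width_kb number and width of unclonable zones,
#'   evenly spaced along the arm. Zones wider than one BAC insert guarantee
#'   true coverage islands. Default 0 (fully clonable arm).
#' @return an object of class `arm_model` with fields `arm_length_kb`,
#'   `fragment_positions` (cut positions in kb, strictly increasing),
#'   `band_sizes`, `band_dyes`, `band_codes` (one per fragment),
#'   `bin_boundaries`, `gap_zones` (two-column matrix, possibly 0 rows).
#' @export
simulate_arm <- function(arm_length_kb = 258000, mean_fragment_kb = 2, seed = 1,
                         n_dyes = 4, bin_boundaries = c(0.63, 0.67, 0.78),
                         n_gap_zones = 0, gap_width_kb = 150) {
  if (arm_length_kb <= 0) stop("arm_length_kb must be positive", call. = FALSE)
  if (mean_fragment_kb <= 0) stop("mean_fragment_kb must be positive", call. = FALSE)
  stopifnot(n_dyes >= 1, all(diff(bin_boundaries) > 0),
            all(bin_boundaries > 0), all(bin_boundaries < 1))
  with_seed(seed, {
    # Poisson process of cut positions; oversample then truncate.
    n_exp <- ceiling(arm_length_kb / mean_fragment_kb * 1.3) + 50
    pos <- cumsum(rexp(n_exp, rate = 1 / mean_fragment_kb))
    while (pos[length(pos)] < arm_length_kb) {
      pos <- c(pos, pos[length(pos)] +
                 cumsum(rexp(n_exp, rate = 1 / mean_fragment_kb)))
    }
    pos <- pos[pos < arm_length_kb]
    n_frag <- length(pos)  # fragment i spans (pos[i-1], pos[i]], pos[0] = 0
    sizes <- sample(50:500, n_frag, replace = TRUE)
    dyes <- sample(seq_len(n_dyes), n_frag, replace = TRUE)
    gaps <- matrix(numeric(0), ncol = 2,
                   dimnames = list(NULL, c("start_kb", "end_kb")))
    if (n_gap_zones > 0) {
      centers <- arm_length_kb * (seq_len(n_gap_zones) / (n_gap_zones + 1))
      gaps <- cbind(start_kb = centers - gap_width_kb / 2,
                    end_kb = centers + gap_width_kb / 2)
    }
    structure(list(
      arm_length_kb = arm_length_kb,
      mean_fragment_kb = mean_fragment_kb,
      n_dyes = n_dyes,
      fragment_positions = pos,
      band_sizes = sizes,
      band_dyes = dyes,
      band_codes = band_code(dyes, sizes),
      bin_boundaries = bin_boundaries,
      gap_zones = gaps,
      seed = as.integer(seed)
    ), class = "arm_model")
  })
}

#' @export
print.arm_model <- function(x, ...) {
  cat(sprintf("arm_model: %g kb, %d fragments (mean %g kb), %d dye channels\n",
              x$arm_length_kb, length(x$fragment_positions),
              x$mean_fragment_kb, x$n_dyes))
  cat(sprintf("  deletion-bin boundaries (arm fractions): %s\n",
              paste(x$bin_boundaries, collapse = ", ")))
  if (nrow(x$gap_zones)) {
    cat(sprintf("  %d unclonable zones of %g kb\n", nrow(x$gap_zones),
                x$gap_zones[1, 2] - x$gap_zones[1, 1]))
  }
  invisible(x)
}

#' Dye-coded band values
#'
#' HICF bands are sized within a dye channel; a band is identified by its
#' (dye, size) pair. fingermap codes this as `(dye - 1) * 1000 + size` so a
#' band list is a plain integer vector, sizes stay on the 50--500 grid, and
#' bands from different channels can never fall within a small matching
#' tolerance of each other.
#'
#' @param dye integer dye channel (1-based).
#' @param size integer band size in base pairs, 50--500.
#' @return integer band code(s).
#' @export
band_code <- function(dye, size) as.integer((dye - 1L) * 1000L + size)

#' @rdname band_code
#' @param code integer band code(s).
#' @export
band_size <- function(code) as.integer(code %% 1000L)

#' @rdname band_code
#' @export
band_dye <- function(code) as.integer(code %/% 1000L + 1L)

#' Sample a BAC clone library from a simulated arm
#'
#' Target clones have starts uniform over the clonable portion of the arm
#' (clones never cross an unclonable zone) and insert lengths
#' `Normal(insert_mean_kb, insert_sd_kb)` truncated below at one mean
#' fragment length. A fixed count `ceiling((1 - purity) * n_clones)` of
#' clones is flagged contaminant; contaminants come from other chromosomes
#' and carry no arm interval.
#'
#' @param arm an `arm_model`.
#' @param n_clones number of clones.
#' @param insert_mean_kb,insert_sd_kb insert length distribution (defaults
#'   143 and 25 kb).
#' @param purity fraction of clones deriving from the target arm, in (0, 1]
#'   (default 0.88, a flow-sorting purity).
#' @param seed integer seed.
#' @return a data.frame with columns `clone_id`, `start_kb`, `end_kb`
#'   (half-open `[start, end)`; NA for contaminants), `is_contaminant`,
#'   `source` ("target" or "contaminant").
#' @export
sample_clone_library <- function(arm, n_clones, insert_mean_kb = 143,
                                 insert_sd_kb = 25, purity = 0.88, seed = 1) {
  stopifnot(inherits(arm, "arm_model"))
  if (!(purity > 0 && purity <= 1)) stop("purity must be in (0, 1]", call. = FALSE)
  if (insert_mean_kb <= 0) stop("insert_mean_kb must be positive", call. = FALSE)
  n_cont <- as.integer(ceiling((1 - purity) * n_clones))
  n_target <- n_clones - n_cont
  with_seed(seed, {
    min_len <- arm$mean_fragment_kb
    draw_len <- function(n) {
      len <- rnorm(n, insert_mean_kb, insert_sd_kb)
      pmax(len, min_len)
    }
    overlaps_gap <- function(s, e) {
      if (!nrow(arm$gap_zones)) return(rep(FALSE, length(s)))
      hit <- rep(FALSE, length(s))
      for (g in seq_len(nrow(arm$gap_zones))) {
        hit <- hit | (s < arm$gap_zones[g, 2] & e > arm$gap_zones[g, 1])
      }
      hit
    }
    starts <- numeric(0); ends <- numeric(0)
    need <- n_target
    while (need > 0) {
      s <- runif(need, 0, arm$arm_length_kb)
      e <- s + draw_len(need)
      # a clone must lie entirely in clonable DNA (and on the arm)
      bad <- overlaps_gap(s, e) | e > arm$arm_length_kb | (e - s) <= 0
      starts <- c(starts, s[!bad]); ends <- c(ends, e[!bad])
      need <- sum(bad)
    }
    ids <- sprintf("CL%05d", seq_len(n_clones))
    is_cont <- c(rep(FALSE, n_target), rep(TRUE, n_cont))
    data.frame(
      clone_id = ids,
      start_kb = c(starts, rep(NA_real_, n_cont)),
      end_kb = c(ends, rep(NA_real_, n_cont)),
      is_contaminant = is_cont,
      source = ifelse(is_cont, "contaminant", "target"),
      stringsAsFactors = FALSE
    )
  })
}

#' Fingerprint noise model
#'
#' @param band_miss_rate probability a true band is absent from the
#'   fingerprint (default 0.05).
#' @param spurious_rate expected number of spurious bands per fingerprint
#'   (default 2).
#' @param size_jitter maximum absolute band-size error in grid units
#'   (default 1); errors are uniform integers on `[-size_jitter, size_jitter]`
#'   and never change the dye channel.
#' @param seed integer seed.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(band_miss_rate = 0.05, spurious_rate = 2,
                        size_jitter = 1, seed = 1) {
  stopifnot(band_miss_rate >= 0, band_miss_rate <= 1,
            spurious_rate >= 0, size_jitter >= 0)
  structure(list(band_miss_rate = band_miss_rate,
                 spurious_rate = spurious_rate,
                 size_jitter = as.integer(size_jitter),
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Noise-free convenience noise model
#' @export
#' @rdname noise_model
no_noise <- function(seed = 1) noise_model(0, 0, 0, seed)

#' Indices of arm fragments fully inside an interval
#'
#' @param arm an `arm_model`.
#' @param start_kb,end_kb half-open interval in kb.
#' @return integer vector of fragment indices.
#' @export
fragments_in_interval <- function(arm, start_kb, end_kb) {
  pos <- arm$fragment_positions
  lo <- c(0, pos[-length(pos)])  # fragment i spans (lo[i], pos[i]]
  which(lo >= start_kb & pos <= end_kb)
}

draw_decoy_bands <- function(n, n_dyes) {
  band_code(sample(seq_len(n_dyes), n, replace = TRUE),
            sample(50:500, n, replace = TRUE))
}

jitter_bands <- function(codes, jit) {
  if (jit <= 0 || !length(codes)) return(codes)
  sz <- band_size(codes) + sample(seq(-jit, jit), length(codes), replace = TRUE)
  sz <- pmin(pmax(sz, 50L), 500L)  # clamp to the valid size range
  band_code(band_dye(codes), sz)
}

#' Fingerprint a single clone
#'
#' Target clones emit the band of every fragment fully inside their interval,
#' each independently dropped with `band_miss_rate`, size-jittered within
#' `size_jitter` grid units, plus `Poisson(spurious_rate)` spurious bands.
#' Contaminant clones draw all bands from an independent decoy pool. Empty
#' fingerprints are allowed (attribute `empty` is set).
#'
#' @param clone one row of a clone library data.frame.
#' @param arm the `arm_model` the clone derives from.
#' @param noise a `noise_model`.
#' @param rng_active set when called inside an outer seeded loop; if FALSE
#'   (default) the clone's bands are drawn under `noise$seed`.
#' @return integer vector of band codes (class `band_profile`, attribute
#'   `clone_id`).
#' @export
fingerprint_clone <- function(clone, arm, noise = noise_model(), rng_active = FALSE) {
  stopifnot(inherits(arm, "arm_model"), inherits(noise, "noise_model"))
  run <- function() {
    if (isTRUE(clone$is_contaminant)) {
      n <- rpois(1, 143 / arm$mean_fragment_kb)
      bands <- draw_decoy_bands(n, arm$n_dyes)
    } else {
      idx <- fragments_in_interval(arm, clone$start_kb, clone$end_kb)
      bands <- arm$band_codes[idx]
      if (noise$band_miss_rate > 0 && length(bands)) {
        bands <- bands[runif(length(bands)) >= noise$band_miss_rate]
      }
      bands <- jitter_bands(bands, noise$size_jitter)
      n_sp <- if (noise$spurious_rate > 0) rpois(1, noise$spurious_rate) else 0L
      if (n_sp > 0) bands <- c(bands, draw_decoy_bands(n_sp, arm$n_dyes))
    }
    structure(as.integer(sort(bands)), clone_id = clone$clone_id,
              empty = length(bands) == 0L, class = "band_profile")
  }
  if (rng_active) run() else with_seed(noise$seed, run())
}

#' Fingerprint a whole clone library
#'
#' @param clones clone library data.frame from [sample_clone_library()].
#' @param arm the `arm_model`.
#' @param noise a `noise_model`; its `seed` drives all band noise.
#' @return a `fingerprint_set` keyed by clone id.
#' @export
fingerprint_library <- function(clones, arm, noise = noise_model()) {
  profiles <- with_seed(noise$seed, {
    lapply(seq_len(nrow(clones)), function(i) {
      fingerprint_clone(clones[i, ], arm, noise, rng_active = TRUE)
    })
  })
  names(profiles) <- clones$clone_id
  fingerprint_set(profiles, provenance = sprintf("simulated(seed=%d)", noise$seed))
}

#' Plant markers and genes along the arm
#'
#' Marker counts per deletion bin follow `round(density * bin_length_Mb)`,
#' with bin lengths measured on the cytogenetic fractions. A fraction
#' `island_fraction` of markers is organized into islands: groups of 2--6
#' markers placed within `island_span_kb` of a shared anchor (genes on the
#' same or overlapping clones). Syntenic markers receive ortholog ranks in
#' positional order. Markers are only planted in clonable regions (genes in
#' unclonable zones are invisible to a BAC map).
#'
#' @param arm an `arm_model`.
#' @param per_bin_density genes/Mb per deletion bin, centromere outward
#'   (default the mapped-contig densities 3.17, 3.53, 5.17, 3.58).
#' @param island_fraction fraction of markers belonging to islands
#'   (default 0.82).
#' @param island_span_kb maximum island spread (default 100).
#' @param syntenic_fraction per-bin probability a marker is syntenic
#'   (defaults from the per-bin syntenic/total gene counts).
#' @param marker_class class label for generated markers.
#' @param seed integer seed.
#' @return data.frame with columns `marker_id`, `class`, `position_kb`,
#'   `bin`, `syntenic`, `ortholog_rank` (NA when non-syntenic), `island_id`
#'   (NA when isolated).
#' @export
plant_markers <- function(arm, per_bin_density = c(3.17, 3.53, 5.17, 3.58),
                          island_fraction = 0.82, island_span_kb = 100,
                          syntenic_fraction = c(131, 44, 13, 20) / c(231, 105, 41, 95),
                          marker_class = "conserved_gene", seed = 1) {
  stopifnot(inherits(arm, "arm_model"))
  if (any(per_bin_density < 0)) stop("densities must be >= 0", call. = FALSE)
  stopifnot(island_fraction >= 0, island_fraction <= 1)
  bins <- deletion_bins(arm$bin_boundaries)
  stopifnot(length(per_bin_density) == nrow(bins))
  syntenic_fraction <- rep_len(syntenic_fraction, nrow(bins))
  in_gap <- function(p) {
    if (!nrow(arm$gap_zones)) return(rep(FALSE, length(p)))
    hit <- rep(FALSE, length(p))
    for (g in seq_len(nrow(arm$gap_zones))) {
      hit <- hit | (p >= arm$gap_zones[g, 1] & p < arm$gap_zones[g, 2])
    }
    hit
  }
  draw_positions <- function(n, lo, hi) {
    out <- numeric(0)
    while (length(out) < n) {
      p <- runif(n - length(out), lo, hi)
      out <- c(out, p[!in_gap(p)])
    }
    out
  }
  with_seed(seed, {
    rows <- list()
    for (b in seq_len(nrow(bins))) {
      lo <- bins$lo[b] * arm$arm_length_kb
      hi <- bins$hi[b] * arm$arm_length_kb
      n_b <- round(per_bin_density[b] * (hi - lo) / 1000)
      if (n_b == 0) next
      n_island <- round(island_fraction * n_b)
      pos <- numeric(0); island <- character(0)
      k_isl <- 0L
      while (length(pos) < n_island) {
        k_isl <- k_isl + 1L
        size <- min(sample(2:6, 1), n_island - length(pos))
        if (size < 2) size <- 2L
        anchor <- draw_positions(1, lo, max(lo, hi - island_span_kb))
        members <- anchor + runif(size, 0, island_span_kb)
        members <- pmin(members, hi - 1e-9)
        members <- members[!in_gap(members)]
        if (!length(members)) next
        pos <- c(pos, members)
        island <- c(island, rep(sprintf("ISL_%d_%d", b, k_isl), length(members)))
      }
      n_iso <- max(n_b - length(pos), 0L)
      if (n_iso > 0) {
        pos <- c(pos, draw_positions(n_iso, lo, hi))
        island <- c(island, rep(NA_character_, n_iso))
      }
      syn <- runif(length(pos)) < syntenic_fraction[b]
      rows[[b]] <- data.frame(
        position_kb = pos, bin = bins$label[b], syntenic = syn,
        island_id = island, stringsAsFactors = FALSE
      )
    }
    mk <- do.call(rbind, rows)
    mk <- mk[order(mk$position_kb), , drop = FALSE]
    mk$marker_id <- sprintf("MK%05d", seq_len(nrow(mk)))
    mk$class <- marker_class
    mk$ortholog_rank <- NA_integer_
    mk$ortholog_rank[mk$syntenic] <- seq_len(sum(mk$syntenic))
    rownames(mk) <- NULL
    mk[, c("marker_id", "class", "position_kb", "bin", "syntenic",
           "ortholog_rank", "island_id")]
  })
}

#' Ground-truth clone partition (coverage islands)
#'
#' Connected components of the geometric overlap graph: two target clones are
#' linked when their intervals overlap by at least `min_overlap_kb`.
#' Contaminants are singletons. Used as the truth oracle for partition
#' recovery.
#'
#' @param clones clone library data.frame.
#' @param min_overlap_kb minimal physical overlap regarded as detectable.
#' @return integer vector of cluster labels, one per clone (named).
#' @export
true_partition <- function(clones, min_overlap_kb) {
  tg <- which(!clones$is_contaminant)
  labels <- integer(nrow(clones))
  if (length(tg)) {
    ord <- tg[order(clones$start_kb[tg])]
    comp <- integer(length(ord))
    comp[1] <- 1L
    reach <- clones$end_kb[ord[1]]
    for (k in seq_along(ord)[-1]) {
      # overlap with the furthest reach so far decides island continuation
      if (reach - clones$start_kb[ord[k]] >= min_overlap_kb) {
        comp[k] <- comp[k - 1]
      } else {
        comp[k] <- comp[k - 1] + 1L
      }
      reach <- max(reach, clones$end_kb[ord[k]])
    }
    labels[ord] <- comp
  }
  n_next <- max(labels) + 1L
  cont <- which(clones$is_contaminant)
  labels[cont] <- seq(n_next, length.out = length(cont))
  names(labels) <- clones$clone_id
  labels
}

#' Minimal detectable physical overlap for a simulated world
#'
#' Calibrates, from the scoring model only (no data), the smallest physical
#' overlap between two average clones expected to pass the net cutoff:
#' solves for the geometric shared-fragment count `s` whose expected matched
#' band count (noise retention applied, expected coincidental matches added)
#' reaches the smallest count significant at `cutoff` for average-size
#' profiles.
#'
#' @param arm an `arm_model`.
#' @param noise a `noise_model`.
#' @param cfg an [assembly_config()].
#' @param insert_mean_kb mean insert length in kb.
#' @return overlap in kb.
#' @export
detectable_overlap_kb <- function(arm, noise, cfg, insert_mean_kb = 143) {
  n <- round(insert_mean_kb / arm$mean_fragment_kb - 1)
  s_needed <- min_significant_shared(n, n, cfg$tolerance, cfg$gellen, cfg$net_cutoff)
  jit_keep <- if (noise$size_jitter == 0) 1 else {
    # P(|J1 - J2| <= tolerance), J uniform on -j..j
    j <- noise$size_jitter
    vals <- seq(-j, j)
    d <- outer(vals, vals, "-")
    mean(abs(d) <= cfg$tolerance)
  }
  ret <- (1 - noise$band_miss_rate)^2 * jit_keep
  x <- 1 - (1 - 2 * cfg$tolerance / cfg$gellen)^n
  # solve ret * s + (n - ret * s) * x >= s_needed
  s_geo <- (s_needed - n * x) / (ret * (1 - x))
  (s_geo + 1) * arm$mean_fragment_kb
}

#' Map markers to their true carrier clones
#'
#' @param markers data.frame from [plant_markers()].
#' @param clones clone library data.frame.
#' @return list keyed by marker id of character vectors of carrier clone ids
#'   (clones whose interval contains the marker position).
#' @export
true_marker_clones <- function(markers, clones) {
  tg <- clones[!clones$is_contaminant, , drop = FALSE]
  out <- lapply(markers$position_kb, function(p) {
    tg$clone_id[tg$start_kb <= p & p < tg$end_kb]
  })
  names(out) <- markers$marker_id
  out
}
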