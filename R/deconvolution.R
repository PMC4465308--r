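#' Deconvolution configuration
#'
#' Confidence-tier thresholds for pool scoring. `c_values` holds one
#' threshold per tier (high/medium/low) and pool type (row/col/plate); the
#' defaults are the published screening thresholds: column 2.8, plate 1.6,
#' row 2.6 at high confidence; 2.6, 1.6, 2.4 at medium; 2.4, 1.4, 2.2 at
#' low. A pool is positive at a tier when its robust z-score reaches the C
#' value and a replicate t-test rejects at `alpha`.
#'
#' @param c_values 3 x 3 numeric matrix, rows `high`, `medium`, `low`,
#'   columns `row`, `col`, `plate`.
#' @param alpha replicate t-test significance level (default 0.01).
#' @return an object of class `deconv_config`.
#' @export
deconv_config <- function(c_values = NULL, alpha = 0.01) {
  if (is.null(c_values)) {
    c_values <- rbind(high = c(row = 2.6, col = 2.8, plate = 1.6),
                      medium = c(row = 2.4, col = 2.6, plate = 1.6),
                      low = c(row = 2.2, col = 2.4, plate = 1.4))
  }
  stopifnot(all(c_values["high", ] >= c_values["medium", ]),
            all(c_values["medium", ] >= c_values["low", ]))
  structure(list(c_values = c_values, alpha = alpha), class = "deconv_config")
}

#' Array signal model
#'
#' Log-intensity of a pool is `baseline + shift * carrier + N(0, sd)` per
#' replicate measurement. The default replicate count is 10: five probes per
#' target hybridized in a dye-swap pair.
#'
#' @param baseline baseline log2 intensity.
#' @param shift carrier mean shift (log2 units).
#' @param sd replicate noise standard deviation.
#' @param n_replicates measurements per pool per probe target (default 10).
#' @return an object of class `signal_model`.
#' @export
signal_model <- function(baseline = 10, shift = 2, sd = 0.3, n_replicates = 10) {
  stopifnot(sd >= 0, n_replicates >= 2)
  structure(list(baseline = baseline, shift = shift, sd = sd,
                 n_replicates = as.integer(n_replicates)),
            class = "signal_model")
}

all_pools <- function(design) {
  data.frame(pool = c(design$pools$row, design$pools$col, design$pools$plate),
             type = rep(c("row", "col", "plate"),
                        c(length(design$pools$row), length(design$pools$col),
                          length(design$pools$plate))),
             stringsAsFactors = FALSE)
}

#' Simulate a PCR screen of 3D pools for one marker
#'
#' Every pool containing a carrier clone is positive (missed with
#' `fn_rate`); every other pool is positive with `fp_rate`.
#'
#' @param carriers character vector of carrier clone ids (clones whose true
#'   span contains the marker).
#' @param design a `pool_design`.
#' @param fp_rate,fn_rate false positive / false negative call rates.
#' @param seed integer seed.
#' @return a `screen_result` with binary `calls` per pool.
#' @export
simulate_pcr_screen <- function(carriers, design, fp_rate = 0.01,
                                fn_rate = 0.05, seed = 1) {
  pools <- all_pools(design)
  pos_pools <- pools_of_clones(design, carriers)
  with_seed(seed, {
    truth <- pools$pool %in% pos_pools
    flip_fn <- runif(nrow(pools)) < fn_rate
    flip_fp <- runif(nrow(pools)) < fp_rate
    calls <- ifelse(truth, !flip_fn, flip_fp)
    structure(list(method = "pcr",
                   calls = setNames(as.logical(calls), pools$pool),
                   pool_type = setNames(pools$type, pools$pool)),
              class = "screen_result")
  })
}

#' Simulate array hybridization signals for a set of markers
#'
#' @param carriers_by_marker named list: marker id -> character vector of
#'   carrier clone ids (may be empty).
#' @param design a `pool_design`.
#' @param model a [signal_model()].
#' @param seed integer seed.
#' @return named list of `screen_result`s with an `intensities` matrix
#'   (pools x replicates) each.
#' @export
simulate_array <- function(carriers_by_marker, design, model = signal_model(),
                           seed = 1) {
  pools <- all_pools(design)
  with_seed(seed, {
    out <- lapply(names(carriers_by_marker), function(mk) {
      pos_pools <- pools_of_clones(design, carriers_by_marker[[mk]])
      carrier <- pools$pool %in% pos_pools
      mu <- model$baseline + model$shift * carrier
      ints <- matrix(rnorm(nrow(pools) * model$n_replicates,
                           mean = rep(mu, model$n_replicates), sd = model$sd),
                     nrow = nrow(pools))
      rownames(ints) <- pools$pool
      structure(list(method = "array", intensities = ints,
                     pool_type = setNames(pools$type, pools$pool)),
                class = "screen_result")
    })
    names(out) <- names(carriers_by_marker)
    out
  })
}

#' Score array pools into per-tier positive calls
#'
#' Per pool type, the statistic is a robust z-score: mean replicate
#' log-intensity minus the median over pools of that type, divided by the
#' MAD over pools of that type (standard deviation when the MAD is zero).
#' A pool is positive at a tier when `z >= C(tier, type)` and a one-sample
#' t-test of its replicates against the pool-type median rejects (two-sided
#' p below `alpha`, deviation in the positive direction). Zero-variance
#' replicates skip the t-test (call by z alone, flagged). Pool types with
#' fewer than 3 pools fall back to the median/MAD of all pools.
#'
#' @param result an array `screen_result`.
#' @param cfg a [deconv_config()].
#' @return list with `scores` (data.frame pool/type/mean/z/t_p/flag) and
#'   `positive` (list of pool id vectors per tier high/medium/low).
#' @export
score_pools <- function(result, cfg = deconv_config()) {
  stopifnot(inherits(result, "screen_result"), result$method == "array")
  ints <- result$intensities
  stopifnot(ncol(ints) >= 2)
  m <- rowMeans(ints)
  type <- result$pool_type[rownames(ints)]
  z <- numeric(length(m)); center <- numeric(length(m))
  # scale fallback chain: pool-type MAD, then global MAD, then global sd —
  # small pool counts leave the type MAD degenerate (carrier-contaminated)
  global_scale <- mad(m)
  if (is.na(global_scale) || global_scale == 0) global_scale <- stats::sd(m)
  for (tp in unique(type)) {
    sel <- type == tp
    ref <- if (sum(sel) >= 3) m[sel] else m
    med <- median(ref)
    scale <- mad(ref)
    if (is.na(scale) || scale == 0) scale <- global_scale
    if (is.na(scale) || scale == 0) scale <- Inf
    z[sel] <- (m[sel] - med) / scale
    center[sel] <- med
  }
  t_p <- vapply(seq_along(m), function(i) {
    x <- ints[i, ]
    if (stats::sd(x) == 0) return(NA_real_)  # degenerate: z-only call
    tt <- stats::t.test(x, mu = center[i])
    tt$p.value
  }, numeric(1))
  pass_t <- (is.na(t_p) | t_p < cfg$alpha) & (m > center)
  scores <- data.frame(pool = rownames(ints), type = unname(type),
                       mean = unname(m), z = unname(z), t_p = unname(t_p),
                       flag = ifelse(is.na(t_p), "zero_variance_replicates", ""),
                       stringsAsFactors = FALSE)
  positive <- lapply(c(high = "high", medium = "medium", low = "low"), function(tier) {
    thr <- cfg$c_values[tier, ][scores$type]
    scores$pool[scores$z >= thr & pass_t]
  })
  list(scores = scores, positive = positive)
}

# Resolve multi-candidate address sets against the map.
# map: data.frame(clone_id, contig_id, coord_kb). Candidates are consistent
# when the mapped ones share one contig and sit within a window of each
# other (overlapping clones).
resolve_candidates <- function(cands, map, window_kb = 300,
                               prior_contigs = NULL) {
  mm <- map[match(cands, map$clone_id), , drop = FALSE]
  mapped <- cands[!is.na(mm$contig_id)]
  if (!is.null(prior_contigs) && length(mapped)) {
    on_prior <- mapped[mm$contig_id[match(mapped, cands)] %in% prior_contigs]
    if (length(on_prior) >= 1) cands <- mapped <- on_prior
  }
  if (length(cands) == 1) {
    ctg <- map$contig_id[match(cands, map$clone_id)]
    return(list(status = "assigned", clones = cands,
                contig = if (is.na(ctg)) NA_character_ else ctg))
  }
  if (length(mapped) < 2) {
    return(list(status = "ambiguous", clones = character(0),
                contig = NA_character_))
  }
  # groups of mutually overlapping candidates: same contig, spans within a
  # window; a unique group of >= 2 is the real location, the rest are
  # address ghosts
  mm2 <- map[match(mapped, map$clone_id), , drop = FALSE]
  n <- length(mapped)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    mm2$contig_id[i] == mm2$contig_id[j] &
      abs(mm2$coord_kb[i] - mm2$coord_kb[j]) <= window_kb)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)
  big <- which(comp$csize >= 2)
  if (length(big) == 1) {
    keep <- mapped[comp$membership == big]
    return(list(status = "assigned", clones = keep,
                contig = mm2$contig_id[comp$membership == big][1]))
  }
  list(status = "ambiguous", clones = character(0), contig = NA_character_)
}

#' Deconvolve binary PCR pool calls into a clone assignment
#'
#' Candidate addresses are the Cartesian product of positive rows, columns
#' and plates restricted to occupied wells. A single candidate is assigned
#' directly (high tier). Multiple candidates are resolved by the
#' overlap-consistency rule: candidates on a common contig within a span
#' window are retained; failing that the call is ambiguous (colony PCR
#' needed). No candidates means unassigned.
#'
#' @param result a PCR `screen_result`.
#' @param design the `pool_design`.
#' @param map data.frame (`clone_id`, `contig_id`, `coord_kb`) placing MTP
#'   clones on the preliminary map.
#' @param marker_id marker name carried into the output.
#' @param prior_contigs optional contigs already known to bear the marker;
#'   used to restrict multi-candidate sets.
#' @return one-row data.frame: `marker_id`, `clones` (comma separated),
#'   `contig_id`, `tier`, `method`, `status`, `reason`.
#' @export
deconvolve_pcr <- function(result, design, map, marker_id = NA_character_,
                           prior_contigs = NULL) {
  stopifnot(result$method == "pcr")
  pos <- names(result$calls)[result$calls]
  w <- design$wells
  cand <- w$clone_id[w$row_pool %in% pos & w$col_pool %in% pos &
                       w$plate_pool %in% pos]
  if (!length(cand)) {
    return(assignment_row(marker_id, character(0), NA, "none", "pcr",
                          "unassigned", "no positive address"))
  }
  if (length(cand) == 1) {
    ctg <- map$contig_id[match(cand, map$clone_id)]
    return(assignment_row(marker_id, cand, ctg, "high", "pcr", "assigned", ""))
  }
  res <- resolve_candidates(cand, map, prior_contigs = prior_contigs)
  if (res$status == "assigned") {
    assignment_row(marker_id, res$clones, res$contig, "high", "pcr", "assigned", "")
  } else {
    assignment_row(marker_id, character(0), NA, "none", "pcr", "ambiguous",
                   "multiple inconsistent addresses; colony PCR needed")
  }
}

assignment_row <- function(marker_id, clones, contig, tier, method, status, reason) {
  data.frame(marker_id = marker_id,
             clones = paste(clones, collapse = ","),
             contig_id = if (length(contig) && !is.na(contig[1])) contig[1] else NA_character_,
             tier = tier, method = method, status = status, reason = reason,
             stringsAsFactors = FALSE)
}

#' Deconvolve tiered array pool calls into a clone assignment
#'
#' Address intersection as for PCR, per tier from high to low; the
#' assignment tier is the highest tier at which a consistent assignment
#' exists. Candidate sets spanning non-overlapping map locations at every
#' tier are discarded as ambiguous (cross-hybridization); no positives at
#' any tier means unassigned.
#'
#' @param positive list of positive pool ids per tier (from
#'   [score_pools()]).
#' @param design the `pool_design`.
#' @param map clone placement data.frame as in [deconvolve_pcr()].
#' @param marker_id marker name carried into the output.
#' @return one-row data.frame as in [deconvolve_pcr()].
#' @export
deconvolve_array <- function(positive, design, map, marker_id = NA_character_) {
  w <- design$wells
  saw_candidates <- FALSE
  for (tier in c("high", "medium", "low")) {
    pos <- positive[[tier]]
    if (!length(pos)) next
    cand <- w$clone_id[w$row_pool %in% pos & w$col_pool %in% pos &
                         w$plate_pool %in% pos]
    if (!length(cand)) next
    saw_candidates <- TRUE
    if (length(cand) == 1) {
      ctg <- map$contig_id[match(cand, map$clone_id)]
      return(assignment_row(marker_id, cand, ctg, tier, "array", "assigned", ""))
    }
    res <- resolve_candidates(cand, map)
    if (res$status == "assigned") {
      return(assignment_row(marker_id, res$clones, res$contig, tier, "array",
                            "assigned", ""))
    }
  }
  if (saw_candidates) {
    assignment_row(marker_id, character(0), NA, "none", "array", "discarded",
                   "candidates span non-overlapping map locations")
  } else {
    assignment_row(marker_id, character(0), NA, "none", "array", "unassigned",
                   "no consistent positive address")
  }
}

#' Screen and deconvolve a marker panel against MTP pools
#'
#' Convenience driver used by the pipeline: simulates a screen (PCR or
#' array) for every marker and deconvolves the signals.
#'
#' @param carriers_by_marker named list of carrier clone vectors.
#' @param design a `pool_design`.
#' @param map clone placement data.frame.
#' @param method "array" or "pcr".
#' @param seed integer seed.
#' @param model [signal_model()] for arrays.
#' @param fp_rate,fn_rate PCR error rates.
#' @param cfg a [deconv_config()].
#' @return data.frame of assignments, one row per marker.
#' @export
screen_and_deconvolve <- function(carriers_by_marker, design, map,
                                  method = c("array", "pcr"), seed = 1,
                                  model = signal_model(), fp_rate = 0.01,
                                  fn_rate = 0.05, cfg = deconv_config()) {
  method <- match.arg(method)
  if (method == "array") {
    screens <- simulate_array(carriers_by_marker, design, model, seed)
    rows <- lapply(names(screens), function(mk) {
      sc <- score_pools(screens[[mk]], cfg)
      deconvolve_array(sc$positive, design, map, marker_id = mk)
    })
  } else {
    rows <- lapply(seq_along(carriers_by_marker), function(k) {
      mk <- names(carriers_by_marker)[k]
      res <- simulate_pcr_screen(carriers_by_marker[[mk]], design,
                                 fp_rate, fn_rate,
                                 seed = seed + k)
      deconvolve_pcr(res, design, map, marker_id = mk)
    })
  }
  do.call(rbind, rows)
}
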