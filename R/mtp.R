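#' Select a minimum tiling path for one contig
#'
#' Greedy end-to-end interval cover on the layout coordinates: starting at
#' the leftmost clone, repeatedly pick among the clones overlapping the
#' current one (edge in the net) the clone whose right end extends furthest,
#' until the contig's right end is reached. Clones whose estimated span is
#' contained in another clone's span (buried clones) are never selected.
#'
#' @param layout a linear `contig_layout`.
#' @param net the `overlap_net`.
#' @param cfg an [assembly_config()]; per-clone span lengths are estimated
#'   as `n_bands * insert_mean_kb / mean(n_bands)`.
#' @return character vector of MTP clone ids in layout order.
#' @export
select_mtp <- function(layout, net, cfg = net$cfg) {
  cl <- layout$clones
  if (length(cl) <= 2) return(cl)
  nb <- net$n_bands[cl]
  len <- nb * cfg$insert_mean_kb / mean(nb)
  starts <- layout$coord_kb[cl]
  ends <- starts + len
  ed <- net$edges[net$edges$a %in% cl & net$edges$b %in% cl, , drop = FALSE]
  nbrs <- split(c(ed$b, ed$a), c(ed$a, ed$b))
  right_end <- max(ends)
  cur <- cl[which.min(starts)]
  mtp <- cur
  while (ends[cur] < right_end - 1e-9) {
    cand <- intersect(nbrs[[cur]], cl)
    cand <- cand[starts[cand] <= ends[cur]]
    # never pick a clone buried in the current clone's span
    cand <- cand[ends[cand] > ends[cur]]
    if (!length(cand)) break  # coverage gap in the layout; stop at the reach
    cur <- cand[which.max(ends[cand])]
    mtp <- c(mtp, cur)
  }
  mtp
}

#' Reinforce weak MTP junctions and assemble the MTP selection
#'
#' Consecutive MTP clones whose overlap is significant only above
#' `reinforce_cutoff` (i.e. weaker than the net-building cutoff) risk a
#' sequence-level gap; for each such junction one additional clone spanning
#' the junction, with stronger overlaps to both flanks than the weak overlap,
#' is added as a reinforcement clone when available, otherwise the junction
#' is flagged as a potential gap.
#'
#' @param mtp_by_contig named list (contig id -> ordered MTP clone vector).
#' @param layouts named list of `contig_layout`s.
#' @param net the `overlap_net`.
#' @param cfg an [assembly_config()].
#' @param reinforce_cutoff junctions weaker than this need reinforcement
#'   (default the net cutoff 1e-15: overlaps only significant at 1e-14 or
#'   above are unreliable).
#' @param q_clones optional character vector of questionable clones to
#'   append, flagged, to the selection.
#' @return an object of class `mtp_selection`: data.frame `clones`
#'   (contig_id, clone_id, category in base/reinforcement/q_clone),
#'   `gap_flags` (junctions lacking a reinforcing clone), `totals`.
#' @export
reinforce_mtp <- function(mtp_by_contig, layouts, net, cfg = net$cfg,
                          reinforce_cutoff = cfg$net_cutoff,
                          q_clones = character(0)) {
  ed <- net$edges
  key <- paste(ed$a, ed$b, sep = "\r")
  p_lookup <- setNames(ed$sulston_p, key)
  get_p <- function(u, v) {
    p <- p_lookup[paste(u, v, sep = "\r")]
    if (is.na(p)) p <- p_lookup[paste(v, u, sep = "\r")]
    unname(p)  # NA = no edge in the net
  }
  rows <- list()
  gaps <- list()
  for (ctg in names(mtp_by_contig)) {
    mtp <- mtp_by_contig[[ctg]]
    lay <- layouts[[ctg]]
    rows[[length(rows) + 1]] <- data.frame(
      contig_id = ctg, clone_id = mtp, category = "base",
      stringsAsFactors = FALSE)
    if (length(mtp) < 2) next
    for (k in seq_len(length(mtp) - 1)) {
      u <- mtp[k]; v <- mtp[k + 1]
      p_uv <- get_p(u, v)
      if (!is.na(p_uv) && p_uv <= reinforce_cutoff) next
      if (is.na(p_uv)) p_uv <- 1
      # candidate spanning clones: between u and v in the layout, stronger
      # overlaps to both flanks than the weak junction
      pos <- lay$coord_kb
      cand <- lay$clones[pos[lay$clones] >= pos[u] & pos[lay$clones] <= pos[v]]
      cand <- setdiff(cand, c(mtp))
      ok <- vapply(cand, function(w) {
        pu <- get_p(u, w); pv <- get_p(w, v)
        !is.na(pu) && !is.na(pv) && pu < p_uv && pv < p_uv
      }, logical(1))
      if (any(ok)) {
        w <- cand[ok][1]
        rows[[length(rows) + 1]] <- data.frame(
          contig_id = ctg, clone_id = w, category = "reinforcement",
          stringsAsFactors = FALSE)
      } else {
        gaps[[length(gaps) + 1]] <- data.frame(
          contig_id = ctg, left_clone = u, right_clone = v,
          sulston_p = p_uv, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(q_clones)) {
    rows[[length(rows) + 1]] <- data.frame(
      contig_id = NA_character_, clone_id = q_clones, category = "q_clone",
      stringsAsFactors = FALSE)
  }
  clones <- do.call(rbind, rows)
  gap_flags <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(contig_id = character(0), left_clone = character(0),
               right_clone = character(0), sulston_p = numeric(0))
  totals <- c(base = sum(clones$category == "base"),
              reinforcement = sum(clones$category == "reinforcement"),
              q_clone = sum(clones$category == "q_clone"))
  structure(list(clones = clones, gap_flags = gap_flags,
                 totals = c(totals, total = sum(totals))),
            class = "mtp_selection")
}

#' @export
print.mtp_selection <- function(x, ...) {
  cat(sprintf("mtp_selection: %d clones (%d base + %d reinforcement + %d questionable)\n",
              x$totals[["total"]], x$totals[["base"]],
              x$totals[["reinforcement"]], x$totals[["q_clone"]]))
  if (nrow(x$gap_flags)) {
    cat(sprintf("  %d junctions flagged as potential sequence-level gaps\n",
                nrow(x$gap_flags)))
  }
  invisible(x)
}

#' MTP clone-count bookkeeping
#'
#' Totals per category of an MTP selection; the grand total is the sum of
#' base, reinforcement and questionable clones (categories are disjoint).
#'
#' @param base,reinforcement,q_clone category counts.
#' @return named numeric vector with the categories and `total`.
#' @export
mtp_totals <- function(base, reinforcement = 0, q_clone = 0) {
  c(base = base, reinforcement = reinforcement, q_clone = q_clone,
    total = base + reinforcement + q_clone)
}

#' Design three-dimensional screening pools
#'
#' Clones are re-arrayed plate-major, row-major into `plate_rows` x
#' `plate_cols` plates, then pooled into one pool per row, per column and per
#' plate, so every clone belongs to exactly three pools and a single positive
#' row/column/plate triple identifies a well address.
#'
#' @param clone_ids character vector of MTP clones (or an `mtp_selection`).
#' @param plate_rows,plate_cols plate geometry (defaults 16 x 24, a 384-well
#'   plate).
#' @param n_plates number of plates (default `ceiling(n / (rows * cols))`).
#' @return an object of class `pool_design`: data.frame `wells` (clone_id,
#'   plate, row, col) plus pool id columns `row_pool`, `col_pool`,
#'   `plate_pool`; field `pools` lists pool sizes.
#' @export
design_3d_pools <- function(clone_ids, plate_rows = 16, plate_cols = 24,
                            n_plates = NULL) {
  if (inherits(clone_ids, "mtp_selection")) clone_ids <- clone_ids$clones$clone_id
  n <- length(clone_ids)
  per_plate <- plate_rows * plate_cols
  if (is.null(n_plates)) n_plates <- ceiling(n / per_plate)
  if (n > n_plates * per_plate) {
    stop(sprintf("%d clones exceed %d plates x %d wells", n, n_plates, per_plate),
         call. = FALSE)
  }
  idx <- seq_len(n) - 1L
  plate <- idx %/% per_plate + 1L
  row <- (idx %% per_plate) %/% plate_cols + 1L
  col <- (idx %% per_plate) %% plate_cols + 1L
  wells <- data.frame(
    clone_id = clone_ids, plate = plate, row = row, col = col,
    row_pool = sprintf("R%02d", row),
    col_pool = sprintf("C%02d", col),
    plate_pool = sprintf("P%d", plate),
    stringsAsFactors = FALSE
  )
  pools <- list(
    row = sprintf("R%02d", seq_len(plate_rows)),
    col = sprintf("C%02d", seq_len(plate_cols)),
    plate = sprintf("P%d", seq_len(n_plates))
  )
  structure(list(wells = wells, pools = pools,
                 plate_rows = plate_rows, plate_cols = plate_cols,
                 n_plates = n_plates),
            class = "pool_design")
}

#' @export
print.pool_design <- function(x, ...) {
  cat(sprintf("pool_design: %d clones in %d plates (%dx%d); %d+%d+%d pools\n",
              nrow(x$wells), x$n_plates, x$plate_rows, x$plate_cols,
              length(x$pools$row), length(x$pools$col), length(x$pools$plate)))
  invisible(x)
}

#' Pools containing each of a set of clones
#'
#' @param design a `pool_design`.
#' @param clone_ids clones to look up.
#' @return character vector of pool ids (union over the clones).
#' @export
pools_of_clones <- function(design, clone_ids) {
  w <- design$wells[design$wells$clone_id %in% clone_ids, , drop = FALSE]
  unique(c(w$row_pool, w$col_pool, w$plate_pool))
}
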