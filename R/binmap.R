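#' Deletion bins of a chromosome arm
#'
#' Bins are fraction-length intervals measured from the centromere; the
#' default boundaries 0.63, 0.67, 0.78 delimit the four bins of a short arm
#' mapped with two deletion lines plus genetic markers.
#'
#' @param boundaries strictly increasing fractions in (0,1).
#' @return data.frame with `label`, `lo`, `hi` tiling `[0, 1)`.
#' @export
deletion_bins <- function(boundaries = c(0.63, 0.67, 0.78)) {
  stopifnot(all(diff(boundaries) > 0), all(boundaries > 0), all(boundaries < 1))
  lo <- c(0, boundaries)
  hi <- c(boundaries, 1)
  fmt <- function(x) ifelse(x == 0, "0", ifelse(x == 1, "1.00", formatC(x, format = "g")))
  data.frame(label = paste0(fmt(lo), "-", fmt(hi)), lo = lo, hi = hi,
             stringsAsFactors = FALSE)
}

#' Deletion bin containing an arm position
#'
#' @param position_kb position(s) in kb from the centromere.
#' @param arm an `arm_model` (or a list with `arm_length_kb` and
#'   `bin_boundaries`).
#' @return character vector of bin labels.
#' @export
bin_of_position <- function(position_kb, arm) {
  bins <- deletion_bins(arm$bin_boundaries)
  frac <- position_kb / arm$arm_length_kb
  idx <- findInterval(frac, c(bins$lo, 1), rightmost.closed = TRUE)
  idx[idx < 1] <- NA; idx[idx > nrow(bins)] <- NA
  bins$label[idx]
}

#' Infer a deletion bin from deletion-line presence calls
#'
#' A deletion line with fraction length FL retains the proximal `[0, FL)`
#' portion of the arm: a marker absent from both lines is distal to the
#' larger FL; present only in the larger-FL line, it lies between the two
#' FLs; present in both, it is proximal to the smaller FL (refined into the
#' two proximal bins only with genetic evidence). Present only in the
#' smaller-FL line is an impossible retention pattern.
#'
#' @param present_in named logical vector of presence calls, named by
#'   deletion line.
#' @param lines named numeric vector of fraction lengths (default
#'   `c("5DS-5" = 0.67, "5DS-2" = 0.78)`).
#' @param genetic_bin optional bin label from genetic-marker evidence,
#'   used to refine a proximal call.
#' @return list with `bin` (label or NA) and `status`
#'   ("ok"/"proximal_unrefined"/"inconsistent").
#' @export
infer_bin_from_deletion_lines <- function(present_in,
                                          lines = c("5DS-5" = 0.67, "5DS-2" = 0.78),
                                          genetic_bin = NULL) {
  stopifnot(length(lines) == 2, all(names(lines) %in% names(present_in)))
  fl_lo <- min(lines); fl_hi <- max(lines)
  lo_line <- names(lines)[which.min(lines)]
  hi_line <- names(lines)[which.max(lines)]
  p_lo <- isTRUE(present_in[[lo_line]])
  p_hi <- isTRUE(present_in[[hi_line]])
  fmt <- function(x) ifelse(x == 0, "0", ifelse(x == 1, "1.00", formatC(x, format = "g")))
  if (!p_lo && !p_hi) {
    list(bin = paste0(fmt(fl_hi), "-1.00"), status = "ok")
  } else if (!p_lo && p_hi) {
    list(bin = paste0(fmt(fl_lo), "-", fmt(fl_hi)), status = "ok")
  } else if (p_lo && p_hi) {
    if (!is.null(genetic_bin)) {
      list(bin = genetic_bin, status = "ok")
    } else {
      list(bin = paste0("0-", fmt(fl_lo)), status = "proximal_unrefined")
    }
  } else {
    list(bin = NA_character_, status = "inconsistent")
  }
}

#' Assign contigs to deletion bins by marker majority vote
#'
#' @param assignments data.frame of marker assignments with columns
#'   `marker_id`, `contig_id`, `status` ("assigned" rows are used).
#' @param marker_bins named character vector: marker id -> bin label.
#' @return data.frame `contig_id`, `bin`, `conflict`, `candidate_bins`,
#'   `n_markers`, `evidence` (comma-separated marker ids). Contigs whose
#'   markers disagree keep the majority bin with the conflict flagged.
#' @export
assign_contigs_to_bins <- function(assignments, marker_bins) {
  ok <- assignments[assignments$status == "assigned" &
                      !is.na(assignments$contig_id), , drop = FALSE]
  ok$bin <- marker_bins[ok$marker_id]
  ok <- ok[!is.na(ok$bin), , drop = FALSE]
  if (!nrow(ok)) {
    return(data.frame(contig_id = character(0), bin = character(0),
                      conflict = logical(0), candidate_bins = character(0),
                      n_markers = integer(0), evidence = character(0)))
  }
  out <- lapply(split(ok, ok$contig_id), function(d) {
    votes <- sort(table(d$bin), decreasing = TRUE)
    data.frame(contig_id = d$contig_id[1],
               bin = names(votes)[1],
               conflict = length(votes) > 1,
               candidate_bins = paste(names(votes), collapse = ","),
               n_markers = nrow(d),
               evidence = paste(sort(unique(d$marker_id)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Coverage-corrected deletion-bin sizes
#'
#' The raw size of a bin is the summed length of the contigs mapped to it;
#' the corrected size divides by the chromosome coverage of the mapped
#' contigs (total mapped length / arm length), so corrected sizes always sum
#' to the arm length when `total_mapped_kb` is the sum of the bin lengths.
#'
#' @param bin_lengths_kb named numeric: summed mapped contig length per bin.
#' @param arm_length_kb arm length.
#' @param total_mapped_kb total mapped length used for the coverage
#'   correction (default `sum(bin_lengths_kb)`; can be overridden when a
#'   separately tabulated total is the authoritative input).
#' @return data.frame `bin`, `mapped_kb`, `corrected_kb`, `share` (fraction
#'   of the arm).
#' @export
estimate_bin_sizes <- function(bin_lengths_kb, arm_length_kb,
                               total_mapped_kb = sum(bin_lengths_kb)) {
  if (total_mapped_kb <= 0) stop("no mapped contig length", call. = FALSE)
  coverage <- total_mapped_kb / arm_length_kb
  data.frame(bin = names(bin_lengths_kb),
             mapped_kb = unname(bin_lengths_kb),
             corrected_kb = unname(bin_lengths_kb) / coverage,
             share = unname(bin_lengths_kb) / total_mapped_kb,
             stringsAsFactors = FALSE)
}

#' Order contigs within deletion bins by ortholog rank
#'
#' Within each bin, contigs are sorted by the median rank of their markers
#' on the primary reference (a related sequenced genome); contigs without a
#' primary-reference rank are interleaved using their median rank on the
#' secondary reference (a synteny-derived virtual gene order), rescaled onto
#' the primary scale by a monotone linear fit over contigs carrying both.
#' Ties break by minimum rank, then contig id. The duplication report lists
#' orthologs matched by two or more non-adjacent contigs; contigs whose
#' marker ranks split into two or more clusters separated by more than
#' `span_frac` of the reference rank range are flagged as split locations.
#'
#' @param bin_assignments data.frame from [assign_contigs_to_bins()].
#' @param marker_contigs data.frame `marker_id`, `contig_id` (assigned
#'   markers).
#' @param rank_table data.frame `marker_id`, `reference` ("tauschii" or
#'   "zipper"), `rank`.
#' @param span_frac split-location gap threshold as a fraction of the
#'   primary rank range (default 0.05).
#' @return list with `ordered` (bin assignments plus `order_value`,
#'   `within_bin_rank`, `orientable`, `unplaced`), `duplications`,
#'   `split_contigs`.
#' @export
order_contigs_within_bins <- function(bin_assignments, marker_contigs,
                                      rank_table, span_frac = 0.05) {
  stopifnot(all(rank_table$rank >= 0))
  mk <- merge(marker_contigs, rank_table, by = "marker_id")
  med_rank <- function(ctg, ref) {
    r <- mk$rank[mk$contig_id == ctg & mk$reference == ref]
    if (!length(r)) NA_real_ else median(r)
  }
  ctgs <- bin_assignments$contig_id
  tau <- vapply(ctgs, med_rank, numeric(1), ref = "tauschii")
  zip <- vapply(ctgs, med_rank, numeric(1), ref = "zipper")
  # rescale the secondary reference onto the primary scale
  both <- !is.na(tau) & !is.na(zip)
  order_value <- tau
  if (any(is.na(tau) & !is.na(zip))) {
    if (sum(both) >= 2 && stats::sd(zip[both]) > 0) {
      fit <- stats::lm.fit(cbind(1, zip[both]), tau[both])
      pred <- fit$coefficients[1] + fit$coefficients[2] * zip
    } else {
      pred <- zip
    }
    order_value[is.na(tau)] <- pred[is.na(tau)]
  }
  min_rank <- vapply(ctgs, function(ctg) {
    r <- mk$rank[mk$contig_id == ctg]
    if (!length(r)) NA_real_ else min(r)
  }, numeric(1))
  n_ranked <- vapply(ctgs, function(ctg)
    sum(mk$contig_id == ctg), numeric(1))
  res <- bin_assignments
  res$order_value <- unname(order_value)
  res$orientable <- n_ranked >= 2
  res$unplaced <- is.na(order_value)
  res$within_bin_rank <- NA_integer_
  for (b in unique(res$bin)) {
    sel <- which(res$bin == b & !res$unplaced)
    if (!length(sel)) next
    ord <- sel[order(res$order_value[sel], min_rank[sel], res$contig_id[sel])]
    res$within_bin_rank[ord] <- seq_along(ord)
  }
  # duplications: one ortholog (rank on a reference) hit by non-adjacent contigs
  dup_rows <- list()
  for (ref in unique(mk$reference)) {
    d <- mk[mk$reference == ref, , drop = FALSE]
    for (rk in unique(d$rank[duplicated(d$rank)])) {
      hits <- unique(d$contig_id[d$rank == rk])
      if (length(hits) < 2) next
      hb <- res[match(hits, res$contig_id), , drop = FALSE]
      adjacent <- nrow(hb) == 2 && !anyNA(hb$within_bin_rank) &&
        length(unique(hb$bin)) == 1 &&
        abs(diff(hb$within_bin_rank)) == 1
      if (!adjacent) {
        dup_rows[[length(dup_rows) + 1]] <- data.frame(
          reference = ref, rank = rk,
          contigs = paste(hits, collapse = ","), stringsAsFactors = FALSE)
      }
    }
  }
  # split locations: rank clusters separated beyond span_frac of the range
  split_rows <- list()
  for (ref in unique(mk$reference)) {
    d <- mk[mk$reference == ref, , drop = FALSE]
    span <- diff(range(rank_table$rank[rank_table$reference == ref]))
    if (span <= 0) next
    for (ctg in unique(d$contig_id)) {
      r <- sort(d$rank[d$contig_id == ctg])
      if (length(r) < 2) next
      gaps <- diff(r)
      if (any(gaps > span_frac * span)) {
        split_rows[[length(split_rows) + 1]] <- data.frame(
          contig_id = ctg, reference = ref,
          n_clusters = sum(gaps > span_frac * span) + 1,
          ranks = paste(r, collapse = ","), stringsAsFactors = FALSE)
      }
    }
  }
  list(ordered = res,
       duplications = if (length(dup_rows)) do.call(rbind, dup_rows) else
         data.frame(reference = character(0), rank = numeric(0), contigs = character(0)),
       split_contigs = if (length(split_rows)) do.call(rbind, split_rows) else
         data.frame(contig_id = character(0), reference = character(0),
                    n_clusters = integer(0), ranks = character(0)))
}

contig_ends <- function(layout, end_window = 2) {
  cl <- layout$clones
  k <- min(end_window, length(cl))
  list(left = cl[seq_len(k)], right = cl[seq(length(cl) - k + 1, length(cl))])
}

#' Elongate contigs into supercontigs
#'
#' Two contigs merge when an end clone of one overlaps an end clone of the
#' other at the elongation cutoff and the merged layout remains linear.
#' Short contigs are eligible; chains of merges are allowed. Merges that
#' would create a non-linear topology are rejected and logged.
#'
#' @param layouts list of `contig_layout`s (main and short).
#' @param net the full `overlap_net` (built at the relaxed net cutoff, so it
#'   retains the cross-contig edges removed by adaptive splitting).
#' @param elongation_cutoff Sulston cutoff for end-clone overlaps (default
#'   1e-15).
#' @param end_window how many clones at each contig end count as end clones
#'   (default 2).
#' @param cfg an [assembly_config()].
#' @return list with `supercontigs` (list: `members`, `clone_counts`,
#'   `total_clones`, `connections`, `layout`), `rejected` (data.frame of
#'   non-linear merge attempts), `unmerged` (contig ids).
#' @export
elongate_supercontigs <- function(layouts, net, elongation_cutoff = 1e-15,
                                  end_window = 2, cfg = net$cfg) {
  names(layouts) <- vapply(layouts, `[[`, character(1), "contig_id")
  groups <- lapply(names(layouts), function(id) list(
    members = id, clones = layouts[[id]]$clones,
    layout = layouts[[id]],
    connections = data.frame(contig_a = character(0), contig_b = character(0),
                             clone_a = character(0), clone_b = character(0))))
  ed <- net$edges[net$edges$sulston_p <= elongation_cutoff, , drop = FALSE]
  rejected <- list()
  merged <- TRUE
  while (merged && length(groups) > 1) {
    merged <- FALSE
    for (i in seq_len(length(groups) - 1)) {
      for (j in seq(i + 1, length(groups))) {
        gi <- groups[[i]]; gj <- groups[[j]]
        ei <- contig_ends(gi$layout, end_window)
        ej <- contig_ends(gj$layout, end_window)
        ends_i <- unique(unlist(ei)); ends_j <- unique(unlist(ej))
        hit <- ed[(ed$a %in% ends_i & ed$b %in% ends_j) |
                    (ed$b %in% ends_i & ed$a %in% ends_j), , drop = FALSE]
        if (!nrow(hit)) next
        lay <- tryCatch(
          layout_and_check_linearity(c(gi$clones, gj$clones), net, cfg,
                                     cutoff = elongation_cutoff),
          error = function(e) NULL)
        if (is.null(lay) || !lay$linear) {
          rejected[[length(rejected) + 1]] <- data.frame(
            contig_a = gi$members[1], contig_b = gj$members[1],
            reason = "merged layout non-linear", stringsAsFactors = FALSE)
          next
        }
        hit1 <- hit[which.min(hit$sulston_p), , drop = FALSE]
        conn <- rbind(gi$connections, gj$connections,
                      data.frame(contig_a = gi$members[length(gi$members)],
                                 contig_b = gj$members[1],
                                 clone_a = hit1$a, clone_b = hit1$b,
                                 stringsAsFactors = FALSE))
        # member order along the merged layout
        mean_pos <- vapply(c(gi$members, gj$members), function(m) {
          mean(lay$coord_kb[intersect(layouts[[m]]$clones, names(lay$coord_kb))])
        }, numeric(1))
        groups[[i]] <- list(members = names(sort(mean_pos)),
                            clones = lay$clones, layout = lay,
                            connections = conn)
        groups[[j]] <- NULL
        merged <- TRUE
        break
      }
      if (merged) break
    }
  }
  is_sc <- vapply(groups, function(g) length(g$members) > 1, logical(1))
  scs <- lapply(which(is_sc), function(k) {
    g <- groups[[k]]
    counts <- vapply(g$members, function(m) length(layouts[[m]]$clones), integer(1))
    list(members = g$members, clone_counts = counts,
         total_clones = sum(counts), connections = g$connections,
         layout = g$layout)
  })
  names(scs) <- sprintf("SC%d", seq_along(scs))
  list(supercontigs = scs,
       rejected = if (length(rejected)) do.call(rbind, rejected) else
         data.frame(contig_a = character(0), contig_b = character(0),
                    reason = character(0)),
       unmerged = unlist(lapply(groups[!is_sc], `[[`, "members")))
}

#' Export an ordered bin map as AGP v2.1
#'
#' Each deletion bin becomes one AGP object; its ordered contigs are W
#' components separated by 100 bp gaps of unknown size (`U`). Unoriented
#' contigs carry orientation `?`.
#'
#' @param ordered data.frame from [order_contigs_within_bins()]`$ordered`.
#' @param contig_lengths_kb named numeric of contig lengths.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_agp <- function(ordered, contig_lengths_kb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  for (b in unique(ordered$bin)) {
    d <- ordered[ordered$bin == b, , drop = FALSE]
    d <- d[order(is.na(d$within_bin_rank), d$within_bin_rank, d$contig_id), ,
           drop = FALSE]
    pos <- 0L; part <- 0L
    obj <- paste0("bin:", b)
    for (k in seq_len(nrow(d))) {
      if (k > 1) {
        part <- part + 1L
        writeLines(paste(obj, pos + 1, pos + 100, part, "U", 100,
                         "contig", "no", "na", sep = "\t"), con)
        pos <- pos + 100L
      }
      len <- round(contig_lengths_kb[[d$contig_id[k]]] * 1000)
      part <- part + 1L
      ori <- if (isTRUE(d$orientable[k])) "+" else "?"
      writeLines(paste(obj, pos + 1, pos + len, part, "W", d$contig_id[k],
                       1, len, ori, sep = "\t"), con)
      pos <- pos + len
    }
  }
  invisible(path)
}

#' Read an AGP v2.1 bin map written by [write_agp()]
#'
#' @param path AGP file.
#' @return data.frame `contig_id`, `bin`, `within_bin_rank`, `orientation`,
#'   `length_kb`.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  parts <- strsplit(lines, "\t")
  w <- Filter(function(p) length(p) == 9 && p[5] == "W", parts)
  out <- do.call(rbind, lapply(w, function(p) {
    data.frame(contig_id = p[6], bin = sub("^bin:", "", p[1]),
               orientation = p[9],
               length_kb = (as.numeric(p[8]) - as.numeric(p[7]) + 1) / 1000,
               stringsAsFactors = FALSE)
  }))
  out$within_bin_rank <- stats::ave(seq_len(nrow(out)), out$bin,
                                    FUN = seq_along)
  out
}
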