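#' Assembly configuration
#'
#' Cutoffs and matching parameters for overlap-net construction and adaptive
#' clustering. Defaults follow the linear-topology (LTC-style) protocol: net
#' built at a relaxed Sulston cutoff of 1e-15, questionable clones and
#' overlaps removed at 1e-15 / 1e-25, adaptive clustering tightening the
#' cutoff to 1e-33 in 6 geometric steps, contigs of more than 5 clones
#' reported as the main set.
#'
#' @param net_cutoff Sulston probability cutoff for the initial overlap net.
#' @param q_clone_cutoff cutoff of the net on which questionable clones are
#'   detected.
#' @param q_overlap_cutoff edges weaker than this are questionable-overlap
#'   candidates.
#' @param final_cutoff most stringent cutoff of the adaptive schedule.
#' @param n_steps number of tightening steps from `net_cutoff` to
#'   `final_cutoff` (exponent schedule is linear, i.e. cutoffs geometric).
#' @param min_contig_clones minimum clone count of a main contig (default 6).
#' @param tolerance band matching tolerance in grid units (default 1).
#' @param gellen number of distinguishable band positions. Default 1804 =
#'   4 dye channels x 451 integer sizes (50--500); HICF sizes bands per dye
#'   channel, so channels multiply the distinguishable positions.
#' @param insert_mean_kb mean insert length used for coordinates, lengths
#'   and depths (default 143).
#' @param q_clone_min_side minimum clones on each side of a bridging clone
#'   for it to count as questionable (default 2).
#' @param support_cutoff lax Sulston cutoff for sub-threshold evidence
#'   retained alongside the net (default 1e-10); used to distinguish genuine
#'   low-coverage bridge clones (their flanks share weak band similarity)
#'   from chimeras (their flanks are unrelated).
#' @return an object of class `assembly_config`.
#' @export
assembly_config <- function(net_cutoff = 1e-15, q_clone_cutoff = 1e-15,
                            q_overlap_cutoff = 1e-25, final_cutoff = 1e-33,
                            n_steps = 6, min_contig_clones = 6,
                            tolerance = 1, gellen = 1804,
                            insert_mean_kb = 143, q_clone_min_side = 2,
                            support_cutoff = 1e-10) {
  if (final_cutoff > net_cutoff) stop("final_cutoff must be <= net_cutoff", call. = FALSE)
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  stopifnot(tolerance >= 0, gellen > 0, insert_mean_kb > 0)
  structure(list(net_cutoff = net_cutoff, q_clone_cutoff = q_clone_cutoff,
                 q_overlap_cutoff = q_overlap_cutoff, final_cutoff = final_cutoff,
                 n_steps = n_steps, min_contig_clones = min_contig_clones,
                 tolerance = tolerance, gellen = gellen,
                 insert_mean_kb = insert_mean_kb,
                 q_clone_min_side = q_clone_min_side,
                 support_cutoff = support_cutoff),
            class = "assembly_config")
}

#' Sulston overlap probability
#'
#' Probability that two clones share at least `shared` bands by chance.
#' With `x = 1 - (1 - 2 * tolerance / gellen)^n_high` (the chance one band of
#' the smaller profile matches some band of the larger), the score is the
#' upper binomial tail `sum_{j >= shared} C(n_low, j) x^j (1-x)^(n_low-j)`,
#' evaluated with the numerically safe tail routine. Vectorized over all
#' arguments.
#'
#' @param n_low,n_high band counts of the smaller and larger profile.
#' @param shared matched band count, `0 <= shared <= n_low`.
#' @param tolerance band matching tolerance.
#' @param gellen number of distinguishable band positions.
#' @return probability in `[0, 1]`.
#' @export
sulston_score <- function(n_low, n_high, shared, tolerance, gellen) {
  if (any(n_low > n_high)) stop("n_low must be <= n_high", call. = FALSE)
  if (any(shared > n_low)) stop("shared must be <= n_low", call. = FALSE)
  if (any(shared < 0)) stop("shared must be >= 0", call. = FALSE)
  x <- 1 - (1 - 2 * tolerance / gellen)^n_high
  pbinom(shared - 1, n_low, x, lower.tail = FALSE)
}

#' Smallest shared-band count significant at a cutoff
#'
#' @inheritParams sulston_score
#' @param cutoff Sulston probability cutoff.
#' @return smallest integer `s` with `sulston_score(...) <= cutoff`, or NA
#'   if even complete sharing is not significant.
#' @export
min_significant_shared <- function(n_low, n_high, tolerance, gellen, cutoff) {
  s <- 0:n_low
  p <- sulston_score(n_low, n_high, s, tolerance, gellen)
  hit <- which(p <= cutoff)
  if (!length(hit)) NA_integer_ else s[hit[1]]
}

#' Shared band count between two profiles
#'
#' Size of a maximum one-to-one matching between the two band multisets with
#' absolute size difference at most `tolerance` (two-pointer matching on the
#' sorted lists; symmetric).
#'
#' @param a,b integer band vectors.
#' @param tolerance matching tolerance (>= 0).
#' @return integer matched count.
#' @export
shared_band_count <- function(a, b, tolerance = 1) {
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  .match_count_cpp(as.integer(a), as.integer(b), as.integer(tolerance))
}

#' Build the overlap net
#'
#' Computes shared band counts for all clone pairs and keeps the pairs whose
#' Sulston probability is at most `cfg$net_cutoff`.
#'
#' @param set a filtered `fingerprint_set`.
#' @param cfg an [assembly_config()].
#' @return an object of class `overlap_net`: fields `clones`, `n_bands`,
#'   `edges` (data.frame `a`, `b`, `shared`, `sulston_p`), `cutoff`, `cfg`.
#' @export
build_net <- function(set, cfg = assembly_config()) {
  stopifnot(inherits(set, "fingerprint_set"))
  ids <- names(set$profiles)
  nb <- lengths(set$profiles)
  n_max <- max(c(nb, 1L))
  x_max <- 1 - (1 - 2 * cfg$tolerance / cfg$gellen)^n_max
  lax <- max(cfg$net_cutoff, cfg$support_cutoff)
  s_floor <- if (x_max <= 0) 1L else max(1L, ceiling(log(lax) / log(x_max)))
  pairs <- .pair_match_counts_cpp(set$profiles, as.integer(cfg$tolerance),
                                  as.integer(s_floor))
  empty <- data.frame(a = character(0), b = character(0),
                      shared = integer(0), sulston_p = numeric(0),
                      stringsAsFactors = FALSE)
  edges <- sub_edges <- empty
  if (nrow(pairs)) {
    n_i <- nb[pairs$i]; n_j <- nb[pairs$j]
    p <- sulston_score(pmin(n_i, n_j), pmax(n_i, n_j), pairs$shared,
                       cfg$tolerance, cfg$gellen)
    keep <- p <= cfg$net_cutoff
    edges <- data.frame(a = ids[pairs$i][keep], b = ids[pairs$j][keep],
                        shared = pairs$shared[keep], sulston_p = p[keep],
                        stringsAsFactors = FALSE)
    sub <- !keep & p <= lax
    sub_edges <- data.frame(a = ids[pairs$i][sub], b = ids[pairs$j][sub],
                            shared = pairs$shared[sub], sulston_p = p[sub],
                            stringsAsFactors = FALSE)
  }
  # self-calibrated band retention: near-identical clone pairs reach a
  # matched fraction of about (1 - miss)^2 * P(jitter within tolerance);
  # the top of the matched-fraction distribution estimates it, and layout
  # offsets divide by it so noisy maps keep physical scale
  retention <- 1
  if (nrow(edges) > 10) {
    ratio <- corrected_overlap_fraction(edges$shared, nb[edges$a], nb[edges$b],
                                        cfg$tolerance, cfg$gellen)
    retention <- min(max(unname(stats::quantile(ratio, 0.99)), 0.25), 1)
  }
  structure(list(clones = ids, n_bands = nb, edges = edges,
                 sub_edges = sub_edges, retention = retention,
                 cutoff = cfg$net_cutoff, cfg = cfg),
            class = "overlap_net")
}

#' @export
print.overlap_net <- function(x, ...) {
  cat(sprintf("overlap_net: %d clones, %d edges at cutoff %g\n",
              length(x$clones), nrow(x$edges), x$cutoff))
  invisible(x)
}

# igraph view of a net, optionally restricted to a cutoff and a clone subset.
net_igraph <- function(net, cutoff = NULL, clones = NULL) {
  ed <- net$edges
  if (!is.null(cutoff)) ed <- ed[ed$sulston_p <= cutoff, , drop = FALSE]
  verts <- if (is.null(clones)) net$clones else clones
  if (!is.null(clones)) ed <- ed[ed$a %in% clones & ed$b %in% clones, , drop = FALSE]
  igraph::graph_from_data_frame(ed, directed = FALSE,
                                vertices = data.frame(name = verts))
}

#' Remove questionable clones and overlaps
#'
#' A questionable overlap (Q-overlap) is an edge weaker than
#' `cfg$q_overlap_cutoff` whose endpoints have no alternative path of length
#' at most 2 through stronger edges; such an uncorroborated weak link is
#' removed. A questionable clone (Q-clone) bridges otherwise-separate
#' clusters: removing it splits its neighborhood into two or more connected
#' components, each containing at least `cfg$q_clone_min_side` clones.
#' Q-clones are removed from the net (they may later be appended to an MTP
#' as flagged material).
#'
#' @param net an `overlap_net`.
#' @param cfg an [assembly_config()].
#' @return list with `net` (cleaned), `q_clones` (character), `q_overlaps`
#'   (data.frame of removed edges).
#' @export
remove_q_elements <- function(net, cfg = net$cfg) {
  ed <- net$edges
  weak <- which(ed$sulston_p > cfg$q_overlap_cutoff)
  removed_edges <- ed[0, , drop = FALSE]
  if (length(weak)) {
    # p-value lookup per neighbor for the alternative-path test
    nb_p <- split(data.frame(n = c(ed$b, ed$a),
                             p = c(ed$sulston_p, ed$sulston_p),
                             stringsAsFactors = FALSE),
                  c(ed$a, ed$b))
    corroborated <- vapply(weak, function(k) {
      pa <- nb_p[[ed$a[k]]]; pb <- nb_p[[ed$b[k]]]
      p_e <- ed$sulston_p[k]
      # no common neighbor at all: the pair sits at a thin junction where
      # corroboration is impossible, so the edge cannot be questioned;
      # otherwise require a 2-hop path through edges stronger than e
      common_any <- length(intersect(setdiff(pa$n, ed$b[k]),
                                     setdiff(pb$n, ed$a[k]))) > 0
      if (!common_any) return(TRUE)
      t_a <- pa$n[pa$p < p_e]; t_b <- pb$n[pb$p < p_e]
      length(intersect(t_a, t_b)) > 0
    }, logical(1))
    drop_idx <- weak[!corroborated]
    removed_edges <- ed[drop_idx, , drop = FALSE]
    if (length(drop_idx)) ed <- ed[-drop_idx, , drop = FALSE]
  }
  # Q-clones on the cleaned net at q_clone_cutoff
  g <- igraph::graph_from_data_frame(
    ed[ed$sulston_p <= cfg$q_clone_cutoff, c("a", "b"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = net$clones))
  # direct pair evidence at the lax support cutoff, for the bridge-vs-
  # chimera distinction
  support <- rbind(ed[, c("a", "b")],
                   if (!is.null(net$sub_edges)) net$sub_edges[, c("a", "b")])
  support_key <- c(paste(support$a, support$b, sep = "\r"),
                   paste(support$b, support$a, sep = "\r"))
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  vnames <- rownames(adj)
  q_clones <- character(0)
  for (v in vnames) {
    nbrs <- vnames[adj[v, ]]
    if (length(nbrs) < 2) next
    sub <- adj[nbrs, nbrs, drop = FALSE]
    gg <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    comp <- igraph::components(gg)
    big <- which(comp$csize >= cfg$q_clone_min_side)
    if (length(big) < 2) next
    # genuine low-coverage bridges: a clone pair across the two sides still
    # shares weak band similarity; chimera flanks are unrelated
    bridged <- FALSE
    for (i in seq_len(length(big) - 1)) {
      for (j in seq(i + 1, length(big))) {
        s1 <- nbrs[comp$membership == big[i]]
        s2 <- nbrs[comp$membership == big[j]]
        cross <- as.vector(outer(s1, s2, function(x, y) paste(x, y, sep = "\r")))
        if (any(cross %in% support_key)) { bridged <- TRUE; break }
      }
      if (bridged) break
    }
    if (!bridged) q_clones <- c(q_clones, v)
  }
  if (length(q_clones)) {
    keep <- !(ed$a %in% q_clones | ed$b %in% q_clones)
    ed <- ed[keep, , drop = FALSE]
  }
  cleaned <- net
  cleaned$edges <- ed
  cleaned$clones <- setdiff(net$clones, q_clones)
  cleaned$n_bands <- net$n_bands[cleaned$clones]
  list(net = cleaned, q_clones = q_clones, q_overlaps = removed_edges)
}

# matched fraction corrected for expected coincidental matches on the
# integer band grid (matching window 2*tol+1 of gellen positions)
corrected_overlap_fraction <- function(shared, nb_a, nb_b, tolerance, gellen) {
  n_low <- pmin(nb_a, nb_b)
  x <- 1 - (1 - (2 * tolerance + 1) / gellen)^pmax(nb_a, nb_b)
  pmax((shared / n_low - x) / (1 - x), 0)
}

# physical edge length between overlapping clones, kb; `retention`
# rescales matched fractions for band noise (1 = noise-free)
edge_phys_length <- function(shared, nb_a, nb_b, insert_mean_kb, retention = 1,
                             tolerance = 1, gellen = 1804) {
  frac <- pmin(corrected_overlap_fraction(shared, nb_a, nb_b, tolerance, gellen) /
                 retention, 1)
  pmax(insert_mean_kb * (1 - frac), 0)
}

#' Lay out a contig and check linearity
#'
#' Clone order comes from seriation on the overlap graph: shortest-path
#' distances with edge lengths `insert * (1 - shared / min(n_bands))` (an
#' overlap-derived physical distance); the two mutually most distant clones
#' (double-sweep) serve as provisional ends, and clones are ordered by
#' distance from one end. Coordinates place consecutive clones at that
#' physical offset. A clone is branching when it has three or more
#' neighbors that are pairwise non-adjacent in the net (a linear order
#' admits at most two such directions); a layout is linear when no clone
#' branches.
#'
#' @param clone_ids clones of one connected component.
#' @param net an `overlap_net` (edges restricted to the component are used).
#' @param cfg an [assembly_config()].
#' @param cutoff optional cutoff at which the component's edges are taken
#'   (default the net's cutoff).
#' @return an object of class `contig_layout`: `clones` (ordered),
#'   `coord_kb` (named, start coordinates), `length_kb`, `depth`, `linear`,
#'   `branching_clones`.
#' @export
layout_and_check_linearity <- function(clone_ids, net, cfg = net$cfg,
                                       cutoff = NULL) {
  ins <- cfg$insert_mean_kb
  if (length(clone_ids) == 1) {
    return(structure(list(contig_id = NA_character_, clones = clone_ids,
                          coord_kb = setNames(0, clone_ids),
                          length_kb = ins, depth = 1, linear = TRUE,
                          branching_clones = character(0)),
                     class = "contig_layout"))
  }
  ed <- net$edges
  if (!is.null(cutoff)) ed <- ed[ed$sulston_p <= cutoff, , drop = FALSE]
  ed <- ed[ed$a %in% clone_ids & ed$b %in% clone_ids, , drop = FALSE]
  ret <- if (is.null(net$retention)) 1 else net$retention
  ed$weight <- pmax(edge_phys_length(ed$shared, net$n_bands[ed$a],
                                     net$n_bands[ed$b], ins, ret,
                                     cfg$tolerance, cfg$gellen), 0.5)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(name = clone_ids))
  if (igraph::components(g)$no > 1) {
    stop("layout_and_check_linearity() requires a connected component", call. = FALSE)
  }
  # double sweep for provisional ends
  d0 <- igraph::distances(g, v = clone_ids[1], weights = igraph::E(g)$weight)[1, ]
  end_a <- names(which.max(d0))
  d_a <- igraph::distances(g, v = end_a, weights = igraph::E(g)$weight)[1, ]
  rk <- rank(d_a, ties.method = "first")
  # coordinates: least-squares 1-d embedding of the overlap-implied
  # distances, signed by the seriation order; averaging over every edge
  # avoids the zigzag accumulation a predecessor-offset walk suffers when
  # nearby clones are locally permuted
  n <- length(clone_ids)
  ia <- match(ed$a, clone_ids); ib <- match(ed$b, clone_ids)
  dl <- edge_phys_length(ed$shared, net$n_bands[ed$a], net$n_bands[ed$b],
                         ins, ret, cfg$tolerance, cfg$gellen)
  # containment edges (a band set inside a distinctly longer clone's, at a
  # fully-matched corrected fraction) carry no distance information: the
  # short clone could sit anywhere inside the long one. Drop them from the
  # fit and let the short clone's partial overlaps place it -- FPC's
  # buried-clone treatment. Clones left edgeless keep one containment edge.
  nbv <- net$n_bands[clone_ids]
  fracv <- corrected_overlap_fraction(ed$shared, net$n_bands[ed$a],
                                      net$n_bands[ed$b], cfg$tolerance,
                                      cfg$gellen)
  containment <- fracv >= 0.95 &
    pmin(nbv[ia], nbv[ib]) <= 0.8 * pmax(nbv[ia], nbv[ib])
  deg <- tabulate(c(ia[!containment], ib[!containment]), nbins = n)
  for (k in which(containment)) {
    if (deg[ia[k]] == 0 || deg[ib[k]] == 0) {
      containment[k] <- FALSE
      deg[ia[k]] <- deg[ia[k]] + 1; deg[ib[k]] <- deg[ib[k]] + 1
    }
  }
  act_edge <- which(!containment)
  L <- matrix(0, n, n)
  for (k in act_edge) {
    i <- ia[k]; j <- ib[k]
    L[i, i] <- L[i, i] + 1; L[j, j] <- L[j, j] + 1
    L[i, j] <- L[i, j] - 1; L[j, i] <- L[j, i] - 1
  }
  # edge-dropping can disconnect the fit; regularize every diagonal a bit
  diag(L) <- diag(L) + 1e-6
  for (iter in 1:5) {
    sgn <- ifelse(rk[ib] > rk[ia], 1, -1)
    rhs <- numeric(n)
    for (k in act_edge) {
      dk <- sgn[k] * dl[k]
      rhs[ia[k]] <- rhs[ia[k]] - dk; rhs[ib[k]] <- rhs[ib[k]] + dk
    }
    p <- solve(L, rhs)
    rk2 <- rank(p, ties.method = "first")
    if (all(rk2 == rk)) break
    rk <- rk2
  }
  # local refinement: for order-adjacent clones the difference of shared
  # counts against a flanking anchor clone cancels the bands the pair has
  # in common, leaving a nearly noise-free relative-position vote
  sh <- matrix(0L, n, n)
  for (k in seq_len(nrow(ed))) {
    sh[ia[k], ib[k]] <- ed$shared[k]; sh[ib[k], ia[k]] <- ed$shared[k]
  }
  for (sweep in 1:10) {
    idx <- order(p)
    swapped <- FALSE
    for (t in seq_len(n - 1)) {
      u <- idx[t]; v <- idx[t + 1]
      anchors <- which(sh[u, ] > 0 & sh[v, ] > 0)
      anchors <- setdiff(anchors, c(u, v))
      if (!length(anchors)) next
      vote <- 0
      for (k in anchors) {
        d <- sh[u, k] - sh[v, k]
        if (d == 0) next
        if (p[k] < min(p[u], p[v])) {
          vote <- vote - d  # left anchor: the closer clone shares more
        } else if (p[k] > max(p[u], p[v])) {
          vote <- vote + d
        }
      }
      if (vote > 0) {  # v should precede u
        tmp <- p[u]; p[u] <- p[v]; p[v] <- tmp
        idx[t] <- v; idx[t + 1] <- u
        swapped <- TRUE
      }
    }
    if (!swapped) break
  }
  names(p) <- clone_ids
  ord <- clone_ids[order(p, rk)]
  coord <- p[ord] - min(p)
  # branching check: >= 3 pairwise separated neighbors. Two neighbors are
  # separated when they have no edge AND no corroborating common neighbor
  # besides the clone under test: band noise drops borderline edges, but a
  # dropped edge inside a linear run leaves many common neighbors, whereas
  # a true branch direction leaves none.
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  common <- crossprod(adj)  # common-neighbor counts
  branching <- character(0)
  for (v in clone_ids) {
    nbrs <- which(adj[v, ])
    if (length(nbrs) < 3) next
    sep <- !adj[nbrs, nbrs, drop = FALSE] &
      (common[nbrs, nbrs, drop = FALSE] - 1L < 1L)
    diag(sep) <- FALSE
    # triangle in the separation graph = 3 pairwise separated neighbors
    if (any((sep %*% sep) * sep > 0)) branching <- c(branching, v)
  }
  len <- max(coord) + ins - min(coord)
  structure(list(contig_id = NA_character_, clones = ord, coord_kb = coord,
                 length_kb = len,
                 depth = length(ord) * ins / len,
                 linear = length(branching) == 0,
                 branching_clones = branching),
            class = "contig_layout")
}

#' @export
print.contig_layout <- function(x, ...) {
  cat(sprintf("contig_layout %s: %d clones, %.0f kb, depth %.1fx, %s\n",
              ifelse(is.na(x$contig_id), "<unnamed>", x$contig_id),
              length(x$clones), x$length_kb, x$depth,
              if (x$linear) "linear" else
                sprintf("non-linear (%d branching)", length(x$branching_clones))))
  invisible(x)
}

#' Contig length and assembly depth
#'
#' Length is the span of the layout plus one insert; depth is the calculated
#' length (clone count times the average insert size) divided by the actual
#' length.
#'
#' @param layout a `contig_layout`.
#' @param insert_mean_kb average insert size in kb.
#' @return list with `length_kb` and `depth`.
#' @export
contig_stats <- function(layout, insert_mean_kb = 143) {
  len <- max(layout$coord_kb) + insert_mean_kb - min(layout$coord_kb)
  list(length_kb = len, depth = length(layout$clones) * insert_mean_kb / len)
}

#' Adaptive clustering into linear contigs
#'
#' Connected components of the (Q-filtered) net are candidate contigs. Each
#' is linearity-checked; a non-linear component is re-clustered at the next
#' more stringent cutoff of a geometric schedule from `net_cutoff` to
#' `final_cutoff` in `n_steps` steps. Components still non-linear at the
#' final cutoff have their branching clones excluded and are re-checked.
#' Output contigs are all linear and are partitioned into main contigs
#' (at least `min_contig_clones` clones), short contigs (2 to
#' `min_contig_clones - 1` clones) and singletons.
#'
#' @param net a Q-filtered `overlap_net`.
#' @param cfg an [assembly_config()].
#' @return list with `contigs` (main, list of `contig_layout`),
#'   `short_contigs`, `singletons` (character), `excluded_clones`
#'   (branching clones dropped at the final cutoff).
#' @export
adaptive_cluster <- function(net, cfg = net$cfg) {
  cutoffs <- 10^seq(log10(cfg$net_cutoff), log10(cfg$final_cutoff),
                    length.out = cfg$n_steps + 1)
  accepted <- list()
  singletons <- character(0)
  excluded <- character(0)
  queue <- list(list(clones = net$clones, step = 1L))
  while (length(queue)) {
    item <- queue[[1]]; queue <- queue[-1]
    g <- net_igraph(net, cutoff = cutoffs[item$step], clones = item$clones)
    comp <- igraph::components(g)
    for (ci in seq_len(comp$no)) {
      members <- names(comp$membership)[comp$membership == ci]
      if (length(members) == 1) { singletons <- c(singletons, members); next }
      lay <- layout_and_check_linearity(members, net, cfg, cutoff = cutoffs[item$step])
      if (lay$linear) {
        accepted[[length(accepted) + 1]] <- lay
      } else if (item$step < length(cutoffs)) {
        queue[[length(queue) + 1]] <- list(clones = members, step = item$step + 1L)
      } else {
        # final cutoff: exclude branching clones until the pieces are linear
        remaining <- members
        final_cut <- cutoffs[length(cutoffs)]
        while (length(remaining)) {
          gg <- net_igraph(net, cutoff = final_cut, clones = remaining)
          cc <- igraph::components(gg)
          still_bad <- character(0)
          bad <- character(0)
          for (cj in seq_len(cc$no)) {
            mem <- names(cc$membership)[cc$membership == cj]
            if (length(mem) == 1) { singletons <- c(singletons, mem); next }
            lay2 <- layout_and_check_linearity(mem, net, cfg, cutoff = final_cut)
            if (lay2$linear) {
              accepted[[length(accepted) + 1]] <- lay2
            } else {
              bad <- c(bad, lay2$branching_clones)
              still_bad <- c(still_bad, setdiff(mem, lay2$branching_clones))
            }
          }
          excluded <- c(excluded, bad)
          remaining <- still_bad
          if (!length(bad)) break
        }
      }
    }
  }
  # name contigs by decreasing clone count
  sizes <- vapply(accepted, function(l) length(l$clones), integer(1))
  ord <- order(-sizes)
  accepted <- accepted[ord]
  for (k in seq_along(accepted)) accepted[[k]]$contig_id <- sprintf("CTG%d", k)
  main <- accepted[vapply(accepted, function(l)
    length(l$clones) >= cfg$min_contig_clones, logical(1))]
  short <- accepted[vapply(accepted, function(l)
    length(l$clones) < cfg$min_contig_clones, logical(1))]
  list(contigs = main, short_contigs = short,
       singletons = unique(singletons), excluded_clones = unique(excluded))
}

#' Clone partition implied by an assembly
#'
#' @param assembly result of [adaptive_cluster()].
#' @param all_clones optional full clone id universe; clones absent from the
#'   assembly (filtered, excluded) become singletons.
#' @return named integer vector of cluster labels.
#' @export
assembly_partition <- function(assembly, all_clones = NULL) {
  labs <- integer(0)
  nxt <- 1L
  for (lay in c(assembly$contigs, assembly$short_contigs)) {
    labs[lay$clones] <- nxt
    nxt <- nxt + 1L
  }
  rest <- setdiff(c(assembly$singletons, all_clones), names(labs))
  labs[rest] <- seq(nxt, length.out = length(rest))
  labs
}
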