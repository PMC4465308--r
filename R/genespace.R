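#' Classify genes into islands and isolated genes
#'
#' Genes located on the same or on overlapping BAC clones form islands.
#' A graph is built over assigned genes with an edge when two genes share a
#' clone or when their clones overlap (an edge in the overlap net, or
#' adjacency within `window_kb` on the same contig when a net is not
#' supplied); connected components of size two or more are islands,
#' singletons are isolated genes.
#'
#' @param assignments data.frame of gene-marker assignments (`marker_id`,
#'   `clones` comma-separated, `status`); only "assigned" rows are used.
#' @param net optional `overlap_net` to decide clone overlap.
#' @param map optional clone placement data.frame (`clone_id`, `contig_id`,
#'   `coord_kb`) used when `net` is NULL.
#' @param window_kb clone span window used with `map` (default 143).
#' @return list with `labels` (data.frame `marker_id`, `island`, `component`)
#'   and `excluded` (unassigned marker ids).
#' @export
classify_island_genes <- function(assignments, net = NULL, map = NULL,
                                  window_kb = 143) {
  ok <- assignments[assignments$status == "assigned" & nzchar(assignments$clones), ,
                    drop = FALSE]
  excluded <- setdiff(assignments$marker_id, ok$marker_id)
  if (!nrow(ok)) {
    return(list(labels = data.frame(marker_id = character(0), island = logical(0),
                                    component = integer(0)),
                excluded = excluded))
  }
  clones_of <- strsplit(ok$clones, ",")
  names(clones_of) <- ok$marker_id
  clone_overlaps <- function(c1, c2) {
    if (any(c1 %in% c2)) return(TRUE)
    if (!is.null(net)) {
      ed <- net$edges
      return(any((ed$a %in% c1 & ed$b %in% c2) | (ed$a %in% c2 & ed$b %in% c1)))
    }
    if (!is.null(map)) {
      m1 <- map[map$clone_id %in% c1, , drop = FALSE]
      m2 <- map[map$clone_id %in% c2, , drop = FALSE]
      if (!nrow(m1) || !nrow(m2)) return(FALSE)
      for (i in seq_len(nrow(m1))) {
        same <- m2$contig_id == m1$contig_id[i] &
          abs(m2$coord_kb - m1$coord_kb[i]) < window_kb
        if (any(same, na.rm = TRUE)) return(TRUE)
      }
    }
    FALSE
  }
  n <- nrow(ok)
  edges <- list()
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq(i + 1, n)) {
      if (clone_overlaps(clones_of[[i]], clones_of[[j]])) {
        edges[[length(edges) + 1]] <- c(i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, unlist(edges))
  comp <- igraph::components(g)
  labels <- data.frame(marker_id = ok$marker_id,
                       island = comp$csize[comp$membership] >= 2,
                       component = comp$membership,
                       stringsAsFactors = FALSE)
  list(labels = labels, excluded = excluded)
}

#' Per-bin gene content and organization table
#'
#' One row per deletion bin with counts and densities (genes/Mb of
#' cumulative mapped contig length) for syntenic, non-syntenic, total,
#' in-island and isolated genes. Row identities `syntenic + non-syntenic =
#' total` and `islands + isolated = total` hold by construction.
#'
#' @param labels island labels from [classify_island_genes()].
#' @param gene_bins named character: marker id -> bin label.
#' @param gene_syntenic named logical: marker id -> syntenic flag.
#' @param bin_lengths_kb named numeric: cumulative mapped length per bin.
#' @param digits densities are additionally reported rounded to this many
#'   decimals (default 2); raw values are retained.
#' @return data.frame of class `gene_space_table`.
#' @export
tabulate_bin_gene_stats <- function(labels, gene_bins, gene_syntenic,
                                    bin_lengths_kb, digits = 2) {
  bins <- names(bin_lengths_kb)
  rows <- lapply(bins, function(b) {
    mks <- labels$marker_id[gene_bins[labels$marker_id] == b]
    mks <- mks[!is.na(mks)]
    len_mb <- bin_lengths_kb[[b]] / 1000
    syn <- sum(gene_syntenic[mks], na.rm = TRUE)
    tot <- length(mks)
    isl <- sum(labels$island[match(mks, labels$marker_id)])
    dens <- function(k) if (len_mb > 0) k / len_mb else NA_real_
    data.frame(bin = b,
               syntenic_n = syn, syntenic_density = dens(syn),
               nonsyntenic_n = tot - syn, nonsyntenic_density = dens(tot - syn),
               total_n = tot, total_density = dens(tot),
               islands_n = isl, islands_density = dens(isl),
               isolated_n = tot - isl, isolated_density = dens(tot - isl),
               length_mb = len_mb,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  for (cl in grep("_density$", names(out), value = TRUE)) {
    out[[paste0(cl, "_2dp")]] <- round(out[[cl]], digits)
  }
  class(out) <- c("gene_space_table", class(out))
  out
}

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson r with `p` from `t = r * sqrt((n-2)/(1-r^2))` on `n - 2`
#' degrees of freedom, two-sided.
#'
#' @param x,y numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
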