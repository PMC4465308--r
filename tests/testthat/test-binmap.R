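test_that("deletion-line presence patterns map to bins", {
  r1 <- infer_bin_from_deletion_lines(c("5DS-5" = FALSE, "5DS-2" = FALSE))
  expect_identical(r1$bin, "0.78-1.00")
  r2 <- infer_bin_from_deletion_lines(c("5DS-5" = FALSE, "5DS-2" = TRUE))
  expect_identical(r2$bin, "0.67-0.78")
  r3 <- infer_bin_from_deletion_lines(c("5DS-5" = TRUE, "5DS-2" = TRUE))
  expect_identical(r3$status, "proximal_unrefined")
  expect_identical(r3$bin, "0-0.67")
  r3b <- infer_bin_from_deletion_lines(c("5DS-5" = TRUE, "5DS-2" = TRUE),
                                       genetic_bin = "0.63-0.67")
  expect_identical(r3b$bin, "0.63-0.67")
  r4 <- infer_bin_from_deletion_lines(c("5DS-5" = TRUE, "5DS-2" = FALSE))
  expect_identical(r4$status, "inconsistent")
  expect_true(is.na(r4$bin))
})

test_that("contig bin assignment uses majority vote with conflict flags", {
  asg <- data.frame(marker_id = c("m1", "m2", "m3", "m4"),
                    contig_id = c("CTG1", "CTG1", "CTG1", "CTG2"),
                    status = "assigned", stringsAsFactors = FALSE)
  bins <- c(m1 = "A", m2 = "A", m3 = "B", m4 = "C")
  res <- assign_contigs_to_bins(asg, bins)
  r1 <- res[res$contig_id == "CTG1", ]
  expect_identical(r1$bin, "A")
  expect_true(r1$conflict)
  expect_match(r1$candidate_bins, "A")
  expect_match(r1$candidate_bins, "B")
  r2 <- res[res$contig_id == "CTG2", ]
  expect_identical(r2$bin, "C")
  expect_false(r2$conflict)
})

test_that("bin size correction reproduces the published estimates", {
  # printed bin lengths (Mb), centromere outward; printed cumulative 138.3
  lens <- c("0-0.63" = 72.92, "0.63-0.67" = 29.71,
            "0.67-0.78" = 7.93, "0.78-1.00" = 26.54) * 1000
  est <- estimate_bin_sizes(lens, 258000, total_mapped_kb = 138300)
  distal <- est[est$bin == "0.78-1.00", ]
  expect_equal(distal$corrected_kb / 1000, 49.5, tolerance = 0.002)
  expect_equal(distal$share, 0.192, tolerance = 0.001)
  narrow <- est[est$bin == "0.63-0.67", ]
  expect_gt(narrow$corrected_kb / 1000, 55)

  # all contigs in one bin: corrected size equals the arm length
  one <- estimate_bin_sizes(c(X = 5000), 258000)
  expect_equal(one$corrected_kb, 258000)

  # algebraic identity: corrected sizes always sum to the arm length
  set.seed(11)
  for (k in 1:5) {
    v <- setNames(runif(4, 100, 9000), letters[1:4])
    est2 <- estimate_bin_sizes(v, 258000)
    expect_equal(sum(est2$corrected_kb), 258000)
    expect_equal(sum(est2$share), 1)
  }
  expect_error(estimate_bin_sizes(c(a = 0), 1000), "mapped")
})

test_that("within-bin ordering follows median ranks with flags", {
  ba <- data.frame(contig_id = c("C1", "C2", "C3"), bin = "A",
                   conflict = FALSE, candidate_bins = "A", n_markers = 3,
                   evidence = "", stringsAsFactors = FALSE)
  mc <- data.frame(marker_id = sprintf("m%d", 1:9),
                   contig_id = rep(c("C1", "C2", "C3"), each = 3),
                   stringsAsFactors = FALSE)
  rk <- data.frame(marker_id = sprintf("m%d", 1:9), reference = "tauschii",
                   rank = c(8, 9, 10, 1, 2, 3, 4, 5, 6),
                   stringsAsFactors = FALSE)
  res <- order_contigs_within_bins(ba, mc, rk)
  ord <- res$ordered
  expect_equal(ord$within_bin_rank[match(c("C2", "C3", "C1"), ord$contig_id)],
               c(1, 2, 3))
  expect_true(all(ord$orientable))

  # one ortholog matched by contigs in different bins -> duplication entry
  ba2 <- data.frame(contig_id = c("C1", "C2"), bin = c("A", "B"),
                    conflict = FALSE, candidate_bins = "", n_markers = 1,
                    evidence = "", stringsAsFactors = FALSE)
  mc2 <- data.frame(marker_id = c("m1", "m2", "m3", "m4"),
                    contig_id = c("C1", "C2", "C1", "C2"),
                    stringsAsFactors = FALSE)
  rk2 <- data.frame(marker_id = c("m1", "m2", "m3", "m4"),
                    reference = "tauschii", rank = c(5, 5, 1, 9),
                    stringsAsFactors = FALSE)
  res2 <- order_contigs_within_bins(ba2, mc2, rk2)
  expect_equal(nrow(res2$duplications), 1)
  expect_equal(res2$duplications$rank, 5)

  # rank clusters separated far beyond the span threshold -> split flag
  ba3 <- data.frame(contig_id = "C1", bin = "A", conflict = FALSE,
                    candidate_bins = "", n_markers = 5, evidence = "",
                    stringsAsFactors = FALSE)
  mc3 <- data.frame(marker_id = sprintf("m%d", 1:5), contig_id = "C1",
                    stringsAsFactors = FALSE)
  rk3 <- data.frame(marker_id = sprintf("m%d", 1:5), reference = "tauschii",
                    rank = c(3, 4, 5, 210, 211), stringsAsFactors = FALSE)
  rk3 <- rbind(rk3, data.frame(marker_id = "anchor", reference = "tauschii",
                               rank = 250))
  res3 <- order_contigs_within_bins(ba3, mc3, rk3)
  expect_equal(res3$split_contigs$contig_id, "C1")
  expect_equal(res3$split_contigs$n_clusters, 2)

  # zipper-only contigs are interleaved through the rescaled secondary rank
  ba4 <- data.frame(contig_id = c("C1", "C2", "C3"), bin = "A",
                    conflict = FALSE, candidate_bins = "", n_markers = 1,
                    evidence = "", stringsAsFactors = FALSE)
  mc4 <- data.frame(marker_id = c("t1", "t2", "z1", "z2", "z3"),
                    contig_id = c("C1", "C3", "C1", "C2", "C3"),
                    stringsAsFactors = FALSE)
  rk4 <- rbind(
    data.frame(marker_id = c("t1", "t2"), reference = "tauschii",
               rank = c(10, 30), stringsAsFactors = FALSE),
    data.frame(marker_id = c("z1", "z2", "z3"), reference = "zipper",
               rank = c(100, 200, 300), stringsAsFactors = FALSE))
  res4 <- order_contigs_within_bins(ba4, mc4, rk4)
  ord4 <- res4$ordered
  expect_equal(ord4$within_bin_rank[match(c("C1", "C2", "C3"), ord4$contig_id)],
               c(1, 2, 3))
})

test_that("supercontig elongation joins split pieces by end-clone overlaps", {
  # noisy world: adaptive splitting plus Q-removal leave rejoinable pieces
  w <- build_world(1, noisy = TRUE, coverage = "standard")
  layouts <- c(w$asm$contigs, w$asm$short_contigs)
  sc <- elongate_supercontigs(layouts, w$net, cfg = w$acfg)
  expect_gt(length(sc$supercontigs), 0)
  all_members <- unlist(lapply(sc$supercontigs, `[[`, "members"))
  expect_equal(anyDuplicated(all_members), 0)  # partition property
  for (s in sc$supercontigs) {
    expect_equal(s$total_clones, sum(s$clone_counts))
    expect_true(s$layout$linear)
    # merged members really belong to one true island
    truth <- w$truth[s$layout$clones]
    expect_equal(length(unique(truth)), 1)
  }
  expect_true(all(setdiff(names(layouts), all_members) %in% sc$unmerged))

  # clone-count bookkeeping of the published example
  expect_equal(sum(c(251, 61, 136)), 448)
})

test_that("elongation requires end clones: interior-only links never merge", {
  arm <- simulate_arm(2000, 2, seed = 21)
  starts <- seq(50, by = 60, length.out = 16)
  clones <- data.frame(clone_id = sprintf("E%02d", seq_along(starts)),
                       start_kb = starts, end_kb = starts + 143,
                       is_contaminant = FALSE, source = "target",
                       stringsAsFactors = FALSE)
  net <- build_net(fingerprint_library(clones, arm, no_noise()), assembly_config())
  half1 <- clones$clone_id[1:8]; half2 <- clones$clone_id[9:16]
  lay1 <- layout_and_check_linearity(half1, net)
  lay1$contig_id <- "H1"
  lay2 <- layout_and_check_linearity(half2, net)
  lay2$contig_id <- "H2"
  # drop every cross-half edge that touches an end clone (window 2)
  e1 <- contig_ends(lay1, 2); e2 <- contig_ends(lay2, 2)
  ends <- c(unlist(e1), unlist(e2))
  cross <- (net$edges$a %in% half1 & net$edges$b %in% half2) |
    (net$edges$a %in% half2 & net$edges$b %in% half1)
  touch_end <- net$edges$a %in% ends | net$edges$b %in% ends
  net$edges <- net$edges[!(cross & touch_end), ]
  res <- elongate_supercontigs(list(H1 = lay1, H2 = lay2), net, cfg = net$cfg)
  expect_length(res$supercontigs, 0)
  expect_setequal(res$unmerged, c("H1", "H2"))
})

test_that("AGP export of the ordered bin map round-trips", {
  ordered <- data.frame(
    contig_id = c("CTG2", "CTG1", "CTG3"),
    bin = c("0-0.63", "0-0.63", "0.78-1.00"),
    conflict = FALSE, candidate_bins = "", n_markers = 2, evidence = "",
    order_value = c(1, 2, 1), orientable = c(TRUE, FALSE, TRUE),
    unplaced = FALSE, within_bin_rank = c(1L, 2L, 1L),
    stringsAsFactors = FALSE)
  lens <- c(CTG1 = 1200, CTG2 = 800, CTG3 = 430)
  f <- file.path(withr::local_tempdir(), "map.agp")
  write_agp(ordered, lens, f)
  back <- read_agp(f)
  expect_equal(back$contig_id, c("CTG2", "CTG1", "CTG3"))
  expect_equal(back$bin, ordered$bin)
  expect_equal(back$within_bin_rank, ordered$within_bin_rank)
  expect_equal(back$length_kb, unname(lens[back$contig_id]), tolerance = 1e-3)
  expect_equal(back$orientation, c("+", "?", "+"))
})
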