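test_that("shared_band_count equals the exhaustive matching oracle", {
  expect_equal(shared_band_count(c(100, 200, 300), c(100, 200, 300), 0), 3)
  expect_equal(shared_band_count(c(100, 200, 300), c(101, 205, 300), 2), 2)
  expect_equal(shared_band_count(c(100, 200), c(300, 400), 1), 0)
  expect_equal(shared_band_count(c(100, 200), integer(0), 1), 0)
  # symmetry + oracle agreement on random small multisets
  set.seed(1)
  for (k in 1:25) {
    a <- sample(1:30, sample(1:6, 1), replace = TRUE)
    b <- sample(1:30, sample(1:6, 1), replace = TRUE)
    tol <- sample(0:3, 1)
    m <- shared_band_count(a, b, tol)
    expect_identical(m, shared_band_count(b, a, tol))
    expect_equal(m, oracle_match_count(a, b, tol))
  }
})

test_that("sulston_score matches its closed form, bounds and examples", {
  expect_equal(sulston_score(5, 8, 0, 1, 100), 1.0)
  expect_equal(sulston_score(5, 8, 3, 0, 100), 0.0)
  expect_equal(sulston_score(3, 5, 2, 2, 100), 0.08967485, tolerance = 1e-6)
  # non-increasing in shared
  p <- sulston_score(10, 12, 0:10, 1, 451)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(sulston_score(3, 5, 4, 1, 100), "shared")
  expect_error(sulston_score(5, 3, 1, 1, 100), "n_low")
})

test_that("sulston_score agrees with the Monte-Carlo band-throwing oracle", {
  cases <- list(c(3, 5, 2, 2, 100), c(4, 6, 2, 1, 50), c(5, 5, 3, 2, 80))
  for (cs in cases) {
    mc <- oracle_sulston_mc(cs[1], cs[2], cs[3], cs[4], cs[5],
                            trials = 40000, seed = 42)
    f <- sulston_score(cs[1], cs[2], cs[3], cs[4], cs[5])
    expect_lt(abs(mc$p - f), 3 * mc$se)
  }
})

test_that("build_net keeps exactly the significant pairs", {
  set.seed(2)
  bands <- sort(band_code(sample(1:4, 30, TRUE), sample(50:500, 30)))
  s <- fingerprint_set(list(A = bands, B = bands,
                            C = band_code(sample(1:4, 30, TRUE), sample(50:500, 30))))
  cfg <- assembly_config()
  net <- build_net(s, cfg)
  key <- paste(net$edges$a, net$edges$b)
  expect_true("A B" %in% key)   # identical profiles: p far below 1e-15
  expect_false(any(grepl("C", key)))  # random clone: no edge
  expect_true(all(net$edges$sulston_p <= cfg$net_cutoff))
})

test_that("noise-free net contains every detectably-overlapping pair", {
  w <- build_contig50(3)
  tg <- w$clones
  nb <- w$net$n_bands
  key <- paste(w$net$edges$a, w$net$edges$b)
  for (i in seq_len(nrow(tg) - 1)) {
    for (j in seq(i + 1, nrow(tg))) {
      ni <- nb[[tg$clone_id[i]]]; nj <- nb[[tg$clone_id[j]]]
      s_needed <- min_significant_shared(min(ni, nj), max(ni, nj),
                                         w$acfg$tolerance, w$acfg$gellen,
                                         w$acfg$net_cutoff)
      sh <- length(intersect(
        fragments_in_interval(w$arm, tg$start_kb[i], tg$end_kb[i]),
        fragments_in_interval(w$arm, tg$start_kb[j], tg$end_kb[j])))
      if (!is.na(s_needed) && sh >= s_needed) {
        k1 <- paste(tg$clone_id[i], tg$clone_id[j])
        k2 <- paste(tg$clone_id[j], tg$clone_id[i])
        expect_true(k1 %in% key || k2 %in% key)
      }
    }
  }
})

test_that("chains stay intact and stars are flagged non-linear", {
  # chain A-B-C from real fragments: A and C do not overlap
  arm <- simulate_arm(600, 2, seed = 5)
  clones <- data.frame(
    clone_id = c("A", "B", "C"),
    start_kb = c(10, 90, 170), end_kb = c(160, 240, 320),
    is_contaminant = FALSE, source = "target", stringsAsFactors = FALSE)
  net <- build_net(fingerprint_library(clones, arm, no_noise()), assembly_config())
  q <- remove_q_elements(net)
  expect_equal(nrow(q$q_overlaps) + length(q$q_clones), 0)
  lay <- layout_and_check_linearity(c("A", "B", "C"), net)
  expect_true(lay$linear)
  expect_true(identical(lay$clones, c("A", "B", "C")) ||
                identical(lay$clones, c("C", "B", "A")))

  # star: hub overlaps three mutually non-overlapping clones
  arm2 <- simulate_arm(4000, 2, seed = 6)
  hubless <- data.frame(
    clone_id = c("L1", "L2", "L3"),
    start_kb = c(100, 1100, 2100), end_kb = c(250, 1250, 2250),
    is_contaminant = FALSE, source = "target", stringsAsFactors = FALSE)
  fps <- fingerprint_library(hubless, arm2, no_noise())
  hub_bands <- sort(arm2$band_codes[c(
    fragments_in_interval(arm2, 100, 250),
    fragments_in_interval(arm2, 1100, 1250),
    fragments_in_interval(arm2, 2100, 2250))])
  profs <- c(fps$profiles, list(HUB = hub_bands))
  net2 <- build_net(fingerprint_set(profs, "star"), assembly_config())
  lay2 <- layout_and_check_linearity(c("L1", "L2", "L3", "HUB"), net2)
  expect_false(lay2$linear)
  expect_identical(lay2$branching_clones, "HUB")
})

test_that("a planted chimera bridging two islands is flagged and split", {
  w <- build_chimera_world(11, n_chim = 1)
  expect_true(w$chim_ids %in% w$q$q_clones)
  expect_false(w$chim_ids %in% w$q$net$clones)
})

test_that("noise-free 50-clone layouts recover clone order (|rho| >= 0.99)", {
  for (s in c(1, 2)) {
    w <- build_contig50(s)
    lay <- w$asm$contigs[[1]]
    st <- setNames(w$clones$start_kb, w$clones$clone_id)
    rho <- abs(cor(lay$coord_kb, st[lay$clones], method = "spearman"))
    expect_gte(rho, 0.99)
    expect_true(lay$linear)
  }
})

test_that("contig_stats implements the depth arithmetic", {
  single <- structure(list(contig_id = "S", clones = "X",
                           coord_kb = c(X = 0), length_kb = 143, depth = 1,
                           linear = TRUE, branching_clones = character(0)),
                      class = "contig_layout")
  st <- contig_stats(single, 143)
  expect_equal(st$length_kb, 143)
  expect_equal(st$depth, 1.0)

  ten <- structure(list(contig_id = "T", clones = sprintf("C%d", 1:10),
                        coord_kb = setNames(seq(0, 507, length.out = 10),
                                            sprintf("C%d", 1:10)),
                        length_kb = 650, depth = NA, linear = TRUE,
                        branching_clones = character(0)),
                   class = "contig_layout")
  expect_equal(contig_stats(ten, 143)$depth, 10 * 143 / 650)
})

test_that("adaptive clustering separates short contigs and is monotone", {
  w <- build_world(2, noisy = TRUE, coverage = "standard")
  sizes_main <- vapply(w$asm$contigs, function(l) length(l$clones), integer(1))
  sizes_short <- vapply(w$asm$short_contigs, function(l) length(l$clones), integer(1))
  expect_true(all(sizes_main >= 6))
  if (length(sizes_short)) expect_true(all(sizes_short <= 5))
  expect_true(all(vapply(c(w$asm$contigs, w$asm$short_contigs),
                         `[[`, logical(1), "linear")))

  # monotone in stringency: components at a stricter cutoff refine the
  # looser components
  g1 <- igraph::graph_from_data_frame(
    w$q$net$edges[, 1:2], directed = FALSE,
    vertices = data.frame(name = w$q$net$clones))
  g2 <- igraph::graph_from_data_frame(
    w$q$net$edges[w$q$net$edges$sulston_p <= 1e-21, 1:2], directed = FALSE,
    vertices = data.frame(name = w$q$net$clones))
  m1 <- igraph::components(g1)$membership
  m2 <- igraph::components(g2)$membership
  # every strict-cutoff cluster lies inside one loose cluster
  expect_true(all(tapply(m1[names(m2)], m2, function(x) length(unique(x))) == 1))
})

test_that("large noisy contigs cluster near the library depth", {
  w <- build_world(2, noisy = TRUE, coverage = "standard")
  big <- Filter(function(l) length(l$clones) >= 26, w$asm$contigs)
  expect_gt(length(big), 3)
  depths <- vapply(big, `[[`, numeric(1), "depth")
  expect_true(all(depths > 6 & depths < 25))
  expect_gt(mean(depths > 10), 0.5)
})
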