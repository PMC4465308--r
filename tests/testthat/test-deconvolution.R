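# small pool design + map shared by the deconvolution tests
make_design <- function(n = 60, rows = 4, cols = 6) {
  ids <- sprintf("Q%03d", seq_len(n))
  design <- design_3d_pools(ids, plate_rows = rows, plate_cols = cols)
  map <- data.frame(clone_id = ids,
                    contig_id = paste0("CTG", (seq_len(n) - 1) %/% 10 + 1),
                    coord_kb = ((seq_len(n) - 1) %% 10) * 20,
                    stringsAsFactors = FALSE)
  list(ids = ids, design = design, map = map)
}

test_that("noise-free PCR screens light exactly one pool per dimension", {
  w <- make_design()
  res <- simulate_pcr_screen(w$ids[7], w$design, fp_rate = 0, fn_rate = 0)
  pos <- names(res$calls)[res$calls]
  expect_length(pos, 3)
  expect_setequal(pos, pools_of_clones(w$design, w$ids[7]))

  none <- simulate_pcr_screen(character(0), w$design, fp_rate = 0, fn_rate = 0)
  expect_false(any(none$calls))
})

test_that("PCR false negatives follow the stated per-pool rate", {
  w <- make_design()
  n_try <- 400
  miss <- 0L; tot <- 0L
  for (k in seq_len(n_try)) {
    res <- simulate_pcr_screen(w$ids[1], w$design, fp_rate = 0, fn_rate = 0.05,
                               seed = k)
    truth <- pools_of_clones(w$design, w$ids[1])
    miss <- miss + sum(!res$calls[truth])
    tot <- tot + length(truth)
  }
  expect_gte(miss, qbinom(5e-4, tot, 0.05))
  expect_lte(miss, qbinom(1 - 5e-4, tot, 0.05))
})

test_that("PCR deconvolution resolves addresses and flags ambiguity", {
  w <- make_design()
  res <- simulate_pcr_screen(w$ids[7], w$design, fp_rate = 0, fn_rate = 0)
  out <- deconvolve_pcr(res, w$design, w$map, marker_id = "m1")
  expect_identical(out$status, "assigned")
  expect_identical(out$clones, w$ids[7])
  expect_identical(out$tier, "high")

  none <- simulate_pcr_screen(character(0), w$design, fp_rate = 0, fn_rate = 0)
  out0 <- deconvolve_pcr(none, w$design, w$map, marker_id = "m0")
  expect_identical(out0$status, "unassigned")

  # 2 rows x 1 column x 1 plate: both addresses occupied but on different
  # contigs; the marker-bearing-contig prior resolves the call
  two <- make_design()
  a <- two$ids[1]    # plate 1, row 1, col 1 -> CTG1
  b <- two$ids[13]   # plate 1, row 3, col 1 -> CTG2
  res2 <- simulate_pcr_screen(c(a, b), two$design, fp_rate = 0, fn_rate = 0)
  prior <- two$map$contig_id[two$map$clone_id == a]
  out2 <- deconvolve_pcr(res2, two$design, two$map, marker_id = "m2",
                         prior_contigs = prior)
  expect_identical(out2$status, "assigned")
  expect_identical(out2$clones, a)
  # without the prior the two single-candidate groups stay ambiguous
  out3 <- deconvolve_pcr(res2, two$design, two$map, marker_id = "m3")
  expect_identical(out3$status, "ambiguous")
})

test_that("pool scoring applies the C-value table per pool type", {
  w <- make_design(n = 384, rows = 16, cols = 24)
  pools <- c(w$design$pools$row, w$design$pools$col, w$design$pools$plate)
  types <- rep(c("row", "col", "plate"),
               c(16, 24, length(w$design$pools$plate)))
  base <- 10
  # per type: one hot pool plus a baseline set built so that, hot included,
  # the median is base + 0.5 and the MAD is 1.4826 exactly
  baseline <- function(k) c(rep(-1, (k - 2) / 2), 0, rep(1, (k - 2) / 2))
  m <- numeric(length(pools))
  hot_row <- base + 0.5 + 3.0 * 1.4826
  hot_col <- base + 0.5 + 2.5 * 1.4826
  m[types == "row"] <- base + c(hot_row - base, baseline(16))
  m[types == "col"] <- base + c(hot_col - base, baseline(24))
  m[types == "plate"] <- base
  set.seed(5)
  ints <- matrix(rnorm(length(m) * 10, rep(m, 10), 0.01), nrow = length(m))
  rownames(ints) <- pools
  sr <- structure(list(method = "array", intensities = ints,
                       pool_type = setNames(types, pools)),
                  class = "screen_result")
  sc <- score_pools(sr)
  row1 <- pools[which(types == "row")[1]]
  col1 <- pools[which(types == "col")[1]]
  expect_equal(sc$scores$z[sc$scores$pool == row1], 3.0, tolerance = 0.02)
  expect_equal(sc$scores$z[sc$scores$pool == col1], 2.5, tolerance = 0.02)
  expect_true(row1 %in% sc$positive$high)     # 3.0 >= 2.6
  expect_true(row1 %in% sc$positive$medium)   # >= 2.4
  expect_true(row1 %in% sc$positive$low)      # >= 2.2
  expect_false(col1 %in% sc$positive$high)    # 2.5 < 2.8
  expect_false(col1 %in% sc$positive$medium)  # 2.5 < 2.6
  expect_true(col1 %in% sc$positive$low)      # 2.5 >= 2.4
})

test_that("flat pools yield no positives; degenerate replicates are flagged", {
  w <- make_design()
  pools <- c(w$design$pools$row, w$design$pools$col, w$design$pools$plate)
  types <- rep(c("row", "col", "plate"),
               c(length(w$design$pools$row), length(w$design$pools$col),
                 length(w$design$pools$plate)))
  ints <- matrix(10, nrow = length(pools), ncol = 4)
  rownames(ints) <- pools
  sr <- structure(list(method = "array", intensities = ints,
                       pool_type = setNames(types, pools)),
                  class = "screen_result")
  sc <- score_pools(sr)
  expect_length(sc$positive$high, 0)
  expect_length(sc$positive$low, 0)
  expect_true(all(sc$scores$flag == "zero_variance_replicates"))
})

test_that("tiers nest and lowering C values never removes positives", {
  w <- make_design()
  carriers <- list(mk1 = w$ids[5], mk2 = w$ids[c(11, 12)], mk3 = character(0))
  screens <- simulate_array(carriers, w$design, signal_model(), seed = 9)
  for (mk in names(screens)) {
    sc <- score_pools(screens[[mk]])
    expect_true(all(sc$positive$high %in% sc$positive$medium))
    expect_true(all(sc$positive$medium %in% sc$positive$low))
    lax <- deconv_config(c_values = rbind(high = c(row = 2.0, col = 2.0, plate = 1.0),
                                          medium = c(row = 1.8, col = 1.8, plate = 1.0),
                                          low = c(row = 1.6, col = 1.6, plate = 0.8)))
    sc2 <- score_pools(screens[[mk]], lax)
    expect_true(all(sc$positive$high %in% sc2$positive$high))
  }
})

test_that("array deconvolution keeps overlapping pairs, discards cross-hyb", {
  w <- make_design()
  # marker on two overlapping clones of one contig
  pair <- w$ids[c(3, 4)]   # same contig, coords 40 and 60
  screens <- simulate_array(list(mk = pair), w$design, signal_model(), seed = 3)
  sc <- score_pools(screens$mk)
  out <- deconvolve_array(sc$positive, w$design, w$map, marker_id = "mk")
  expect_identical(out$status, "assigned")
  expect_setequal(strsplit(out$clones, ",")[[1]], pair)
  expect_identical(out$contig_id, "CTG1")

  # cross-hybridizing probe: candidates on two distant contigs; build the
  # pool calls directly so the address set is exactly the two clones
  ghost_map <- w$map
  ghost_map$contig_id[ghost_map$clone_id == w$ids[2]] <- "CTG6"
  ghost_map$coord_kb[ghost_map$clone_id == w$ids[2]] <- 5000
  pos <- pools_of_clones(w$design, w$ids[c(1, 2)])
  positive <- list(high = pos, medium = pos, low = pos)
  out2 <- deconvolve_array(positive, w$design, ghost_map, marker_id = "mk")
  expect_identical(out2$status, "discarded")
})

test_that("PCR and array agree on noise-free single-carrier markers (18/18)", {
  w <- make_design()
  set.seed(6)
  carriers <- setNames(as.list(sample(w$ids, 18)), sprintf("mk%02d", 1:18))
  pcr <- do.call(rbind, lapply(names(carriers), function(mk) {
    res <- simulate_pcr_screen(carriers[[mk]], w$design, fp_rate = 0, fn_rate = 0)
    deconvolve_pcr(res, w$design, w$map, marker_id = mk)
  }))
  arr_screens <- simulate_array(carriers, w$design,
                                signal_model(sd = 0.15), seed = 7)
  arr <- do.call(rbind, lapply(names(carriers), function(mk) {
    deconvolve_array(score_pools(arr_screens[[mk]])$positive, w$design, w$map,
                     marker_id = mk)
  }))
  agree <- sum(pcr$clones == arr$clones & pcr$status == "assigned" &
                 arr$status == "assigned")
  expect_equal(agree, 18)
})
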