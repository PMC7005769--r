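test_that("moving-average smoothing behaves at the identity, constants, and impulses", {
  x <- c(5, 1, 4, 1, 5)
  expect_identical(smooth_profile(x, window = 1), x)
  expect_equal(smooth_profile(rep(2, 10), window = 5), rep(2, 10))
  imp <- c(0, 0, 0, 1, 0, 0, 0)
  expect_equal(smooth_profile(imp, window = 3), c(0, 0, 1/3, 1/3, 1/3, 0, 0))
  # truncated edge windows
  expect_equal(smooth_profile(c(3, 0, 0), window = 3)[1], 1.5)
  expect_error(smooth_profile(x, window = 4), "odd")
})

test_that("region calling finds, merges, and filters threshold crossings", {
  prof <- tibble::tibble(
    residue_id = 1:7,
    longevity = c(1, 1, 0.05, 0.05, 0.05, 1, 1)
  )
  r <- call_regions(prof, direction = "below", threshold = 0.2, window = 1)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(3L, 5L))
  expect_equal(r$score, 0.05)

  # two qualifying runs separated by one residue merge across the gap
  prof2 <- tibble::tibble(
    residue_id = 1:11,
    longevity = c(1, 0.1, 0.1, 0.1, 1, 0.1, 0.1, 0.1, 1, 1, 1)
  )
  r2 <- call_regions(prof2, direction = "below", threshold = 0.2,
                     window = 1, merge_gap = 2)
  expect_equal(nrow(r2), 1L)
  expect_equal(c(r2$start, r2$end), c(2L, 8L))
  # with no gap bridging the runs stay separate
  r2b <- call_regions(prof2, direction = "below", threshold = 0.2,
                      window = 1, merge_gap = 0)
  expect_equal(nrow(r2b), 2L)

  # runs shorter than min_len are discarded after merging
  prof3 <- tibble::tibble(residue_id = 1:9,
                          longevity = c(1, 0.1, 0.1, 1, 1, 1, 1, 1, 1))
  expect_equal(nrow(call_regions(prof3, direction = "below", threshold = 0.2,
                                 window = 1, merge_gap = 0, min_len = 3)), 0L)

  # nothing qualifies
  prof4 <- tibble::tibble(residue_id = 1:6, longevity = rep(0.9, 6))
  expect_equal(nrow(call_regions(prof4, direction = "below", threshold = 0.2)), 0L)

  expect_error(call_regions(prof, direction = "below", threshold = 0.2,
                            window = 2), "odd")
  expect_error(call_regions(prof, direction = "below", threshold = Inf), "finite")
})

test_that("region calls ignore added non-qualifying flanks", {
  set.seed(9)
  core <- c(rep(1, 10), runif(8, 0, 0.05), rep(1, 10))
  call_core <- call_regions(
    tibble::tibble(residue_id = seq_along(core), longevity = core),
    direction = "below", threshold = 0.2
  )
  padded <- c(rep(1, 6), core, rep(1, 4))
  call_pad <- call_regions(
    tibble::tibble(residue_id = seq_along(padded), longevity = padded),
    direction = "below", threshold = 0.2
  )
  expect_equal(call_pad$start, call_core$start + 6L)
  expect_equal(call_pad$end, call_core$end + 6L)
})

test_that("disorder consensus requires k agreeing predictors", {
  block <- function(score_in, score_out) {
    c(rep(score_out, 10), rep(score_in, 8), rep(score_out, 10))
  }
  long <- dplyr::bind_rows(
    tibble::tibble(predictor = "d1", residue_id = 1:28, score = block(0.9, 0.1)),
    tibble::tibble(predictor = "d2", residue_id = 1:28, score = block(0.8, 0.2)),
    tibble::tibble(predictor = "d3", residue_id = 1:28, score = block(0.7, 0.1))
  )
  r <- disorder_consensus(long, k = 2)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(11L, 18L))

  # only one predictor fires: no consensus at k = 2
  lone <- dplyr::bind_rows(
    tibble::tibble(predictor = "d1", residue_id = 1:28, score = block(0.9, 0.1)),
    tibble::tibble(predictor = "d2", residue_id = 1:28, score = 0.1),
    tibble::tibble(predictor = "d3", residue_id = 1:28, score = 0.1)
  )
  expect_equal(nrow(disorder_consensus(lone, k = 2)), 0L)

  expect_error(disorder_consensus(long, k = 5), "between 1 and")
  short <- dplyr::bind_rows(
    tibble::tibble(predictor = "d1", residue_id = 1:5, score = 0.1),
    tibble::tibble(predictor = "d2", residue_id = 1:4, score = 0.1)
  )
  expect_error(disorder_consensus(short, k = 1), "length")
})

test_that("k = 1 consensus equals the residue-wise union of single-predictor calls", {
  for (s in 1:20) {
    set.seed(s)
    n <- 60
    long <- purrr::map_dfr(1:3, function(j) {
      tibble::tibble(predictor = paste0("d", j), residue_id = 1:n,
                     score = runif(n))
    })
    cons <- disorder_consensus(long, threshold = 0.5, k = 1,
                               min_len = 1, merge_gap = 0)
    brute_union <- sort(unique(long$residue_id[long$score >= 0.5]))
    expect_equal(sort(region_residues(cons)), brute_union)
  }
})

test_that("consensus regions shrink residue-wise as k grows", {
  set.seed(77)
  n <- 80
  long <- purrr::map_dfr(1:3, function(j) {
    tibble::tibble(predictor = paste0("d", j), residue_id = 1:n,
                   score = runif(n))
  })
  prev <- NULL
  for (k in 1:3) {
    cur <- region_residues(disorder_consensus(long, k = k, min_len = 1,
                                              merge_gap = 0))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("discordant regions are the flexible regions no disorder call covers", {
  low <- tibble::tibble(protein_id = "p", start = 100L, end = 150L,
                        kind = "low_longevity", score = 0.1)
  expect_equal(nrow(discordant_regions(low, empty_disorder <- low[0, ])), 1L)
  expect_equal(discordant_regions(low, low[0, ])$kind, "discordant")

  low2 <- tibble::tibble(protein_id = "p", start = 45L, end = 70L,
                         kind = "low_longevity", score = 0.1)
  dis <- tibble::tibble(protein_id = "p", start = 45L, end = 55L,
                        kind = "disorder_consensus", score = 2)
  expect_equal(nrow(discordant_regions(low2, dis, min_overlap = 5)), 0L)
  # identical sets: nothing discordant
  expect_equal(nrow(discordant_regions(low2, low2)), 0L)
  # overlap below min_overlap does not count as covered
  dis2 <- tibble::tibble(protein_id = "p", start = 68L, end = 80L,
                         kind = "disorder_consensus", score = 2)
  expect_equal(nrow(discordant_regions(low2, dis2, min_overlap = 5)), 1L)
  expect_equal(nrow(discordant_regions(low2, dis2, min_overlap = 1)), 0L)
})

test_that("rank correlation matches hand-computed values and flags degeneracy", {
  expect_equal(spearman_rho(1:6, (1:6)^3), 1)
  expect_equal(spearman_rho(1:6, rev(1:6)), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(spearman_rho(1:5, rep(2, 5)), "zero variance")
  expect_error(spearman_rho(1:4, 1:5), "equal length")
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
})

test_that("region Jaccard counts shared residues over the union", {
  a <- tibble::tibble(start = 1L, end = 10L)
  b <- tibble::tibble(start = 6L, end = 15L)
  expect_equal(region_jaccard(a, b), 5 / 15)
  expect_equal(region_jaccard(a, a), 1)
  expect_equal(region_jaccard(a, b[0, ]), 0)
  expect_equal(region_jaccard(a[0, ], b[0, ]), 1)
})

test_that("low-longevity calls recover the planted flexible blocks", {
  fx <- recovery_fixture()
  lon <- longevity_profile(fx$traj)
  calls <- call_regions(lon, direction = "below", threshold = 0.2,
                        kind = "low_longevity")
  expect_gte(region_jaccard(calls, fx$planted), 0.8)

  # the disorder-blind middle block is recovered as discordant
  cons <- disorder_consensus(fx$disorder)
  disc <- discordant_regions(calls, cons)
  expect_gte(region_jaccard(disc, fx$blind), 0.8)
  # and the two seen blocks are consensus-called
  expect_gte(region_jaccard(cons, fx$planted[c(1, 3), ]), 0.8)
})

test_that("profile correlations restate the concordance claims on joint synthetic data", {
  sim <- sim_reference(length = 200, seed = 61)
  traj <- sim_trajectory(sim$reference, sim$phi, n_frames = 600, seed = 62)
  lon <- longevity_profile(traj)
  pred <- sim_predictions(sim$reference, sim$phi, seed = 63)
  sc <- signed_confidence(pred, sim$reference$label)
  blind <- tibble::tibble(start = 1L, end = 0L)[0, ]
  dis <- sim_disorder(sim$phi, seed = 64)
  mean_dis <- dis |>
    dplyr::summarise(m = mean(score), .by = residue_id) |>
    dplyr::arrange(residue_id)
  expect_gte(spearman_rho(lon$longevity, sc$signed_conf), 0.6)
  expect_lte(spearman_rho(lon$longevity, mean_dis$m), -0.6)
})

test_that("the analysis object bundles regions, correlations, and tidiers", {
  fx <- recovery_fixture()
  lon <- longevity_profile(fx$traj)
  pred <- sim_predictions(fx$sim$reference, fx$sim$phi, seed = 101)
  sc <- signed_confidence(pred, fx$sim$reference$label)
  co <- sim_coordinates(fx$sim$phi, n_frames = 100, seed = 102)
  an <- concordance_analysis(
    lon, signed = sc, disorder = fx$disorder,
    rmsf = rmsf_profile(co), protein_id = "synthetic"
  )
  expect_s3_class(an, "concordance_analysis")
  td <- tidy(an)
  expect_setequal(
    unique(td$kind),
    c("low_longevity", "low_confidence", "disorder_consensus", "discordant")
  )
  gl <- glance(an)
  expect_equal(gl$n_residues, 200L)
  expect_lt(gl$rho_rmsf, 0)
  expect_gt(gl$rho_signed_conf, 0)
  expect_gt(gl$n_discordant, 0L)
  expect_output(print(an), "concordance_analysis")
  p <- ggplot2::autoplot(an)
  expect_s3_class(p, "ggplot")
})
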