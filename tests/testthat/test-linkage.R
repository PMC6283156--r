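test_that("the correlation LOD equals the regression likelihood-ratio LOD", {
  # oracle: per-marker least squares, LOD = (n/2) log10(SST/SSE)
  g <- small_panel(n_strains = 80, n_markers = 6, seed = 61)
  set.seed(62)
  y <- 0.5 * g$calls[, 7] + stats::rnorm(80)
  sc <- lod_scan(y, g)
  ys <- as.numeric(scale(y))
  for (j in seq_len(ncol(g$calls))) {
    fit <- stats::lm(ys ~ g$calls[, j])
    sst <- sum((ys - mean(ys))^2)
    sse <- sum(stats::residuals(fit)^2)
    expect_equal(sc$lod[j], (80 / 2) * log10(sst / sse), tolerance = 1e-9)
  }
})

test_that("LOD edge cases: zero correlation, monomorphic, perfect fit", {
  g <- structure(list(
    calls = cbind(m1 = c(-1, -1, 1, 1), m2 = c(-1, -1, -1, -1),
                  m3 = c(-1, 1, -1, 1)),
    map = data.frame(marker = c("m1", "m2", "m3"), chrom = "I",
                     pos_bp = 1:3, pos_cM = c(0, 1, 2))),
    class = "geno_matrix")
  y <- c(1, -1, 1, -1)                     # orthogonal to m1, perfect on m3
  sc <- lod_scan(y, g)
  expect_equal(sc$lod[1], 0)
  expect_equal(sc$lod[2], 0)               # monomorphic: defined 0
  expect_equal(sc$lod[3], -4 * log(1e-12) / (2 * log(10)), tolerance = 1e-6)
  expect_equal(attr(sc, "capped"), 3L)     # capped and flagged
  expect_error(lod_scan(rep(1, 4), g), "zero variance")
})

test_that("mapping is invariant to phenotype scaling", {
  g <- small_panel(n_strains = 60, n_markers = 5, seed = 63)
  set.seed(64)
  y <- g$calls[, 12] + stats::rnorm(60)
  a <- lod_scan(y, g)
  b <- lod_scan(100 + 17 * y, g)
  expect_equal(a$lod, b$lod, tolerance = 1e-10)
})

test_that("permutation thresholds are deterministic and monotone in alpha", {
  g <- small_panel(n_strains = 60, n_markers = 5, seed = 65)
  set.seed(66)
  y <- stats::rnorm(60)
  t1 <- permutation_threshold(y, g, n_perm = 200, seed = 9)
  t2 <- permutation_threshold(y, g, n_perm = 200, seed = 9)
  expect_identical(t1, t2)
  ta <- vapply(c(0.5, 0.2, 0.05, 0.01), function(a)
    permutation_threshold(y, g, n_perm = 200, alpha = a, seed = 9),
    numeric(1))
  expect_true(all(diff(ta) >= 0))
  expect_error(permutation_threshold(y, g, n_perm = 50, seed = 1),
               "at least 100")
})

test_that("joint permutation preserves correlation among traits", {
  g <- small_panel(n_strains = 50, n_markers = 4, seed = 67)
  set.seed(68)
  y1 <- stats::rnorm(50)
  Y <- cbind(t1 = y1, t2 = y1)             # identical traits
  thr <- permutation_threshold(Y, g, n_perm = 150, seed = 5)
  expect_equal(unname(thr["t1"]), unname(thr["t2"]))
})

test_that("the 1.5-LOD-drop interval follows the contiguous rule", {
  sc <- data.frame(marker = paste0("m", 1:5), chrom = "I", pos_cM = 0:4,
                   lod = c(1, 3, 5, 3, 1))
  ci <- lod_drop_interval(sc, peak = 3, drop = 1.5)
  expect_equal(c(ci$left, ci$right), c(3, 3))   # 3 < 5 - 1.5: peak only
  # flat curve spans the chromosome
  flat <- data.frame(marker = paste0("m", 1:5), chrom = "I", pos_cM = 0:4,
                     lod = rep(4, 5))
  ci2 <- lod_drop_interval(flat, peak = 3, drop = 1.5)
  expect_equal(c(ci2$left, ci2$right), c(1, 5))
  # drop = 0 keeps contiguous ties only
  tie <- data.frame(marker = paste0("m", 1:5), chrom = "I", pos_cM = 0:4,
                    lod = c(1, 5, 5, 1, 5))
  ci3 <- lod_drop_interval(tie, peak = 2, drop = 0)
  expect_equal(c(ci3$left, ci3$right), c(2, 3))
  expect_error(lod_drop_interval(sc, peak = 2, drop = 1.5), "not the chromosome maximum")
})

test_that("forward search finds a planted QTL and controls the null", {
  map <- riail_map(n_markers = 8)
  hits <- vapply(1:15, function(s) {
    g <- simulate_riail_panel(296, map, seed = 700 + s)
    ph <- simulate_phenotypes(g, architecture(
      additive = data.frame(marker = 20, var_frac = 0.10)), seed = 800 + s)
    fit <- forward_search(ph$latent, g, n_perm = 200, seed = 900 + s)
    nrow(fit$qtl) >= 1 && fit$qtl$peak_marker[1] == "III_004"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # null phenotypes yield empty QTL lists at about the 5% GWER
  nulls <- vapply(1:15, function(s) {
    g <- simulate_riail_panel(150, map, seed = 1700 + s)
    set.seed(1800 + s)
    fit <- forward_search(stats::rnorm(150), g, n_perm = 200, seed = 1900 + s)
    nrow(fit$qtl) == 0
  }, logical(1))
  expect_gte(mean(nulls), 0.75)
})

test_that("two unlinked planted QTL are reported stronger-first", {
  ok <- vapply(1:10, function(s) {
    g <- simulate_riail_panel(296, riail_map(n_markers = 8), seed = 2000 + s)
    ph <- simulate_phenotypes(g, architecture(
      additive = data.frame(marker = c(12, 36), var_frac = c(0.15, 0.10))),
      seed = 2100 + s)
    fit <- forward_search(ph$latent, g, n_perm = 200, seed = 2200 + s)
    nrow(fit$qtl) >= 2 &&
      all(c("II_004", "V_004") %in% fit$qtl$peak_marker[1:2]) &&
      fit$qtl$lod[1] >= fit$qtl$lod[2]
  }, logical(1))
  expect_gte(mean(ok), 0.6)
})

test_that("variance-explained annotation matches the planted fraction", {
  ve <- vapply(1:30, function(s) {
    g <- simulate_riail_panel(296, riail_map(n_markers = 4), seed = 2300 + s)
    ph <- simulate_phenotypes(g, architecture(
      additive = data.frame(marker = 10, var_frac = 0.20)), seed = 2400 + s)
    qtl <- data.frame(peak_marker = "III_002")
    annotate_variance_explained(qtl, ph$latent, g)$var_exp
  }, numeric(1))
  expect_lt(abs(mean(ve) - 0.20), 0.05)
  # an uncorrelated marker explains nothing
  g <- simulate_riail_panel(200, riail_map(n_markers = 4), seed = 2500)
  set.seed(2501)
  qtl <- annotate_variance_explained(data.frame(peak_marker = "I_001"),
                                     stats::rnorm(200), g)
  expect_lt(qtl$var_exp, 0.05)
})

test_that("the pair scan respects model nesting and finds planted epistasis", {
  g <- simulate_riail_panel(296, riail_map(n_markers = 4), seed = 2600)
  ph <- simulate_phenotypes(g, architecture(
    epistatic = data.frame(marker1 = 6, marker2 = 18, var_frac = 0.15)),
    seed = 2601)
  ps <- pair_scan(ph$latent, g, grid_cM = 0, n_perm = 250, seed = 2602)
  expect_true(all(ps$pairs$lod_full >= ps$pairs$lod_add - 1e-9))
  expect_true(all(ps$pairs$lod_int >= 0))
  pk <- ps$pairs[ps$peak, ]
  expect_setequal(c(pk$marker1, pk$marker2), c("II_002", "V_002"))
  expect_gt(pk$lod_int, ps$threshold)
  # a purely additive trait shows no significant interaction
  ph2 <- simulate_phenotypes(g, architecture(
    additive = data.frame(marker = 6, var_frac = 0.3)), seed = 2603)
  ps2 <- pair_scan(ph2$latent, g, grid_cM = 0, n_perm = 250, seed = 2604)
  expect_lt(max(ps2$pairs$lod_int), ps2$threshold)
})

test_that("qtl_scan objects print, summarize and plot", {
  g <- small_panel(n_strains = 100, n_markers = 6, seed = 2700)
  ph <- simulate_phenotypes(g, architecture(
    additive = data.frame(marker = 15, var_frac = 0.3)), seed = 2701)
  fit <- forward_search(ph$latent, g, n_perm = 150, seed = 2702)
  expect_output(print(fit), "Forward-search QTL scan")
  expect_output(print(summary(fit)), "variance explained")
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf)
  expect_silent(plot(fit))
  grDevices::dev.off()
  unlink(tf)
})
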