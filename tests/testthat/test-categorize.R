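test_that("Tukey HSD is calibrated on the null and decisive on large effects", {
  rejects <- vapply(1:400, function(s) {
    set.seed(5000 + s)
    v <- stats::rnorm(20)
    tk <- tukey_hsd(v, rep(c("a", "b"), each = 10))
    tk$p["a", "b"] < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejects) - 0.05), 0.03)
  # two groups five SDs apart
  set.seed(5500)
  v <- c(stats::rnorm(20, 0), stats::rnorm(20, 5))
  tk <- tukey_hsd(v, rep(c("a", "b"), each = 20))
  expect_lt(tk$p["a", "b"], 0.001)
})

test_that("degenerate Tukey inputs resolve to explicit p-values", {
  # all groups identical constants: no difference anywhere
  tk <- tukey_hsd(rep(2, 12), rep(c("a", "b", "c"), each = 4))
  off <- tk$p[upper.tri(tk$p)]
  expect_true(all(off == 1))
  # zero within-group variance but different means: certain difference
  tk2 <- tukey_hsd(rep(c(0, 5), each = 4), rep(c("a", "b"), each = 4))
  expect_equal(tk2$p["a", "b"], 0)
  # single-replicate strains are excluded with a warning
  expect_warning(tk3 <- tukey_hsd(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
                 "excluding")
  expect_equal(rownames(tk3$p), c("a", "b"))
})

test_that("replicate counts solve the noncentral-t power equation", {
  n1 <- replicates_for_power(1.0)
  expect_equal(n1, 17L)   # analytic solution for d = 1, power 0.8, alpha 0.05
  # Monte-Carlo oracle: simulated power at the returned n is about 0.80
  set.seed(5600)
  hits <- vapply(1:10000, function(i) {
    a <- stats::rnorm(n1); b <- stats::rnorm(n1, 1)
    stats::t.test(a, b)$p.value < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.80), 0.03)
  # huge effects floor at 2; tiny effects hit the cap with a flag
  expect_equal(as.integer(replicates_for_power(10)), 2L)
  capped <- replicates_for_power(0.1)
  expect_equal(as.integer(capped), 100L)
  expect_true(attr(capped, "capped"))
  expect_error(replicates_for_power(0), "positive")
})

test_that("the NIL tree reproduces constructed recapitulation and transgression", {
  # recapitulation: each line shifts to its introgression parent
  vals <- assay_values(c(N2 = 10, CB = 0, nil_bgA = 0.2, nil_bgB = 9.8))
  cmp <- compare_strains(vals$value, vals$strain, nil_roles,
                         trait = "cisplatin.norm.n")
  expect_equal(categorize_nil(cmp)$category, "recapitulation")
  # no parental difference short-circuits everything
  vals2 <- assay_values(c(N2 = 0, CB = 0.05, nil_bgA = 30, nil_bgB = -30))
  cmp2 <- compare_strains(vals2$value, vals2$strain, nil_roles)
  expect_equal(categorize_nil(cmp2)$category, "no parental difference")
  # unidirectional: one line transgressive (20, outside [0, 10]), the
  # other shows no QTL effect
  vals3 <- assay_values(c(N2 = 10, CB = 0, nil_bgA = 9.9, nil_bgB = 20))
  cmp3 <- compare_strains(vals3$value, vals3$strain, nil_roles)
  r3 <- categorize_nil(cmp3)
  expect_equal(r3$category, "unidirectional transgressive")
  expect_equal(unname(r3$direction$bgB["side"]), "above")
  # bidirectional: both lines beyond the parental range
  vals4 <- assay_values(c(N2 = 10, CB = 0, nil_bgA = -10, nil_bgB = 20))
  cmp4 <- compare_strains(vals4$value, vals4$strain, nil_roles)
  expect_equal(categorize_nil(cmp4)$category, "bidirectional transgressive")
  # no QTL effect: lines match their background parents
  vals5 <- assay_values(c(N2 = 10, CB = 0, nil_bgA = 10.1, nil_bgB = -0.1))
  cmp5 <- compare_strains(vals5$value, vals5$strain, nil_roles)
  expect_equal(categorize_nil(cmp5)$category, "no QTL effect")
})

test_that("the six-category tree is total and mutually exclusive", {
  # enumerate the configuration space: every combination of the six
  # pairwise significance indicators times median orderings of the four
  # strains (all permutations of distinct values plus tie patterns)
  categories <- c("no parental difference", "recapitulation", "no QTL effect",
                  "bidirectional transgressive", "unidirectional transgressive",
                  "miscellaneous")
  sig_levels <- c(0.01, 0.5)
  perms <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  ties <- rbind(c(1, 1, 2, 3), c(1, 2, 1, 3), c(1, 2, 3, 1), c(2, 1, 1, 3),
                c(1, 2, 2, 2), c(1, 1, 1, 1), c(1, 1, 2, 2), c(1, 2, 2, 1))
  med_grid <- rbind(perms, ties)
  n_checked <- 0L
  for (i in seq_len(nrow(med_grid))) {
    meds <- stats::setNames(as.numeric(med_grid[i, ]),
                            c("parentA", "parentB", "intro_bgA", "intro_bgB"))
    for (s in 0:63) {
      bits <- as.integer(intToBits(s))[1:6]
      P <- role_pmatrix(sig_levels[bits[1] + 1], sig_levels[bits[2] + 1],
                        sig_levels[bits[3] + 1], sig_levels[bits[4] + 1],
                        sig_levels[bits[5] + 1], sig_levels[bits[6] + 1])
      cmp <- synthetic_comparison(P, meds)
      res <- categorize_nil(cmp)
      expect_true(res$category %in% categories)
      n_checked <- n_checked + 1L
    }
  }
  expect_equal(n_checked, (24 + 8) * 64)
})

test_that("categories are invariant under relabeling parents A and B", {
  set.seed(5700)
  for (rep in 1:200) {
    meds <- stats::setNames(stats::rnorm(4),
                            c("parentA", "parentB", "intro_bgA", "intro_bgB"))
    pv <- stats::runif(6)
    P <- role_pmatrix(pv[1], pv[2], pv[3], pv[4], pv[5], pv[6])
    cmp <- synthetic_comparison(P, meds)
    # swap A<->B with introgression labels swapped accordingly
    swap <- c(parentA = "parentB", parentB = "parentA",
              intro_bgA = "intro_bgB", intro_bgB = "intro_bgA")
    P2 <- P[swap, swap]
    dimnames(P2) <- dimnames(P)
    meds2 <- stats::setNames(meds[swap], names(meds))
    cmp2 <- synthetic_comparison(P2, meds2)
    expect_equal(categorize_nil(cmp)$category, categorize_nil(cmp2)$category)
  }
})

test_that("recapitulation dominates on simulated single-QTL NIL assays", {
  # a planted additive QTL inside the introgression, replicates at the
  # power calculation's recommendation
  # power each Tukey-corrected pairwise comparison, not just a lone t-test:
  # the category needs three simultaneous significant comparisons
  d <- 1.0                                   # standardized parental effect
  n_rep <- replicates_for_power(d, power = 0.975, alpha = 0.05 / 6)
  hits <- vapply(1:100, function(s) {
    set.seed(5800 + s)
    means <- c(N2 = 0, CB = d, nil_bgA = d, nil_bgB = 0)  # recapitulating
    vals <- data.frame(strain = rep(names(means), each = n_rep),
                       value = stats::rnorm(4 * n_rep, rep(means, each = n_rep)))
    cmp <- compare_strains(vals$value, vals$strain, nil_roles)
    categorize_nil(cmp)$category == "recapitulation"
  }, logical(1))
  expect_gte(mean(hits), 0.75)
  # with an antagonistic background locus the assay turns transgressive
  trans <- vapply(1:60, function(s) {
    set.seed(5900 + s)
    means <- c(N2 = 0, CB = 2, nil_bgA = 4, nil_bgB = 2)
    means["nil_bgA"] <- 4                  # beyond both parents
    vals <- data.frame(strain = rep(names(means), each = 30),
                       value = stats::rnorm(4 * 30, rep(means, each = 30), 0.8))
    cmp <- compare_strains(vals$value, vals$strain, nil_roles)
    grepl("transgressive", categorize_nil(cmp)$category)
  }, logical(1))
  expect_gt(mean(trans), 0.5)
})

test_that("combined NIL+CSS classification reproduces the worked outcomes", {
  css_roles <- nil_roles
  # recapitulation in both assays -> recapitulation
  nil_v <- assay_values(c(N2 = 10, CB = 0, nil_bgA = 0.2, nil_bgB = 9.8),
                        seed = 11)
  css_v <- assay_values(c(N2 = 10, CB = 0, nil_bgA = 0.3, nil_bgB = 9.7),
                        seed = 12)
  nil_r <- categorize_nil(compare_strains(nil_v$value, nil_v$strain, nil_roles,
                                          trait = "cisplatin.norm.n"))
  css_r <- categorize_nil(compare_strains(css_v$value, css_v$strain, css_roles,
                                          trait = "cisplatin.norm.n",
                                          assay = "CSS"))
  expect_equal(categorize_combined(nil_r, css_r)$category, "recapitulation")
  # CSS bidirectional + NIL no-QTL-effect -> interchromosomal external
  nil_v <- assay_values(c(N2 = 10, CB = 0, nil_bgA = 10.1, nil_bgB = -0.1),
                        seed = 13)
  css_v <- assay_values(c(N2 = 10, CB = 0, nil_bgA = 20, nil_bgB = -10),
                        seed = 14)
  nil_r <- categorize_nil(compare_strains(nil_v$value, nil_v$strain, nil_roles,
                                          trait = "silver.median.TOF"))
  css_r <- categorize_nil(compare_strains(css_v$value, css_v$strain, css_roles,
                                          trait = "silver.median.TOF",
                                          assay = "CSS"))
  comb <- categorize_combined(nil_r, css_r)
  expect_equal(comb$category, "interchromosomal external")
  expect_equal(comb$direction, "bidirectional")
  # same unidirectional interaction in both -> interchromosomal internal
  nil_v <- assay_values(c(N2 = 10, CB = 0, nil_bgA = 9.9, nil_bgB = 20),
                        seed = 15)
  css_v <- assay_values(c(N2 = 10, CB = 0, nil_bgA = 10.1, nil_bgB = 21),
                        seed = 16)
  nil_r <- categorize_nil(compare_strains(nil_v$value, nil_v$strain, nil_roles,
                                          trait = "carmustine.median.EXT"))
  css_r <- categorize_nil(compare_strains(css_v$value, css_v$strain, css_roles,
                                          trait = "carmustine.median.EXT",
                                          assay = "CSS"))
  comb2 <- categorize_combined(nil_r, css_r)
  expect_equal(comb2$category, "interchromosomal internal")
  expect_equal(comb2$direction, "unidirectional")
  # NIL interaction without CSS interaction -> intrachromosomal
  nil_v <- assay_values(c(N2 = 10, CB = 0, nil_bgA = 9.9, nil_bgB = 20),
                        seed = 17)
  css_v <- assay_values(c(N2 = 10, CB = 0, nil_bgA = 0.2, nil_bgB = 9.8),
                        seed = 18)
  nil_r <- categorize_nil(compare_strains(nil_v$value, nil_v$strain, nil_roles,
                                          trait = "cisplatin.q90.EXT"))
  css_r <- categorize_nil(compare_strains(css_v$value, css_v$strain, css_roles,
                                          trait = "cisplatin.q90.EXT",
                                          assay = "CSS"))
  expect_equal(categorize_combined(nil_r, css_r)$category, "intrachromosomal")
  # mismatched traits are rejected
  expect_error(categorize_combined(nil_r, comb2), "differ")
})

test_that("the combined tree is consistent over the category product table", {
  # enumerate NIL x CSS category combinations through synthetic results and
  # check the fixed evaluation order of the seven classes
  mk_res <- function(category, trait = "t", parent_dir = 1,
                     sig = character(0)) {
    direction <- NULL
    if (grepl("transgressive", category)) {
      direction <- list(bgA = NULL, bgB = c(side = "above", tag = "synergistic"))
      if (category == "bidirectional transgressive")
        direction$bgA <- c(side = "below", tag = "antagonistic")
    }
    structure(list(category = category, assay = "NIL", trait = trait,
                   direction = direction, parent_direction = parent_dir),
              class = "category_result")
  }
  cats <- c("no parental difference", "recapitulation", "no QTL effect",
            "bidirectional transgressive", "unidirectional transgressive",
            "miscellaneous")
  combined_cats <- c("no parental difference", "recapitulation",
                     "no QTL effect", "interchromosomal external",
                     "interchromosomal internal", "intrachromosomal",
                     "miscellaneous")
  for (nc in cats) for (cc in cats) {
    got <- categorize_combined(mk_res(nc), mk_res(cc))$category
    expect_true(got %in% combined_cats)
    if (nc == "no parental difference" || cc == "no parental difference")
      expect_equal(got, "no parental difference")
  }
  # matching interactions with the same signature -> internal
  expect_equal(categorize_combined(mk_res("unidirectional transgressive"),
                                   mk_res("unidirectional transgressive"))$category,
               "interchromosomal internal")
  # opposite parental directions force no-parental-difference
  expect_equal(categorize_combined(mk_res("recapitulation", parent_dir = 1),
                                   mk_res("recapitulation", parent_dir = -1))$category,
               "no parental difference")
})
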