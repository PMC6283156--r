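#' Pairwise strain comparisons by Tukey's honest significant difference
#'
#' One-way fixed-effects ANOVA `phenotype ~ strain` followed by Tukey's HSD,
#' returning the family-wise adjusted p-value for every strain pair. Strains
#' with fewer than 2 replicates are excluded with a warning. Degenerate
#' inputs are handled explicitly: when the within-group variance is zero,
#' pairs with equal group means get p = 1 and pairs with different means
#' get p = 0.
#'
#' @param values numeric replicate values.
#' @param strain factor (or coercible) of strain labels.
#' @return List of class `tukey_pairs`: `p` (symmetric strains x strains
#'   matrix, diagonal NA), `medians` (named), `n` (replicates per strain).
#' @export
tukey_hsd <- function(values, strain) {
  strain <- factor(strain)
  stopifnot(length(values) == length(strain))
  keep <- !is.na(values)
  values <- values[keep]; strain <- droplevels(strain[keep])
  counts <- table(strain)
  if (any(counts < 2)) {
    warning("excluding ", sum(counts < 2), " strain(s) with < 2 replicates")
    ok <- strain %in% names(counts)[counts >= 2]
    values <- values[ok]
    strain <- droplevels(strain[ok])
  }
  lv <- levels(strain)
  if (length(lv) < 2) stop("need at least 2 strains with >= 2 replicates")
  P <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  gm <- tapply(values, strain, mean)
  sse <- sum((values - gm[as.integer(strain)])^2)
  if (sse < .Machine$double.eps * sum(values^2) + 1e-300) {
    scale_ <- max(abs(gm), 1)
    for (i in seq_along(lv)) for (j in seq_along(lv)) if (i != j)
      P[i, j] <- if (abs(gm[i] - gm[j]) < 1e-12 * scale_) 1 else 0
  } else {
    fit <- stats::aov(values ~ strain)
    tk <- stats::TukeyHSD(fit)$strain
    prs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (k in seq_len(nrow(tk))) {
      a <- prs[[k]][1L]; b <- prs[[k]][2L]
      P[a, b] <- P[b, a] <- tk[k, "p adj"]
    }
  }
  meds <- tapply(values, strain, stats::median)
  structure(list(p = P, medians = stats::setNames(as.numeric(meds), lv),
                 n = stats::setNames(as.integer(table(strain)), lv)),
            class = "tukey_pairs")
}

#' Replicates per group for a target power
#'
#' Smallest number of technical replicates per group so a two-sided
#' two-sample t comparison at level `alpha` detects a standardized effect
#' `effect` with at least the requested power (noncentral-t power
#' function). Experimental throughput caps the answer at `cap`; a capped
#' value is flagged via the `capped` attribute. Group sizes below 2 are
#' meaningless, so the floor is 2.
#'
#' @param effect standardized mean difference (Cohen's d, > 0).
#' @param power target power. Default 0.80.
#' @param alpha two-sided significance level. Default 0.05.
#' @param cap maximum replicates per group. Default 100.
#' @return Integer replicates per group (attribute `capped` when the
#'   uncapped solution exceeded `cap`).
#' @export
replicates_for_power <- function(effect, power = 0.80, alpha = 0.05, cap = 100) {
  if (effect <= 0) stop("effect must be positive")
  # power at n = cap: if still insufficient, report the cap
  p_cap <- stats::power.t.test(n = cap, delta = effect, sd = 1,
                               sig.level = alpha)$power
  if (p_cap < power) {
    return(structure(as.integer(cap), capped = TRUE))
  }
  n <- tryCatch(stats::power.t.test(delta = effect, sd = 1, sig.level = alpha,
                                    power = power)$n,
                error = function(e) 2)
  max(2L, as.integer(ceiling(n)))
}

#' Pairwise comparison of the strains of a validation assay
#'
#' Runs [tukey_hsd()] over the four strains of a NIL (or CSS) assay --
#' both parents and the two reciprocal introgression lines -- and packages
#' the p-values and medians under their assay roles for categorization.
#'
#' @param values numeric replicate values.
#' @param strain strain labels.
#' @param roles named character vector mapping the roles `parentA`,
#'   `parentB`, `intro_bgA` (opposite-allele introgression in the parent-A
#'   background), `intro_bgB` to strain labels.
#' @param trait trait label.
#' @param assay assay kind, "NIL" or "CSS".
#' @return Object of class `strain_comparison`: `p` and `medians` indexed
#'   by role, plus `trait` and `assay`.
#' @export
compare_strains <- function(values, strain, roles, trait = "trait",
                            assay = c("NIL", "CSS")) {
  assay <- match.arg(assay)
  need <- c("parentA", "parentB", "intro_bgA", "intro_bgB")
  if (!all(need %in% names(roles)))
    stop("roles must name: ", paste(need, collapse = ", "))
  tk <- tukey_hsd(values, strain)
  missing_strains <- setdiff(roles[need], rownames(tk$p))
  if (length(missing_strains))
    stop("strain(s) missing from the assay: ",
         paste(missing_strains, collapse = ", "))
  P <- tk$p[roles[need], roles[need]]
  dimnames(P) <- list(need, need)
  meds <- stats::setNames(tk$medians[roles[need]], need)
  structure(list(p = P, medians = meds, trait = trait, assay = assay),
            class = "strain_comparison")
}

# Internal: evaluate the per-line patterns the category trees consume.
# For each introgression line: which parent is its background, which is its
# introgression source, and whether it recapitulates, shows no effect, or is
# transgressive (and on which side of the parental median range).
line_patterns <- function(cmp, p_cut = 0.05) {
  sig <- function(a, b) !is.na(cmp$p[a, b]) && cmp$p[a, b] < p_cut
  med <- cmp$medians
  rng <- range(med[c("parentA", "parentB")])
  pat <- function(line, bg, intro) {
    sig_bg <- sig(line, bg)
    sig_intro <- sig(line, intro)
    toward <- sign(med[line] - med[bg]) == sign(med[intro] - med[bg]) &&
      med[intro] != med[bg]
    outside <- med[line] < rng[1L] || med[line] > rng[2L]
    side <- if (!outside) NA_character_ else
      if (med[line] > rng[2L]) "above" else "below"
    # synergy: the transgressive line overshoots past its introgression
    # parent; antagonism: it flips past its background parent.
    tag <- if (!outside) NA_character_ else
      if (toward) "synergistic" else "antagonistic"
    trans <- sig_bg && sig_intro && outside
    # a transgressive line does not "recapitulate": it overshoots past the
    # parental range instead of matching its introgression parent
    list(recap = sig_bg && toward && !trans, no_effect = !sig_bg,
         transgressive = trans,
         side = side, tag = tag)
  }
  list(parents_sig = sig("parentA", "parentB"),
       parent_direction = sign(med["parentB"] - med["parentA"]),
       bgA = pat("intro_bgA", "parentA", "parentB"),
       bgB = pat("intro_bgB", "parentB", "parentA"))
}

#' Categorize a NIL assay into the six-phenotype classes
#'
#' Decision tree over the pairwise significance pattern and median ordering
#' of the four assay strains, evaluated in fixed order:
#' \enumerate{
#'   \item parents not significantly different: "no parental difference";
#'   \item both lines differ from their background parent and shift toward
#'     their introgression parent: "recapitulation";
#'   \item neither line differs from its background parent: "no QTL effect";
#'   \item both lines differ from both parents with medians outside the
#'     parental-median range: "bidirectional transgressive";
#'   \item exactly one line transgressive while the other recapitulates or
#'     shows no effect: "unidirectional transgressive";
#'   \item otherwise "miscellaneous".
#' }
#' A transgressive line also carries a direction tag: "synergistic" when it
#' overshoots past its introgression parent, "antagonistic" when it flips
#' past its background parent (the tag does not affect the category).
#'
#' @param cmp a [compare_strains()] result.
#' @param p_cut significance threshold. Default 0.05.
#' @return Object of class `category_result`: `category`, `assay`, `trait`,
#'   `direction` (for transgressive categories: the tags and sides per
#'   line), `patterns` (the evaluated per-line patterns), `parent_direction`.
#' @export
categorize_nil <- function(cmp, p_cut = 0.05) {
  stopifnot(inherits(cmp, "strain_comparison"))
  lp <- line_patterns(cmp, p_cut)
  a <- lp$bgA; b <- lp$bgB
  category <- if (!lp$parents_sig) {
    "no parental difference"
  } else if (a$recap && b$recap) {
    "recapitulation"
  } else if (a$no_effect && b$no_effect) {
    "no QTL effect"
  } else if (a$transgressive && b$transgressive) {
    "bidirectional transgressive"
  } else if (xor(a$transgressive, b$transgressive) &&
             (if (a$transgressive) b$recap || b$no_effect
              else a$recap || a$no_effect)) {
    "unidirectional transgressive"
  } else {
    "miscellaneous"
  }
  direction <- NULL
  if (category %in% c("unidirectional transgressive",
                      "bidirectional transgressive")) {
    direction <- list(
      bgA = if (a$transgressive) c(side = a$side, tag = a$tag) else NULL,
      bgB = if (b$transgressive) c(side = b$side, tag = b$tag) else NULL)
  }
  structure(list(category = category, assay = cmp$assay, trait = cmp$trait,
                 direction = direction, patterns = lp,
                 parent_direction = unname(lp$parent_direction)),
            class = "category_result")
}

#' @export
print.category_result <- function(x, ...) {
  cat(x$assay, " assay, trait '", x$trait, "': ", x$category, "\n", sep = "")
  if (!is.null(x$direction)) {
    for (nm in names(x$direction)) if (!is.null(x$direction[[nm]]))
      cat("  ", nm, ": ", paste(x$direction[[nm]], collapse = ", "), "\n",
          sep = "")
  }
  invisible(x)
}

# Is a category result an interaction (transgressive) class, and if so which
# directionality?
interaction_kind <- function(res) {
  switch(res$category,
         "unidirectional transgressive" = "unidirectional",
         "bidirectional transgressive" = "bidirectional",
         NA_character_)
}

# Transgressive signature: which line(s) and side(s), for matching the
# "same interaction" requirement across assays.
transgressive_signature <- function(res) {
  d <- res$direction
  if (is.null(d)) return(character(0))
  sig <- character(0)
  for (nm in c("bgA", "bgB")) if (!is.null(d[[nm]]))
    sig <- c(sig, paste(nm, d[[nm]][["side"]], sep = ":"))
  sort(sig)
}

#' Combine NIL and CSS categorizations into the seven-class scheme
#'
#' Places a trait tested in both the interval-introgression (NIL) and
#' whole-chromosome (CSS) assays into one of seven classes, locating the
#' interacting partner locus relative to the introgressed interval:
#' \enumerate{
#'   \item parents non-significant in either assay, or with opposite
#'     direction across assays: "no parental difference";
#'   \item both assays recapitulate: "recapitulation";
#'   \item both show no QTL effect: "no QTL effect";
#'   \item CSS shows an interaction (uni/bidirectional transgression) while
#'     the NIL recapitulates or shows no effect: "interchromosomal
#'     external" (the partner locus is on the introgressed chromosome but
#'     outside the NIL interval -- both loci share a genotype in the NIL);
#'   \item both assays show the same interaction (same directionality and
#'     same transgressive line/side): "interchromosomal internal";
#'   \item the NIL shows an interaction but the CSS does not:
#'     "intrachromosomal";
#'   \item otherwise "miscellaneous".
#' }
#'
#' @param nil_result,css_result [categorize_nil()] results for the same
#'   trait from the NIL and CSS assays.
#' @return Object of class `category_result` with `assay = "combined"`; the
#'   `direction` field carries the CSS directionality for interaction
#'   classes.
#' @export
categorize_combined <- function(nil_result, css_result) {
  stopifnot(inherits(nil_result, "category_result"),
            inherits(css_result, "category_result"))
  if (!identical(nil_result$trait, css_result$trait))
    stop("trait ids differ between the NIL and CSS results")
  nil_int <- interaction_kind(nil_result)
  css_int <- interaction_kind(css_result)
  nil_plain <- nil_result$category %in% c("recapitulation", "no QTL effect")
  css_plain <- css_result$category %in% c("recapitulation", "no QTL effect")
  category <- if (nil_result$category == "no parental difference" ||
                  css_result$category == "no parental difference" ||
                  nil_result$parent_direction != css_result$parent_direction) {
    "no parental difference"
  } else if (nil_result$category == "recapitulation" &&
             css_result$category == "recapitulation") {
    "recapitulation"
  } else if (nil_result$category == "no QTL effect" &&
             css_result$category == "no QTL effect") {
    "no QTL effect"
  } else if (!is.na(css_int) && nil_plain) {
    "interchromosomal external"
  } else if (!is.na(css_int) && !is.na(nil_int) && css_int == nil_int &&
             identical(transgressive_signature(nil_result),
                       transgressive_signature(css_result))) {
    "interchromosomal internal"
  } else if (!is.na(nil_int) && is.na(css_int)) {
    "intrachromosomal"
  } else {
    "miscellaneous"
  }
  direction <- if (category %in% c("interchromosomal external",
                                   "interchromosomal internal"))
    css_int else if (category == "intrachromosomal") nil_int else NULL
  structure(list(category = category, assay = "combined",
                 trait = nil_result$trait, direction = direction,
                 nil = nil_result$category, css = css_result$category,
                 parent_direction = nil_result$parent_direction),
            class = "category_result")
}
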