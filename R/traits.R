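#' Principal-component trait reduction with a cumulative-variance rule
#'
#' Trait values are standardized (mean 0, SD 1) per trait, then
#' eigendecomposed; the number of retained components is the smallest k
#' whose cumulative variance fraction reaches `variance_threshold`.
#' Constant traits are dropped with a warning before scaling, and strains
#' with any missing trait value are excluded (components need complete
#' vectors). Each component's sign is fixed so its largest-magnitude
#' loading is positive, making the decomposition deterministic.
#'
#' @param pheno strains x traits numeric matrix.
#' @param variance_threshold cumulative variance fraction to reach.
#'   Default 0.90.
#' @param condition optional condition label carried in the result.
#' @return Object of class `pc_set`: `loadings` (traits x PCs, orthonormal),
#'   `scores` (strains x PCs), `variance_fractions`, `n_selected`,
#'   `condition`.
#' @export
pca_select <- function(pheno, variance_threshold = 0.90, condition = NULL) {
  stopifnot(is.matrix(pheno), nrow(pheno) >= 2, ncol(pheno) >= 2)
  complete <- stats::complete.cases(pheno)
  pheno <- pheno[complete, , drop = FALSE]
  if (nrow(pheno) < 2) stop("fewer than 2 strains with complete trait vectors")
  sds <- apply(pheno, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant trait(s) before scaling")
    pheno <- pheno[, sds > 0, drop = FALSE]
  }
  z <- scale(pheno)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  # deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  n_sel <- which(cumsum(vf) >= variance_threshold)[1L]
  structure(list(loadings = pc$rotation, scores = pc$x,
                 variance_fractions = vf, n_selected = as.integer(n_sel),
                 variance_threshold = variance_threshold,
                 condition = condition),
            class = "pc_set")
}

#' @export
print.pc_set <- function(x, ...) {
  cat("PC set", if (!is.null(x$condition)) paste0("(", x$condition, ")"), ":",
      length(x$variance_fractions), "components;",
      x$n_selected, "retained at the",
      sprintf("%.0f%%", 100 * x$variance_threshold), "variance rule\n")
  invisible(x)
}

#' Hierarchical clustering of traits by absolute correlation
#'
#' Pairwise Pearson correlations over strains (pairwise-complete
#' observations), distance 1 - |r|, agglomerative clustering (complete
#' linkage by default), cut into k groups. k is typically the number of
#' principal components retained by [pca_select()] for the same condition,
#' so that each trait cluster corresponds roughly to one axis of variation.
#'
#' @param pheno strains x traits matrix.
#' @param k number of groups (1 <= k <= number of traits).
#' @param method linkage method for [stats::hclust()]. Default "complete".
#' @return Object of class `trait_clustering`: `correlation` matrix,
#'   `dendrogram` (hclust object), `groups` (named integer vector).
#' @export
cluster_traits <- function(pheno, k, method = "complete") {
  stopifnot(is.matrix(pheno))
  if (k < 1 || k > ncol(pheno)) stop("k must be between 1 and the number of traits")
  r <- stats::cor(pheno, use = "pairwise.complete.obs")
  d <- stats::as.dist(1 - abs(r))
  hc <- stats::hclust(d, method = method)
  groups <- stats::cutree(hc, k = k)
  structure(list(correlation = r, dendrogram = hc, groups = groups, k = k),
            class = "trait_clustering")
}

#' Representative traits for a principal component
#'
#' Returns the trait most correlated (in absolute value) with the given
#' component's scores, together with every trait in that trait's cluster --
#' the set of directly measurable traits carried forward into validation
#' assays for the component. Ties in |correlation| break by trait-name
#' order. The reported correlation range is over the returned traits'
#' absolute correlations with the component.
#'
#' @param pc_scores numeric vector of one component's scores (named by
#'   strain or aligned with `pheno` rows).
#' @param pheno strains x traits matrix over the same strains.
#' @param clustering a [cluster_traits()] result for the same traits.
#' @return List: `top` (the most correlated trait), `traits` (the full
#'   cluster, ordered by decreasing |correlation|), `correlations` (named,
#'   signed), `correlation_range` (range of |correlation| over `traits`).
#' @export
representative_traits <- function(pc_scores, pheno, clustering) {
  stopifnot(inherits(clustering, "trait_clustering"),
            length(pc_scores) == nrow(pheno))
  cors <- apply(pheno, 2, function(v) {
    ok <- !is.na(v) & !is.na(pc_scores)
    if (sum(ok) < 3 || stats::sd(v[ok]) == 0) return(NA_real_)
    stats::cor(pc_scores[ok], v[ok])
  })
  ord <- order(-abs(cors), colnames(pheno))
  top <- colnames(pheno)[ord[1L]]
  members <- names(clustering$groups)[clustering$groups == clustering$groups[top]]
  members <- members[order(-abs(cors[members]))]
  list(top = top, traits = members, correlations = cors[members],
       correlation_range = range(abs(cors[members]), na.rm = TRUE))
}

#' Count validation tests from a trait-panel design table
#'
#' Given the panel of traits selected to represent each mapped component
#' (one row per component: its toxin, the hotspot regions its QTL fall in,
#' and the correlated trait list), counts the unique toxin-trait pairs
#' assayed per hotspot region -- each unique pair is one test of
#' recapitulation -- and the total across regions.
#'
#' @param panel data frame with columns `toxin`, `hotspots`
#'   (comma-separated region labels), `traits` (comma-separated trait
#'   names).
#' @return List: `per_hotspot` (named integer vector) and `total`.
#' @export
count_validation_tests <- function(panel) {
  stopifnot(all(c("toxin", "hotspots", "traits") %in% names(panel)))
  long <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    hs <- trimws(strsplit(panel$hotspots[i], ",")[[1L]])
    tr <- trimws(strsplit(panel$traits[i], ",")[[1L]])
    expand.grid(hotspot = hs, toxin = panel$toxin[i], trait = tr,
                stringsAsFactors = FALSE)
  }))
  long <- unique(long)
  per <- tapply(seq_len(nrow(long)), long$hotspot, length)
  per <- stats::setNames(as.integer(per), names(per))
  list(per_hotspot = per, total = sum(per))
}
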