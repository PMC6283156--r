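#' Write a genotype matrix as TSV
#'
#' One row per marker: `marker`, `chrom`, `pos_bp`, `pos_cM`, then one
#' column per strain with allele labels ("N2" for parent A, "CB" for parent
#' B by default, "NA" for missing).
#'
#' @param geno a `geno_matrix`.
#' @param path output file.
#' @param alleles length-2 character vector: labels for the -1 and +1
#'   alleles.
#' @export
write_genotypes <- function(geno, path, alleles = c("N2", "CB")) {
  stopifnot(inherits(geno, "geno_matrix"), length(alleles) == 2)
  lab <- matrix(NA_character_, ncol(geno$calls), nrow(geno$calls))
  calls_t <- t(geno$calls)
  lab[calls_t == -1] <- alleles[1L]
  lab[calls_t == 1] <- alleles[2L]
  colnames(lab) <- rownames(geno$calls)
  out <- cbind(geno$map[, c("marker", "chrom", "pos_bp", "pos_cM")],
               as.data.frame(lab, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a genotype matrix from TSV
#'
#' Expects the format written by [write_genotypes()]: header columns
#' `marker`, `chrom`, `pos_bp`, `pos_cM` (optional) followed by strain
#' columns of allele labels. Duplicate marker ids and non-monotone
#' positions within a chromosome are rejected with the offending line
#' numbers; an unknown allele token is rejected naming its row and column.
#' Reports the overall missingness fraction via the `missingness`
#' attribute.
#'
#' @param path TSV file.
#' @param alleles length-2 character vector: labels for the -1 and +1
#'   alleles. Default `c("N2", "CB")`.
#' @return A `geno_matrix`.
#' @export
load_genotypes <- function(path, alleles = c("N2", "CB")) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  need <- c("marker", "chrom", "pos_bp")
  if (!all(need %in% names(tab)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  has_cM <- "pos_cM" %in% names(tab)
  dup <- which(duplicated(tab$marker))
  if (length(dup))
    stop("duplicate marker id(s) at line(s) ",
         paste(dup + 1L, collapse = ", "))
  map <- data.frame(marker = tab$marker, chrom = tab$chrom,
                    pos_bp = as.numeric(tab$pos_bp),
                    pos_cM = if (has_cM) as.numeric(tab$pos_cM) else NA_real_,
                    stringsAsFactors = FALSE)
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    bad <- idx[which(diff(map$pos_bp[idx]) <= 0) + 1L]
    if (has_cM)
      bad <- union(bad, idx[which(diff(map$pos_cM[idx]) < 0) + 1L])
    if (length(bad))
      stop("non-monotone position(s) on chromosome ", chr, " at line(s) ",
           paste(sort(bad) + 1L, collapse = ", "))
  }
  strain_cols <- setdiff(names(tab), c(need, "pos_cM"))
  if (!length(strain_cols)) stop("no strain columns found")
  calls <- matrix(NA_real_, length(strain_cols), nrow(tab),
                  dimnames = list(strain_cols, tab$marker))
  for (s in strain_cols) {
    v <- tab[[s]]
    v[is.na(v)] <- "NA"
    known <- v %in% c(alleles, "NA", "")
    if (!all(known)) {
      i <- which(!known)[1L]
      stop("unknown allele token '", v[i], "' at line ", i + 1L,
           ", column '", s, "'")
    }
    calls[s, ] <- ifelse(v == alleles[1L], -1,
                         ifelse(v == alleles[2L], 1, NA_real_))
  }
  geno <- structure(list(calls = calls, map = map), class = "geno_matrix")
  attr(geno, "missingness") <- mean(is.na(calls))
  geno
}

#' Write strain phenotypes as long-format TSV
#'
#' Columns: `strain`, `condition`, `trait`, `value`.
#'
#' @param pheno strains x traits matrix (row and column names required).
#' @param path output file.
#' @param condition condition label; defaults to the matrix's `condition`
#'   attribute.
#' @export
write_phenotypes <- function(pheno, path, condition = NULL) {
  if (is.null(condition)) condition <- attr(pheno, "condition")
  if (is.null(condition)) condition <- "condition"
  long <- data.frame(strain = rep(rownames(pheno), ncol(pheno)),
                     condition = condition,
                     trait = rep(colnames(pheno), each = nrow(pheno)),
                     value = as.vector(pheno), stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load strain phenotypes from long-format TSV
#'
#' @param path TSV with columns `strain`, `condition`, `trait`, `value`.
#' @param condition optional condition filter.
#' @return strains x traits matrix with a `condition` attribute.
#' @export
load_phenotypes <- function(path, condition = NULL) {
  long <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  stopifnot(all(c("strain", "condition", "trait", "value") %in% names(long)))
  if (!is.null(condition)) long <- long[long$condition == condition, ]
  strains <- unique(long$strain)
  traits <- unique(long$trait)
  out <- matrix(NA_real_, length(strains), length(traits),
                dimnames = list(strains, traits))
  out[cbind(match(long$strain, strains), match(long$trait, traits))] <- long$value
  attr(out, "condition") <- if (is.null(condition))
    long$condition[1L] else condition
  out
}

#' Run the full analysis pipeline on simulated or loaded data
#'
#' Orchestrates the stages in the order of the study design: simulate (or
#' load) genotypes and phenotypes, principal-component reduction, forward-
#' search linkage mapping of the retained components, variance-component
#' heritability, empirical-map binning, and hotspot detection. All stage
#' outputs are written as TSV to `config$out_dir` together with a
#' machine-readable JSON manifest (parameters, package version, input
#' digests). Deterministic given `config$seed`.
#'
#' @param config a list: `seed` (required), `out_dir` (required), and
#'   optionally `n_strains` (default 296), `n_markers` (per chromosome,
#'   default 20), `genotypes` (TSV path to load instead of simulating),
#'   `additive`, `epistatic` (architecture data frames), `n_perm` (default
#'   1000), `alpha` (default 0.05), `variance_threshold` (default 0.90),
#'   `lod_drop` (default 1.5), `bin_size_cM` (default 26),
#'   `hotspot_percentile` (default 0.99), `max_qtl` (default 10).
#' @return Invisibly, a list with the stage results (`geno`, `pheno`,
#'   `pcs`, `scans`, `qtl`, `herit`, `bins`) and the manifest.
#' @export
run_pipeline <- function(config) {
  defaults <- list(n_strains = 296L, n_markers = 20L, n_perm = 1000L,
                   alpha = 0.05, variance_threshold = 0.90, lod_drop = 1.5,
                   bin_size_cM = 26, hotspot_percentile = 0.99, max_qtl = 10L,
                   additive = data.frame(marker = integer(),
                                         var_frac = numeric()),
                   epistatic = data.frame(marker1 = integer(),
                                          marker2 = integer(),
                                          var_frac = numeric()))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$seed)) stop("config$seed is required")
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  if (config$alpha <= 0 || config$alpha >= 1) stop("alpha must be in (0, 1)")
  if (config$variance_threshold <= 0 || config$variance_threshold > 1)
    stop("variance_threshold must be in (0, 1]")
  if (config$n_perm < 100) stop("n_perm must be at least 100")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  run_id <- sprintf("run-%d", as.integer(config$seed))

  if (!is.null(config$genotypes)) {
    geno <- load_genotypes(config$genotypes)
  } else {
    geno <- simulate_riail_panel(config$n_strains,
                                 riail_map(n_markers = config$n_markers),
                                 seed = config$seed)
  }
  arch <- architecture(additive = config$additive,
                       epistatic = config$epistatic)
  sim <- simulate_phenotypes(geno, arch, seed = config$seed + 1L)
  pheno <- sim$traits
  attr(pheno, "condition") <- "simulated"

  geno_path <- file.path(config$out_dir, "genotypes.tsv")
  write_genotypes(geno, geno_path)
  pheno_path <- file.path(config$out_dir, "phenotypes.tsv")
  write_phenotypes(pheno, pheno_path)

  pcs <- pca_select(pheno, variance_threshold = config$variance_threshold,
                    condition = "simulated")
  pc_tab <- data.frame(run_id = run_id,
                       pc = seq_along(pcs$variance_fractions),
                       variance_fraction = pcs$variance_fractions,
                       selected = seq_along(pcs$variance_fractions) <=
                         pcs$n_selected)
  utils::write.table(pc_tab, file.path(config$out_dir, "pc_selection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  scans <- list()
  qtl_list <- list()
  for (k in seq_len(pcs$n_selected)) {
    fit <- forward_search(pcs$scores[, k], geno, n_perm = config$n_perm,
                          alpha = config$alpha, max_qtl = config$max_qtl,
                          seed = config$seed + 100L * k,
                          drop = config$lod_drop, trait = paste0("PC", k))
    scans[[k]] <- fit
    if (nrow(fit$qtl)) qtl_list[[length(qtl_list) + 1L]] <- fit$qtl
  }
  qtl <- if (length(qtl_list)) do.call(rbind, qtl_list) else
    scans[[1L]]$qtl
  utils::write.table(cbind(run_id = run_id, qtl),
                     file.path(config$out_dir, "qtl.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  A <- additive_kernel(geno)
  herit <- lapply(seq_len(pcs$n_selected), function(k)
    fit_variance_components(pcs$scores[, k], A, with_interaction = TRUE))
  herit_tab <- data.frame(run_id = run_id,
                          trait = paste0("PC", seq_len(pcs$n_selected)),
                          h2_additive = vapply(herit, `[[`, numeric(1),
                                               "h2_additive"),
                          interaction_fraction =
                            vapply(herit, `[[`, numeric(1),
                                   "interaction_fraction"),
                          residual_fraction =
                            vapply(herit, `[[`, numeric(1),
                                   "residual_fraction"),
                          loglik = vapply(herit, `[[`, numeric(1), "loglik"),
                          model = "two-component")
  utils::write.table(herit_tab, file.path(config$out_dir, "heritability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  gmap <- estimate_genetic_map(geno)
  bins <- bin_genome(gmap, bin_size_cM = config$bin_size_cM)
  if (nrow(qtl)) {
    peaks <- data.frame(chrom = qtl$chrom,
                        peak_pos = gmap$pos_cM[match(qtl$peak_marker,
                                                     gmap$marker)])
    bins <- detect_hotspots(peaks, bins,
                            percentile = config$hotspot_percentile)
  } else {
    bins$count <- 0L
    bins$hotspot <- FALSE
  }
  utils::write.table(cbind(run_id = run_id, as.data.frame(bins)),
                     file.path(config$out_dir, "hotspots.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    run_id = run_id,
    package_version = as.character(utils::packageVersion("riailqtl")),
    parameters = config[c("seed", "n_strains", "n_markers", "n_perm",
                          "alpha", "variance_threshold", "lod_drop",
                          "bin_size_cM", "hotspot_percentile", "max_qtl")],
    input_digests = as.list(tools::md5sum(c(geno_path, pheno_path))),
    outputs = c("genotypes.tsv", "phenotypes.tsv", "pc_selection.tsv",
                "qtl.tsv", "heritability.tsv", "hotspots.tsv"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(geno = geno, pheno = pheno, pcs = pcs, scans = scans,
                 qtl = qtl, herit = herit, bins = bins, manifest = manifest))
}
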