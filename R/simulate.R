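#' Simulate a recombinant inbred advanced intercross (RIAIL) panel
#'
#' Each strain's genotype along a chromosome is a two-state Markov chain over
#' the markers: the first marker is parent A (-1) or parent B (+1) with
#' probability 1/2, and the allele switches between adjacent markers with the
#' recombination fraction obtained from the interval's expanded-map distance
#' through the Haldane map function, r = (1 - exp(-2d))/2 with d in Morgans.
#' Symmetric initialization keeps the marginal allele frequency at 1/2 for
#' every marker. Inbred panels are modelled as fully homozygous, so calls are
#' coded -1 (parent A, "N2-like") and +1 (parent B, "CB4856-like").
#'
#' @param n_strains number of strains to simulate (>= 2).
#' @param map a [map_spec()] object; defaults to [riail_map()].
#' @param seed integer seed; required for reproducibility.
#' @param missing_rate optional fraction of calls set to `NA` at random, to
#'   exercise missing-data paths. Default 0 (no missing data).
#' @return An object of class `geno_matrix`: list with `calls` (strains x
#'   markers matrix of -1/+1, possibly `NA`) and `map` (marker data frame
#'   with `marker`, `chrom`, `pos_bp`, `pos_cM`).
#' @examples
#' g <- simulate_riail_panel(20, riail_map(n_markers = 5), seed = 1)
#' dim(g$calls)
#' @export
simulate_riail_panel <- function(n_strains, map = riail_map(), seed,
                                 missing_rate = 0) {
  if (n_strains < 2) stop("n_strains must be at least 2")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  stopifnot(inherits(map, "map_spec"))
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  mk <- map$markers
  calls <- matrix(NA_real_, n_strains, nrow(mk))
  for (chr in unique(mk$chrom)) {
    idx <- which(mk$chrom == chr)
    d <- diff(mk$pos_cM[idx])
    r <- haldane_r(d)
    block <- matrix(0, n_strains, length(idx))
    block[, 1L] <- sample(c(-1, 1), n_strains, replace = TRUE)
    if (length(idx) > 1L) {
      for (k in seq_along(r)) {
        flip <- stats::rbinom(n_strains, 1L, r[k])
        block[, k + 1L] <- block[, k] * (1 - 2 * flip)
      }
    }
    calls[, idx] <- block
  }
  dimnames(calls) <- list(sprintf("QX%03d", seq_len(n_strains)), mk$marker)
  if (missing_rate > 0) {
    drop <- which(stats::runif(length(calls)) < missing_rate)
    calls[drop] <- NA_real_
  }
  structure(list(calls = calls, map = mk), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$calls), "strains x", ncol(x$calls),
      "markers on", length(unique(x$map$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$calls))
  if (miss > 0) cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Simulate a near-isogenic line or chromosome-substitution genotype
#'
#' A NIL carries a single genomic interval introgressed from one parent in
#' the uniform background of the other; a CSS carries one whole chromosome.
#' All markers take the background allele except those inside the interval,
#' which take the opposite allele.
#'
#' @param map a [map_spec()] object giving the marker layout.
#' @param background background allele code, -1 (parent A) or +1 (parent B).
#' @param chrom chromosome of the introgression, or `NULL` for a pure
#'   parental genotype.
#' @param start_cM,end_cM interval bounds in cM on `chrom` (markers with
#'   `start_cM <= pos < end_cM` are introgressed). Omit both for a
#'   whole-chromosome substitution.
#' @param strain_id row name for the returned genotype.
#' @return A `geno_matrix` with a single strain.
#' @export
simulate_introgression_line <- function(map, background = -1, chrom = NULL,
                                        start_cM = NULL, end_cM = NULL,
                                        strain_id = "NIL") {
  stopifnot(inherits(map, "map_spec"), background %in% c(-1, 1))
  mk <- map$markers
  calls <- matrix(background, 1L, nrow(mk),
                  dimnames = list(strain_id, mk$marker))
  if (!is.null(chrom)) {
    if (!chrom %in% mk$chrom) stop("chromosome '", chrom, "' not on the map")
    on_chr <- mk$chrom == chrom
    if (is.null(start_cM) && is.null(end_cM)) {
      calls[1L, on_chr] <- -background
    } else {
      len <- max(mk$pos_cM[on_chr])
      if (start_cM < 0 || end_cM > len || start_cM > end_cM)
        stop("interval outside map bounds")
      inside <- on_chr & mk$pos_cM >= start_cM & mk$pos_cM < end_cM
      calls[1L, inside] <- -background
    }
  }
  structure(list(calls = calls, map = mk), class = "geno_matrix")
}

#' Specify a phenotype architecture for simulation
#'
#' Encodes the variance structure that the variance-component analyses
#' estimate: planted additive QTL, planted pairwise (product-term) epistatic
#' interactions, assay/batch shifts, and residual noise. Under the -1/+1
#' allele coding each marker has unit variance and the product of two
#' unlinked markers is orthogonal to both, so an effect of
#' sqrt(f) per unit-variance term plants a variance fraction of f exactly.
#'
#' @param additive data frame with columns `marker` (index into the
#'   genotype matrix columns) and `var_frac`; may be empty.
#' @param epistatic data frame with columns `marker1`, `marker2`,
#'   `var_frac`; may be empty.
#' @param trait_loadings numeric vector of per-trait loadings on the latent
#'   genetic value, one per output trait. Each trait is
#'   `w * latent + sqrt(1 - w^2) * noise`, giving unit-variance traits
#'   correlated through the shared latent value. Defaults to the 24-trait
#'   sorter roster with loadings from 1 down to 0.55.
#' @param assay_effect_sd standard deviation of per-assay batch shifts
#'   (applied on the latent scale). Default 0.
#' @param noise_var residual variance of the latent value; defaults to
#'   1 minus the summed planted fractions, for a unit-variance latent.
#' @return An object of class `arch_spec`.
#' @export
architecture <- function(additive = data.frame(marker = integer(), var_frac = numeric()),
                         epistatic = data.frame(marker1 = integer(),
                                                marker2 = integer(),
                                                var_frac = numeric()),
                         trait_loadings = NULL,
                         assay_effect_sd = 0,
                         noise_var = NULL) {
  planted <- sum(additive$var_frac) + sum(epistatic$var_frac)
  if (planted > 1) stop("summed variance fractions exceed 1")
  if (is.null(noise_var)) noise_var <- 1 - planted
  if (noise_var < 0) stop("noise_var must be non-negative")
  if (is.null(trait_loadings)) {
    trait_loadings <- stats::setNames(
      seq(1, 0.55, length.out = length(trait_roster())), trait_roster())
  }
  if (any(abs(trait_loadings) > 1)) stop("trait loadings must lie in [-1, 1]")
  structure(list(additive = additive, epistatic = epistatic,
                 trait_loadings = trait_loadings,
                 assay_effect_sd = assay_effect_sd,
                 noise_var = noise_var),
            class = "arch_spec")
}

#' Simulate strain phenotypes from a genotype matrix and an architecture
#'
#' The latent genetic value of each strain is the sum of planted additive
#' marker effects, planted pairwise product (epistatic) effects, an optional
#' per-assay batch shift, and Gaussian noise; each of the 24 output traits is
#' a loading-weighted copy of the latent value plus independent trait noise,
#' so traits are mutually correlated the way sorter summary statistics are.
#'
#' @param geno a `geno_matrix`.
#' @param arch an [architecture()] specification.
#' @param seed integer seed.
#' @param n_assays number of assay batches the strains are split across
#'   (round-robin); batch shifts are drawn iid Normal(0, `assay_effect_sd`).
#' @return A list of class `sim_pheno`: `latent` (named vector), `traits`
#'   (strains x traits matrix), `assay` (factor of batch labels).
#' @export
simulate_phenotypes <- function(geno, arch, seed, n_assays = 1L) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(arch, "arch_spec"))
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  G <- geno$calls
  n <- nrow(G)
  m <- ncol(G)
  if (nrow(arch$additive) && any(arch$additive$marker > m | arch$additive$marker < 1))
    stop("additive marker index out of range")
  if (nrow(arch$epistatic) &&
      any(c(arch$epistatic$marker1, arch$epistatic$marker2) > m |
          c(arch$epistatic$marker1, arch$epistatic$marker2) < 1))
    stop("epistatic marker index out of range")
  latent <- numeric(n)
  if (nrow(arch$additive)) {
    for (i in seq_len(nrow(arch$additive)))
      latent <- latent + sqrt(arch$additive$var_frac[i]) * G[, arch$additive$marker[i]]
  }
  if (nrow(arch$epistatic)) {
    for (i in seq_len(nrow(arch$epistatic)))
      latent <- latent + sqrt(arch$epistatic$var_frac[i]) *
        G[, arch$epistatic$marker1[i]] * G[, arch$epistatic$marker2[i]]
  }
  assay <- factor(rep_len(paste0("assay", seq_len(n_assays)), n))
  if (arch$assay_effect_sd > 0) {
    shifts <- stats::rnorm(n_assays, 0, arch$assay_effect_sd)
    latent <- latent + shifts[as.integer(assay)]
  }
  latent <- latent + stats::rnorm(n, 0, sqrt(arch$noise_var))
  names(latent) <- rownames(G)
  w <- arch$trait_loadings
  traits <- outer(latent, w) +
    matrix(stats::rnorm(n * length(w)), n) * rep(sqrt(1 - w^2), each = n)
  dimnames(traits) <- list(rownames(G), names(w))
  structure(list(latent = latent, traits = traits, assay = assay),
            class = "sim_pheno")
}

#' Simulate raw per-object sorter records
#'
#' Generates per-animal time-of-flight (TOF, length) and extinction (EXT,
#' optical density) draws for each well, with the strain's latent genetic
#' value shifting mean length. EXT is generated as TOF times a normalized
#' optical density, mirroring how the sorter traits deconvolve density from
#' length. Useful for exercising the well-summarization pipeline against
#' known strain-level values.
#'
#' @param geno a `geno_matrix` (strain names are taken from it).
#' @param arch an [architecture()] specification for the latent values.
#' @param seed integer seed.
#' @param condition condition label stamped on every record.
#' @param n_wells wells per strain.
#' @param sorted_count animals dispensed per well.
#' @param mean_brood mean number of measured objects per well.
#' @param tof_mean,tof_sd baseline TOF distribution; the latent value shifts
#'   the mean by `tof_effect` units per latent SD.
#' @param tof_effect TOF units per unit latent value.
#' @return A data frame with columns `assay`, `plate`, `well`, `strain`,
#'   `condition`, `sorted_count`, `TOF`, `EXT` (one row per object).
#' @export
simulate_raw_objects <- function(geno, arch, seed, condition = "toxin",
                                 n_wells = 3L, sorted_count = 3L,
                                 mean_brood = 30, tof_mean = 300, tof_sd = 30,
                                 tof_effect = 30) {
  stopifnot(inherits(geno, "geno_matrix"))
  sim <- simulate_phenotypes(geno, arch, seed = seed)
  set.seed(as.integer(seed) + 1L)
  strains <- rownames(geno$calls)
  out <- vector("list", length(strains) * n_wells)
  k <- 0L
  for (s in seq_along(strains)) {
    for (w in seq_len(n_wells)) {
      k <- k + 1L
      n_obj <- max(1L, stats::rpois(1L, mean_brood))
      tof <- stats::rnorm(n_obj, tof_mean + tof_effect * sim$latent[s], tof_sd)
      tof <- pmax(tof, 1)
      norm_ext <- pmax(stats::rnorm(n_obj, 0.18, 0.02), 0.01)
      out[[k]] <- data.frame(
        assay = "assay1", plate = sprintf("p%02d", w),
        well = sprintf("%s%02d", LETTERS[(s - 1L) %% 8L + 1L], (s - 1L) %/% 8L + 1L),
        strain = strains[s], condition = condition,
        sorted_count = sorted_count,
        TOF = tof, EXT = tof * norm_ext,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
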