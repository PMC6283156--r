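#' The 24-trait sorter roster
#'
#' The per-well growth-response traits: {mean, median, q10, q25, q75, q90}
#' for each of TOF (animal length), EXT (optical density), and norm.EXT
#' (EXT/TOF per animal), plus var.TOF, var.EXT, cv.TOF, cv.EXT, brood size
#' `n`, and normalized brood size `norm.n` (n / animals sorted).
#'
#' @return Character vector of the 24 trait names.
#' @export
trait_roster <- function() {
  stats_ <- c("mean", "median", "q10", "q25", "q75", "q90")
  c(as.vector(outer(stats_, c("TOF", "EXT", "norm.EXT"), paste, sep = ".")),
    "var.TOF", "var.EXT", "cv.TOF", "cv.EXT", "n", "norm.n")
}

#' Summarize one well of sorter objects into the 24 traits
#'
#' Objects with non-positive TOF are rejected as invalid. Quantiles use the
#' linear-interpolation definition (type 7, the default of the statistical
#' environment the pipeline reproduces); the type is configurable. With a
#' single object all quantiles collapse to it, the variance is 0 by
#' convention and so is the coefficient of variation. An empty well reports
#' `n = 0`, `norm.n = 0` and `NA` for every distributional trait.
#'
#' @param tof numeric vector of per-object time-of-flight values.
#' @param ext numeric vector of per-object extinction values (same length).
#' @param sorted_count number of animals dispensed into the well (>= 1).
#' @param quantile_type passed to [stats::quantile()]. Default 7.
#' @return Named numeric vector over [trait_roster()].
#' @examples
#' summarize_well(c(100, 200), c(50, 100), sorted_count = 3)[c("mean.norm.EXT", "norm.n")]
#' @export
summarize_well <- function(tof, ext, sorted_count, quantile_type = 7) {
  stopifnot(length(tof) == length(ext), sorted_count >= 1)
  ok <- !is.na(tof) & !is.na(ext) & tof > 0
  tof <- tof[ok]; ext <- ext[ok]
  out <- stats::setNames(rep(NA_real_, 24L), trait_roster())
  out["n"] <- length(tof)
  out["norm.n"] <- length(tof) / sorted_count
  if (length(tof) == 0L) return(out)
  norm_ext <- ext / tof
  measures <- list(TOF = tof, EXT = ext, norm.EXT = norm_ext)
  for (m in names(measures)) {
    v <- measures[[m]]
    q <- stats::quantile(v, c(.10, .25, .75, .90), type = quantile_type, names = FALSE)
    out[paste0(c("mean.", "median.", "q10.", "q25.", "q75.", "q90."), m)] <-
      c(mean(v), stats::median(v), q[1], q[2], q[3], q[4])
  }
  vt <- if (length(tof) > 1L) stats::var(tof) else 0
  ve <- if (length(ext) > 1L) stats::var(ext) else 0
  out["var.TOF"] <- vt
  out["var.EXT"] <- ve
  out["cv.TOF"] <- if (mean(tof) != 0) sqrt(vt) / mean(tof) else 0
  out["cv.EXT"] <- if (mean(ext) != 0) sqrt(ve) / mean(ext) else 0
  out
}

#' Summarize a raw object table into per-well trait rows
#'
#' Applies [summarize_well()] to every (assay, plate, well, strain,
#' condition) group of a raw per-object table. Records flagged invalid via
#' an optional logical `valid` column (e.g. wells failing visual
#' contamination inspection) are dropped first.
#'
#' @param raw data frame with columns `assay`, `plate`, `well`, `strain`,
#'   `condition`, `sorted_count`, `TOF`, `EXT`, and optionally `valid`.
#' @param quantile_type passed to [summarize_well()].
#' @return Data frame: one row per well with the grouping columns followed
#'   by the 24 traits.
#' @export
summarize_wells <- function(raw, quantile_type = 7) {
  need <- c("assay", "plate", "well", "strain", "condition", "sorted_count", "TOF", "EXT")
  stopifnot(all(need %in% names(raw)))
  if ("valid" %in% names(raw)) raw <- raw[raw$valid, , drop = FALSE]
  key <- interaction(raw$assay, raw$plate, raw$well, raw$strain, raw$condition,
                     drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(raw)), key)
  rows <- lapply(groups, function(idx) {
    slice <- raw[idx, , drop = FALSE]
    tr <- summarize_well(slice$TOF, slice$EXT, slice$sorted_count[1L],
                         quantile_type = quantile_type)
    cbind(slice[1L, c("assay", "plate", "well", "strain", "condition")],
          as.data.frame(as.list(tr), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regress assay (batch) effects out of trait values
#'
#' Fits the one-way fixed-effect model `phenotype ~ assay` per trait and
#' returns the residuals, removing additive batch shifts between assay
#' days. With a single assay level this is mean-centering. An observation
#' that is alone in its assay level gets residual 0 (flagged via attribute
#' `singletons`).
#'
#' @param values numeric vector of trait values.
#' @param assay factor (or coercible) of assay labels, same length.
#' @return Numeric vector of residuals (sums to ~0).
#' @export
regress_assay <- function(values, assay) {
  assay <- factor(assay)
  stopifnot(length(values) == length(assay))
  if (length(values) < 2) stop("need at least 2 observations")
  means <- tapply(values, assay, mean, na.rm = TRUE)
  res <- values - as.numeric(means[as.integer(assay)])
  counts <- table(assay)
  singles <- which(as.numeric(counts[as.integer(assay)]) == 1 & !is.na(values))
  if (length(singles)) attr(res, "singletons") <- singles
  res
}

#' Remove outliers beyond a standard-deviation band, with an exemption
#'
#' Values outside `mean +/- sd_mult * SD` (mean and SD computed once on the
#' input, not iteratively) are set to `NA` -- unless at least
#' `exemption_fraction` of the values lie outside the band, in which case
#' everything is retained: a heavy tail that large is treated as real strain
#' variation, not measurement error. Zero-variance input is returned
#' unchanged.
#'
#' @param values numeric vector (>= 3 non-missing values).
#' @param sd_mult width of the band in SDs. Default 2.
#' @param exemption_fraction retain-all threshold. Default 0.05.
#' @return `values` with outliers set to `NA`; attribute `removed` holds the
#'   indices removed (if any).
#' @export
remove_outliers <- function(values, sd_mult = 2, exemption_fraction = 0.05) {
  ok <- !is.na(values)
  if (sum(ok) < 3) stop("need at least 3 non-missing values")
  m <- mean(values[ok])
  s <- stats::sd(values[ok])
  if (s == 0) return(values)
  outside <- ok & (values < m - sd_mult * s | values > m + sd_mult * s)
  if (sum(outside) / sum(ok) >= exemption_fraction) return(values)
  if (any(outside)) {
    values[outside] <- NA_real_
    attr(values, "removed") <- which(outside)
  }
  values
}

#' Regress control-condition phenotypes out of toxin phenotypes
#'
#' Fits `toxin phenotype ~ control phenotype` per trait over strains matched
#' by name and returns the residuals: the toxin-specific effect after
#' accounting for strain differences already present in the control
#' condition. Strains missing a control value are dropped. A zero-variance
#' control degenerates to mean-centering (flagged via attribute
#' `degenerate_control`).
#'
#' @param toxin_values named numeric vector (names = strains).
#' @param control_values named numeric vector (names = strains).
#' @return Named numeric residual vector over the strains present in both.
#' @export
regress_control <- function(toxin_values, control_values) {
  stopifnot(!is.null(names(toxin_values)), !is.null(names(control_values)))
  common <- intersect(names(toxin_values)[!is.na(toxin_values)],
                      names(control_values)[!is.na(control_values)])
  y <- toxin_values[common]
  x <- control_values[common]
  if (length(common) < 2) stop("need at least 2 matched strains")
  if (stats::sd(x) == 0) {
    res <- y - mean(y)
    attr(res, "degenerate_control") <- TRUE
    return(res)
  }
  stats::setNames(stats::residuals(stats::lm(y ~ x)), common)
}

#' Process raw sorter records into residual strain phenotypes
#'
#' The full trait pipeline: per-well summarization, averaging to one value
#' per strain x assay, assay-effect regression (when more than one assay is
#' present), outlier removal per trait, and control-condition regression,
#' yielding the residual toxin-specific phenotype per strain and trait.
#'
#' @param raw raw object table (see [summarize_wells()]), containing the
#'   toxin condition and optionally the control condition.
#' @param condition toxin condition to process.
#' @param control control condition name, or `NULL` to skip control
#'   regression.
#' @param regress_assay_effects regress out assay labels? Default `TRUE`.
#' @param sd_mult,exemption_fraction outlier-removal parameters.
#' @return A strains x 24 matrix of residual phenotype values, with
#'   attributes `condition` and `provenance` (which steps ran).
#' @export
process_phenotypes <- function(raw, condition, control = NULL,
                               regress_assay_effects = TRUE,
                               sd_mult = 2, exemption_fraction = 0.05) {
  ws <- summarize_wells(raw)
  build <- function(cond) {
    sub <- ws[ws$condition == cond, , drop = FALSE]
    if (!nrow(sub)) stop("no records for condition '", cond, "'")
    traits <- trait_roster()
    # mean over wells within strain x assay
    key <- interaction(sub$strain, sub$assay, drop = TRUE)
    agg <- do.call(rbind, lapply(split(seq_len(nrow(sub)), key), function(idx) {
      cbind(sub[idx[1L], c("strain", "assay")],
            as.data.frame(as.list(colMeans(sub[idx, traits, drop = FALSE],
                                           na.rm = TRUE)), check.names = FALSE))
    }))
    if (regress_assay_effects && length(unique(agg$assay)) > 1L) {
      for (tr in traits) agg[[tr]] <- as.numeric(regress_assay(agg[[tr]], agg$assay))
    }
    # collapse to one value per strain
    out <- do.call(rbind, lapply(split(seq_len(nrow(agg)), agg$strain), function(idx)
      colMeans(agg[idx, traits, drop = FALSE], na.rm = TRUE)))
    out
  }
  pheno <- build(condition)
  for (tr in colnames(pheno)) {
    v <- pheno[, tr]
    if (sum(!is.na(v)) >= 3 && stats::sd(v, na.rm = TRUE) > 0)
      pheno[, tr] <- as.numeric(remove_outliers(v, sd_mult, exemption_fraction))
  }
  prov <- c(assay_regressed = regress_assay_effects, control_regressed = FALSE)
  if (!is.null(control)) {
    ctrl <- build(control)
    common <- intersect(rownames(pheno), rownames(ctrl))
    res <- matrix(NA_real_, length(common), ncol(pheno),
                  dimnames = list(common, colnames(pheno)))
    for (tr in colnames(pheno)) {
      tv <- stats::setNames(pheno[common, tr], common)
      cv <- stats::setNames(ctrl[common, tr], common)
      keep <- !is.na(tv) & !is.na(cv)
      if (sum(keep) >= 2 && stats::sd(cv[keep]) >= 0) {
        r <- regress_control(tv[keep], cv[keep])
        res[names(r), tr] <- as.numeric(r)
      }
    }
    pheno <- res
    prov["control_regressed"] <- TRUE
  }
  attr(pheno, "condition") <- condition
  attr(pheno, "provenance") <- prov
  pheno
}
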