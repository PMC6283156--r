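#' Specify a genetic map for panel simulation
#'
#' A map specification lists the chromosomes of the cross, how many markers
#' each carries, and the *expanded* genetic length of each chromosome in
#' centimorgans. Advanced-intercross panels accumulate recombination over
#' several generations of intercrossing, so the map consumed here is the
#' already-expanded map: no pedigree is simulated, because downstream
#' analyses only consume marginal genotype correlations.
#'
#' Marker genetic positions are laid out evenly from 0 to the chromosome
#' length; physical positions are laid out evenly along a nominal 15-Mb
#' chromosome and are annotation only (all analyses work in cM).
#'
#' @param chromosomes data frame with columns `name`, `n_markers`, and
#'   `length_cM` (expanded genetic length per chromosome).
#' @param expansion_generations integer, the number of intercross
#'   generations the expanded lengths already reflect (recorded, not used).
#' @return An object of class `map_spec`: the input plus a `markers` data
#'   frame (`marker`, `chrom`, `pos_bp`, `pos_cM`).
#' @examples
#' ms <- map_spec(data.frame(name = "I", n_markers = 11, length_cM = 100))
#' head(ms$markers)
#' @export
map_spec <- function(chromosomes, expansion_generations = 10L) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "n_markers", "length_cM") %in% names(chromosomes)))
  if (any(chromosomes$n_markers < 1))
    stop("each chromosome needs at least one marker")
  if (any(chromosomes$length_cM < 0))
    stop("genetic lengths must be non-negative")
  if (anyDuplicated(chromosomes$name))
    stop("duplicate chromosome names")
  markers <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i) {
    n <- chromosomes$n_markers[i]
    len <- chromosomes$length_cM[i]
    pos_cM <- if (n == 1L) 0 else seq(0, len, length.out = n)
    if (n > 1L && any(diff(pos_cM) <= 0) && len > 0)
      stop("marker genetic positions must be strictly increasing")
    data.frame(
      marker = sprintf("%s_%03d", chromosomes$name[i], seq_len(n)),
      chrom = as.character(chromosomes$name[i]),
      pos_bp = if (n == 1L) 1L else as.integer(round(seq(1, 15e6, length.out = n))),
      pos_cM = pos_cM,
      stringsAsFactors = FALSE
    )
  }))
  rownames(markers) <- NULL
  structure(list(chromosomes = chromosomes,
                 expansion_generations = as.integer(expansion_generations),
                 markers = markers),
            class = "map_spec")
}

#' Default RIAIL-style map specification
#'
#' Six chromosomes (I-V and X) with expanded lengths chosen so the genome
#' totals 1,690 cM and divides evenly into 65 bins of 26 cM
#' (10 + 10 + 10 + 12 + 12 + 11 bins per chromosome), matching the binning
#' used for hotspot detection on the empirical RIAIL map.
#'
#' @param n_markers markers per chromosome (same for all six).
#' @return A [map_spec()] object.
#' @export
riail_map <- function(n_markers = 50L) {
  map_spec(data.frame(
    name = c("I", "II", "III", "IV", "V", "X"),
    n_markers = as.integer(n_markers),
    length_cM = c(260, 260, 260, 312, 312, 286),
    stringsAsFactors = FALSE
  ))
}

#' @export
print.map_spec <- function(x, ...) {
  cat("Genetic map specification:", nrow(x$chromosomes), "chromosome(s),",
      nrow(x$markers), "markers,",
      sum(x$chromosomes$length_cM), "cM total (expanded)\n")
  invisible(x)
}

# Haldane map function: cM distance -> recombination fraction.
haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

# Inverse Haldane: recombination fraction -> cM.
haldane_d <- function(r) -50 * log(1 - 2 * r)
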