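# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files are read except the shipped
# plain-text study-design tables.

# Small RIAIL-style panel: 6 chromosomes, few markers, quick to simulate.
small_panel <- function(n_strains = 100, n_markers = 10, seed = 1) {
  simulate_riail_panel(n_strains, riail_map(n_markers = n_markers), seed = seed)
}

# One-chromosome map with explicit marker count/length.
one_chrom_map <- function(n_markers, length_cM, name = "I") {
  map_spec(data.frame(name = name, n_markers = n_markers,
                      length_cM = length_cM, stringsAsFactors = FALSE))
}

# Build a strain_comparison object directly from a role-indexed p-value
# matrix and medians, bypassing replicate data -- used to enumerate the
# categorization decision trees over their full configuration space.
synthetic_comparison <- function(p, medians, trait = "trait", assay = "NIL") {
  roles <- c("parentA", "parentB", "intro_bgA", "intro_bgB")
  stopifnot(identical(rownames(p), roles), identical(names(medians), roles))
  structure(list(p = p, medians = medians, trait = trait, assay = assay),
            class = "strain_comparison")
}

role_pmatrix <- function(pAB, pAa, pAb, pBa, pBb, pab) {
  roles <- c("parentA", "parentB", "intro_bgA", "intro_bgB")
  P <- matrix(NA_real_, 4, 4, dimnames = list(roles, roles))
  P["parentA", "parentB"] <- P["parentB", "parentA"] <- pAB
  P["parentA", "intro_bgA"] <- P["intro_bgA", "parentA"] <- pAa
  P["parentA", "intro_bgB"] <- P["intro_bgB", "parentA"] <- pAb
  P["parentB", "intro_bgA"] <- P["intro_bgA", "parentB"] <- pBa
  P["parentB", "intro_bgB"] <- P["intro_bgB", "parentB"] <- pBb
  P["intro_bgA", "intro_bgB"] <- P["intro_bgB", "intro_bgA"] <- pab
  P
}

# Replicate values for a four-strain validation assay with the given true
# strain means and a small, fixed noise SD (significance is then governed
# by the mean separation).
assay_values <- function(means, n_rep = 20, sd = 0.4, seed = 7) {
  set.seed(seed)
  strains <- names(means)
  data.frame(
    strain = rep(strains, each = n_rep),
    value = unlist(lapply(means, function(m) stats::rnorm(n_rep, m, sd))),
    stringsAsFactors = FALSE)
}

nil_roles <- c(parentA = "N2", parentB = "CB", intro_bgA = "nil_bgA",
               intro_bgB = "nil_bgB")
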