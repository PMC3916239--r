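# Built-in motif models and worked-example sequences.
#
# The functional HMG and Helper site alignments behind the original search
# matrices were published only as figure panels and formatted supplements;
# the site sets below are synthetic stand-ins designed to the published
# summary features: the Helper set reproduces the worm Helper consensus
# GCCRAnW (R = A/G, W = A/T, one fully degenerate position), the HMG set is
# centered on the high-affinity HMG consensus SCTTTGATS (S = G/C), and each
# build set includes the optimal synthetic-reporter site embedded in the
# printed 27-bp HMG-Helper repeat unit. The published cutoffs (Helper 5.51,
# HMG 6.69) are applied to these matrices on the package's log2 log-odds
# scale.

#' Synthetic stand-in Helper site alignment
#'
#' Eight 7-bp "genomic" Helper sites whose [derive_consensus()] under the
#' default rule is `GCCRAnW`, plus (optionally) the optimal synthetic
#' Helper site `GCCGCCA` from the concatemerized reporter repeat.
#'
#' @param include_optimal Include the optimal synthetic-reporter site used
#'   when building the search matrix (default TRUE). Exclude it to work
#'   with the eight-site consensus alignment alone.
#' @return A [site_set()].
#' @export
helper_sites_synthetic <- function(include_optimal = TRUE) {
  genomic <- c("GCCGAAA", "GCCAACT", "GCCGAGA", "GCCAATT",
               "GCCGACA", "GCCGATT", "GCCAAAA", "GCCGAGT")
  labels <- sprintf("synthetic_helper_%d", seq_along(genomic))
  if (include_optimal) {
    genomic <- c(genomic, "GCCGCCA")
    labels <- c(labels, "optimal_reporter_helper")
  }
  site_set(genomic, motif = "HELPER", labels = labels)
}

#' Synthetic stand-in HMG site alignment
#'
#' Five 9-bp "genomic" HMG sites around the high-affinity consensus
#' `SCTTTGATS`, plus (optionally) the optimal synthetic HMG site
#' `CCTTTGATC` carried on the minus strand of the reporter repeat unit.
#'
#' @inheritParams helper_sites_synthetic
#' @return A [site_set()].
#' @export
hmg_sites_synthetic <- function(include_optimal = TRUE) {
  genomic <- c("GCTTTGATG", "CCTTTGATG", "GCTTTGTTC",
               "ACTTTGAAG", "CCTTTGCTC")
  labels <- sprintf("synthetic_hmg_%d", seq_along(genomic))
  if (include_optimal) {
    genomic <- c(genomic, "CCTTTGATC")
    labels <- c(labels, "optimal_reporter_hmg")
  }
  site_set(genomic, motif = "HMG", labels = labels)
}

#' Default HMG and Helper matrices
#'
#' Log2 log-odds matrices (pseudocount 1, uniform background) built from
#' the synthetic stand-in site alignments, carrying the published search
#' cutoffs: 5.51 for Helper, 6.69 for HMG.
#'
#' @return List with elements `hmg` and `helper`, each a `wre_pwm`.
#' @export
default_pwms <- function() {
  list(
    hmg = build_pwm(hmg_sites_synthetic(), pseudocount = 1, cutoff = 6.69),
    helper = build_pwm(helper_sites_synthetic(), pseudocount = 1, cutoff = 5.51)
  )
}

#' The 27-bp HMG-Helper repeat unit of the concatemerized reporter
#'
#' The printed repeat carries one high-affinity HMG site on its minus
#' strand (`CCTTTGATC`) and one optimal Helper site on its plus strand
#' (`GCCGCCA`).
#'
#' @return A character string of length 27.
#' @export
pophhop_repeat <- function() "GGAAGATCAAAGGGGGTAGCCGCCAGT"

#' Concatemer of the HMG-Helper repeat unit
#'
#' @param n Number of repeats (default 6, the reporter configuration).
#' @return A character string of length `27 * n`.
#' @export
pophhop_concatemer <- function(n = 6L) strrep(pophhop_repeat(), n)

#' Synthetic region reproducing the K08D12.3-like cluster arrangement
#'
#' A deterministic 500-bp region carrying three Helper sites and one HMG
#' site, with the HMG site between Helpers and all three Helper starts
#' within 50 bp of the HMG start — the arrangement described for the
#' K08D12.3 upstream cluster. The flanking sequence is a fixed periodic
#' spacer free of Helper/HMG cores, so the region contains exactly the
#' planted sites; it is a synthetic stand-in, not genomic sequence.
#'
#' @return A named character vector of length 1 (name
#'   `"synthetic_K08D12.3_like"`).
#' @export
synthetic_k08d12_region <- function() {
  spacer <- function(n) substr(strrep("ATCAGA", ceiling(n / 6) + 1L), 1L, n)
  seqs <- c(spacer(120), "GCCGAGA",           # Helper1 at 121
            spacer(8), "GCCGAAA",             # Helper2 at 136
            spacer(6), "CCTTTGATC",           # HMG at 149
            spacer(10), "GCCAATT")            # Helper3 at 168
  region <- paste(seqs, collapse = "")
  region <- paste0(region, spacer(500L - nchar(region)))
  stats::setNames(region, "synthetic_K08D12.3_like")
}
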