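# End-to-end orchestration: scan regions with both matrices, detect and
# classify clusters, build the ranked report and a machine-readable run
# manifest with the counts at each funnel stage (regions scanned, regions
# with hits, clusters, topology-filtered clusters).

# Normalize region input (extract_upstream frame, named character vector,
# or DNAStringSet) to a region frame with region_id + sequence.
as_region_frame <- function(regions) {
  if (is.data.frame(regions)) {
    stopifnot(all(c("region_id", "sequence") %in% names(regions)))
    return(regions)
  }
  seqs <- as_dna_character_set(regions)
  data.frame(region_id = names(seqs), gene_id = names(seqs),
             anchor_kind = NA_character_, chrom = NA_character_,
             genomic_start = NA_integer_, genomic_end = NA_integer_,
             gene_strand = "+", sequence = unname(seqs), truncated = FALSE,
             stringsAsFactors = FALSE)
}

as_dna_character_set <- function(x) {
  if (inherits(x, "DNAStringSet")) x <- as.character(x)
  x <- unlist(x)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    names(x) <- sprintf("region_%03d", seq_along(x))
  }
  x
}

#' Run the full bipartite cluster search over a set of regions
#'
#' Scans every region with the HMG and Helper matrices, detects 50-bp-window
#' clusters, classifies topology and builds the ranked candidate report plus
#' a run manifest. When truth annotations from [plant_genome()] are
#' supplied, planted-cluster recovery (sensitivity) and cluster precision
#' against the truth are added to the manifest.
#'
#' @param regions An [extract_upstream()] frame, named character vector of
#'   sequences, or `DNAStringSet`.
#' @param hmg_pwm,helper_pwm Matrices with finite cutoffs (defaults:
#'   [default_pwms()]).
#' @param cfg A [scan_config()]; its cutoffs override the matrices' own.
#' @param truth Optional truth frame from [plant_genome()].
#' @return List of class `wre_scan_result`: `hits` (all motif hits),
#'   `clusters` (list of `wre_cluster`), `report` (ranked table), and
#'   `manifest` (named list of parameters and funnel counts).
#' @examples
#' pw <- default_pwms()
#' res <- run_scan_pipeline(pophhop_concatemer(6), pw$hmg, pw$helper)
#' res$manifest$n_clusters
#' @export
run_scan_pipeline <- function(regions, hmg_pwm = default_pwms()$hmg,
                              helper_pwm = default_pwms()$helper,
                              cfg = scan_config(), truth = NULL) {
  regions <- as_region_frame(regions)
  all_hits <- list()
  clusters <- list()
  n_regions_with_hits <- 0L
  n_regions_with_clusters <- 0L
  n_regions_topology <- 0L
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (!nzchar(r$sequence)) next
    hh <- scan_pwm(helper_pwm, r$sequence, region_id = r$region_id,
                   cutoff = cfg$helper_cutoff)
    gh <- scan_pwm(hmg_pwm, r$sequence, region_id = r$region_id,
                   cutoff = cfg$hmg_cutoff)
    if (nrow(hh) + nrow(gh) > 0L) {
      n_regions_with_hits <- n_regions_with_hits + 1L
      all_hits[[length(all_hits) + 1L]] <- rbind(hh, gh)
    }
    cl <- find_clusters(hh, gh, cfg)
    if (length(cl) > 0L) {
      n_regions_with_clusters <- n_regions_with_clusters + 1L
      if (any(vapply(cl, function(x) x$topology, character(1)) ==
              "HMG_BETWEEN_HELPERS")) {
        n_regions_topology <- n_regions_topology + 1L
      }
      clusters <- c(clusters, cl)
    }
  }
  hits <- if (length(all_hits) > 0L) do.call(rbind, all_hits) else
    scan_pwm(helper_pwm, "", region_id = "none")[0, ]
  rownames(hits) <- NULL
  topologies <- vapply(clusters, function(x) x$topology, character(1))
  manifest <- list(
    package_version = as.character(utils::packageVersion("wrescan")),
    parameters = list(
      window = cfg$window, min_helpers = cfg$min_helpers,
      min_hmg = cfg$min_hmg, helper_cutoff = cfg$helper_cutoff,
      hmg_cutoff = cfg$hmg_cutoff, upstream_length = cfg$upstream_length,
      membership = cfg$membership,
      hmg_matrix_width = hmg_pwm$width, helper_matrix_width = helper_pwm$width),
    n_regions = nrow(regions),
    n_regions_with_hits = n_regions_with_hits,
    n_regions_with_clusters = n_regions_with_clusters,
    n_regions_topology_filtered = n_regions_topology,
    n_hits = nrow(hits),
    n_helper_hits = sum(hits$motif == "HELPER"),
    n_hmg_hits = sum(hits$motif == "HMG"),
    n_clusters = length(clusters),
    n_topology_clusters = sum(topologies == "HMG_BETWEEN_HELPERS")
  )
  if (!is.null(truth)) {
    manifest <- c(manifest, recovery_stats(clusters, truth))
  }
  structure(
    list(hits = hits, clusters = clusters,
         report = rank_and_report(clusters, regions = regions),
         manifest = manifest),
    class = "wre_scan_result"
  )
}

#' @export
print.wre_scan_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "wre_scan_result: %d regions -> %d with hits -> %d clusters (%d regions) -> %d HMG-between-Helpers\n",
    m$n_regions, m$n_regions_with_hits, m$n_clusters,
    m$n_regions_with_clusters, m$n_topology_clusters))
  invisible(x)
}

# Sensitivity / precision of detected clusters against planted truth.
recovery_stats <- function(clusters, truth) {
  planted_regions <- unique(truth$region_id)
  if (length(planted_regions) == 0L) {
    return(list(n_planted = 0L, n_recovered = 0L, sensitivity = NA_real_,
                precision = if (length(clusters) == 0L) NA_real_ else 0))
  }
  cluster_span <- lapply(clusters, function(cl)
    list(region = cl$region_id, lo = cl$span_start, hi = cl$span_end))
  recovered <- vapply(planted_regions, function(rid) {
    tr <- truth[truth$region_id == rid, , drop = FALSE]
    any(vapply(cluster_span, function(cs) {
      cs$region == rid && cs$lo <= max(tr$end) && cs$hi >= min(tr$start)
    }, logical(1)))
  }, logical(1))
  true_clusters <- vapply(cluster_span, function(cs) {
    tr <- truth[truth$region_id == cs$region, , drop = FALSE]
    nrow(tr) > 0L && cs$lo <= max(tr$end) && cs$hi >= min(tr$start)
  }, logical(1))
  list(
    n_planted = length(planted_regions),
    n_recovered = sum(recovered),
    sensitivity = sum(recovered) / length(planted_regions),
    precision = if (length(clusters) == 0L) NA_real_
                else sum(true_clusters) / length(clusters)
  )
}

#' Write a run manifest as JSON
#'
#' @param result A `wre_scan_result` (or a bare manifest list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(result, path) {
  manifest <- if (inherits(result, "wre_scan_result")) result$manifest else result
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
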