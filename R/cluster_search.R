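# Detection of HMG-Helper clusters: a region scores positive when some
# 50-bp window holds at least two (distinct) Helper sites and one HMG site
# above their cutoffs. Overlapping qualifying windows merge into one cluster
# per locus; topology records whether an HMG site lies between two Helpers.

#' Scan configuration for the bipartite cluster search
#'
#' Defaults reproduce the published search criterion: a 50-bp window must
#' contain at least two Helper sites (cutoff 5.51) and one HMG site (cutoff
#' 6.69), scanning 500-bp upstream regions.
#'
#' @param window Window size in bp.
#' @param min_helpers Minimum distinct Helper hits per window.
#' @param min_hmg Minimum HMG hits per window.
#' @param helper_cutoff,hmg_cutoff Score thresholds for the two matrices.
#' @param upstream_length Upstream region length in bp.
#' @param membership Window membership rule for a hit: by `"start"` position
#'   (default) or full `"containment"` of the hit window.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(window = 50L, min_helpers = 2L, min_hmg = 1L,
                        helper_cutoff = 5.51, hmg_cutoff = 6.69,
                        upstream_length = 500L,
                        membership = c("start", "containment")) {
  membership <- match.arg(membership)
  if (window < 1L) stopf("window must be positive")
  if (min_helpers < 1L || min_hmg < 1L) stopf("site minima must be >= 1")
  structure(
    list(window = as.integer(window), min_helpers = as.integer(min_helpers),
         min_hmg = as.integer(min_hmg), helper_cutoff = helper_cutoff,
         hmg_cutoff = hmg_cutoff, upstream_length = as.integer(upstream_length),
         membership = membership),
    class = "scan_config"
  )
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf(
    "scan_config: >=%d Helper (cutoff %.2f) + >=%d HMG (cutoff %.2f) in %d bp; upstream %d bp; membership by %s\n",
    x$min_helpers, x$helper_cutoff, x$min_hmg, x$hmg_cutoff, x$window,
    x$upstream_length, x$membership))
  invisible(x)
}

# Collapse Helper hits that overlap on opposite strands by more than half
# the motif width (one palindromic site must not satisfy the two-Helper
# minimum twice). Returns representative starts, one per distinct site.
collapse_helper_starts <- function(hits) {
  if (nrow(hits) == 0L) return(integer(0))
  hits <- hits[order(hits$start, hits$strand, -hits$score), , drop = FALSE]
  reps <- list()
  for (i in seq_len(nrow(hits))) {
    merged <- FALSE
    for (j in seq_along(reps)) {
      r <- reps[[j]]
      if (r$strand != hits$strand[i] &&
          abs(hits$start[i] - r$start) < hits$width[i] / 2) {
        merged <- TRUE
        break
      }
    }
    if (!merged) reps[[length(reps) + 1L]] <-
        list(start = hits$start[i], strand = hits$strand[i])
  }
  sort(unique(vapply(reps, `[[`, numeric(1), "start")))
}

# Hit membership of the window [s, s + window - 1].
in_window <- function(starts, widths, s, window, membership) {
  if (membership == "start") {
    starts >= s & starts <= s + window - 1L
  } else {
    starts >= s & starts + widths - 1L <= s + window - 1L
  }
}

#' Find HMG-Helper clusters among the hits of one region
#'
#' Enumerates every window position, marks windows holding at least
#' `min_helpers` distinct Helper sites and `min_hmg` HMG sites, and merges
#' maximal runs of overlapping qualifying windows into one cluster per
#' locus. Hits on either strand count; Helper hits overlapping on opposite
#' strands at (essentially) the same position are collapsed to one site for
#' the count.
#'
#' @param helper_hits,hmg_hits Hit frames from [scan_pwm()], all from the
#'   same region.
#' @param cfg A [scan_config()].
#' @return A list of `wre_cluster` objects; each has `region_id`, `hits`
#'   (member hit frame), `span_start`, `span_end`, `topology`,
#'   `n_proximal_helpers`, `oriented_pair` and `aggregate_score`.
#' @examples
#' h <- data.frame(motif = "HELPER", region_id = "r", start = c(1, 40),
#'                 strand = "+", score = 6, width = 7)
#' g <- data.frame(motif = "HMG", region_id = "r", start = 20,
#'                 strand = "+", score = 7, width = 9)
#' length(find_clusters(h, g, scan_config()))  # 1
#' @export
find_clusters <- function(helper_hits, hmg_hits, cfg = scan_config()) {
  if (nrow(helper_hits) == 0L || nrow(hmg_hits) == 0L) return(list())
  region_id <- unique(c(helper_hits$region_id, hmg_hits$region_id))
  if (length(region_id) != 1L) {
    stopf("find_clusters expects hits from a single region, got: %s",
          paste(region_id, collapse = ", "))
  }
  helper_starts <- collapse_helper_starts(helper_hits)
  hmg_starts <- hmg_hits$start
  all_starts <- c(helper_starts, hmg_starts)
  s_min <- max(1L, min(all_starts) - cfg$window + 1L)
  s_max <- max(all_starts)
  qualifying <- integer(0)
  for (s in s_min:s_max) {
    nh <- sum(in_window(helper_starts, rep(helper_hits$width[1], length(helper_starts)),
                        s, cfg$window, cfg$membership))
    ng <- sum(in_window(hmg_starts, hmg_hits$width, s, cfg$window, cfg$membership))
    if (nh >= cfg$min_helpers && ng >= cfg$min_hmg) {
      qualifying <- c(qualifying, s)
    }
  }
  if (length(qualifying) == 0L) return(list())
  # Merge runs of qualifying window starts whose windows overlap.
  gaps <- which(diff(qualifying) > cfg$window - 1L)
  run_starts <- c(1L, gaps + 1L)
  run_ends <- c(gaps, length(qualifying))
  all_hits <- rbind(helper_hits, hmg_hits)
  all_hits <- all_hits[order(all_hits$start, all_hits$strand, -all_hits$score), ,
                       drop = FALSE]
  lapply(seq_along(run_starts), function(k) {
    lo <- qualifying[run_starts[k]]
    hi <- qualifying[run_ends[k]] + cfg$window - 1L
    members <- all_hits[all_hits$start >= lo & all_hits$start <= hi, , drop = FALSE]
    new_cluster(region_id, members, cfg)
  })
}

new_cluster <- function(region_id, hits, cfg) {
  rownames(hits) <- NULL
  cl <- structure(
    list(region_id = region_id, hits = hits,
         span_start = min(hits$start),
         span_end = max(hits$start + hits$width - 1L),
         topology = NA_character_, n_proximal_helpers = NA_integer_,
         oriented_pair = NA, aggregate_score = sum(hits$score)),
    class = "wre_cluster"
  )
  cl$topology <- classify_topology(cl)
  cl$n_proximal_helpers <- count_proximal_helpers(cl, radius = cfg$window)
  cl$oriented_pair <- detect_oriented_pair(cl, window = cfg$window)
  cl
}

#' @export
print.wre_cluster <- function(x, ...) {
  cat(sprintf("wre_cluster [%s] %d-%d: %d Helper + %d HMG hits, %s, %d proximal helpers, oriented pair: %s, score %.2f\n",
              x$region_id, x$span_start, x$span_end,
              sum(x$hits$motif == "HELPER"), sum(x$hits$motif == "HMG"),
              x$topology, x$n_proximal_helpers, x$oriented_pair,
              x$aggregate_score))
  invisible(x)
}

#' Classify cluster topology
#'
#' `HMG_BETWEEN_HELPERS` when some HMG hit has at least one Helper hit
#' strictly before and one strictly after it (by start position) within the
#' cluster — the arrangement found in validated WREs — else `OTHER`.
#'
#' @param cluster A `wre_cluster` from [find_clusters()].
#' @return `"HMG_BETWEEN_HELPERS"` or `"OTHER"`.
#' @export
classify_topology <- function(cluster) {
  hits <- cluster$hits
  helper <- hits$start[hits$motif == "HELPER"]
  hmg <- hits$start[hits$motif == "HMG"]
  between <- any(vapply(hmg, function(h) {
    any(helper < h) && any(helper > h)
  }, logical(1)))
  if (between) "HMG_BETWEEN_HELPERS" else "OTHER"
}

#' Count Helper sites proximal to the best-served HMG site
#'
#' Maximum over the cluster's HMG hits of the number of distinct Helper
#' sites whose start lies within `radius` bp of the HMG start.
#'
#' @param cluster A `wre_cluster`.
#' @param radius Distance in bp (default 50).
#' @return Integer count.
#' @export
count_proximal_helpers <- function(cluster, radius = 50L) {
  hits <- cluster$hits
  helper <- hits[hits$motif == "HELPER", , drop = FALSE]
  hmg <- hits$start[hits$motif == "HMG"]
  if (length(hmg) == 0L) stopf("cluster has no HMG hit")
  helper_starts <- collapse_helper_starts(helper)
  if (length(helper_starts) == 0L) return(0L)
  max(vapply(hmg, function(h)
    sum(abs(helper_starts - h) <= radius), integer(1)))
}

#' Detect an oriented HMG-Helper pair
#'
#' Tests whether some HMG/Helper hit pair within `window` bp shows the
#' configured relative arrangement. Order is evaluated in the reading
#' direction of the HMG hit (downstream of a minus-strand HMG hit means a
#' smaller region-local start), so the predicate is invariant under
#' reverse-complementing the region.
#'
#' @param cluster A `wre_cluster`.
#' @param orientation List with `order` (one of `"helper_downstream"`,
#'   `"helper_upstream"`, `"any"`) and `same_strand` (TRUE/FALSE/NA for
#'   either). The default is the configuration of the optimal synthetic
#'   HMG-Helper pair: Helper downstream of the HMG site on the same strand.
#' @param window Maximum start-to-start distance in bp.
#' @return Logical.
#' @export
detect_oriented_pair <- function(cluster,
                                 orientation = list(order = "helper_downstream",
                                                    same_strand = TRUE),
                                 window = 50L) {
  hits <- cluster$hits
  helper <- hits[hits$motif == "HELPER", , drop = FALSE]
  hmg <- hits[hits$motif == "HMG", , drop = FALSE]
  if (nrow(helper) == 0L || nrow(hmg) == 0L) return(FALSE)
  for (i in seq_len(nrow(hmg))) {
    for (j in seq_len(nrow(helper))) {
      if (abs(helper$start[j] - hmg$start[i]) > window) next
      if (isTRUE(orientation$same_strand) &&
          helper$strand[j] != hmg$strand[i]) next
      if (isFALSE(orientation$same_strand) &&
          helper$strand[j] == hmg$strand[i]) next
      downstream <- if (hmg$strand[i] == "+") {
        helper$start[j] > hmg$start[i]
      } else {
        helper$start[j] < hmg$start[i]
      }
      ok <- switch(orientation$order,
                   helper_downstream = downstream,
                   helper_upstream = !downstream,
                   any = TRUE,
                   stopf("unknown orientation order '%s'", orientation$order))
      if (ok) return(TRUE)
    }
  }
  FALSE
}

#' Rank clusters and build the candidate report table
#'
#' One row per cluster, sorted with `HMG_BETWEEN_HELPERS` topology first,
#' then by proximal-Helper count and aggregate score (both descending).
#' When a region table is supplied, genomic span coordinates are added.
#'
#' @param clusters List of `wre_cluster` objects (possibly from many regions).
#' @param regions Optional [extract_upstream()] frame for genomic coordinates.
#' @param path Optional TSV output path.
#' @return The report data.frame (invisibly when `path` is given).
#' @export
rank_and_report <- function(clusters, regions = NULL, path = NULL) {
  cols <- c("region_id", "span_start", "span_end", "chrom", "genomic_start",
            "genomic_end", "n_helpers", "n_hmg", "topology",
            "n_proximal_helpers", "oriented_pair", "aggregate_score", "hits")
  if (length(clusters) == 0L) {
    report <- as.data.frame(setNames(
      list(character(), integer(), integer(), character(), integer(),
           integer(), integer(), integer(), character(), integer(),
           logical(), numeric(), character()), cols))
  } else {
    rows <- lapply(clusters, function(cl) {
      g <- list(chrom = NA_character_, gs = NA_integer_, ge = NA_integer_)
      if (!is.null(regions)) {
        r <- regions[match(cl$region_id, regions$region_id), ]
        if (nrow(r) == 1L && !is.na(r$chrom)) {
          g1 <- region_to_genomic(r, cl$span_start)
          g2 <- region_to_genomic(r, cl$span_end)
          g <- list(chrom = r$chrom, gs = min(g1, g2), ge = max(g1, g2))
        }
      }
      data.frame(
        region_id = cl$region_id, span_start = cl$span_start,
        span_end = cl$span_end, chrom = g$chrom, genomic_start = g$gs,
        genomic_end = g$ge,
        n_helpers = sum(cl$hits$motif == "HELPER"),
        n_hmg = sum(cl$hits$motif == "HMG"),
        topology = cl$topology,
        n_proximal_helpers = cl$n_proximal_helpers,
        oriented_pair = cl$oriented_pair,
        aggregate_score = cl$aggregate_score,
        hits = paste(sprintf("%s@%d(%s)%.2f", cl$hits$motif, cl$hits$start,
                             cl$hits$strand, cl$hits$score), collapse = ";"),
        stringsAsFactors = FALSE)
    })
    report <- do.call(rbind, rows)
    report <- report[order(report$topology != "HMG_BETWEEN_HELPERS",
                           -report$n_proximal_helpers,
                           -report$aggregate_score), , drop = FALSE]
    rownames(report) <- NULL
  }
  if (!is.null(path)) {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(report))
  }
  report
}
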