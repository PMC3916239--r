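# Seeded generators for fully specified synthetic inputs: background
# genomes with planted HMG-Helper clusters plus exact truth annotations,
# and defecation-cycle interval series with group-specific means, SDs and
# missed-expulsion probabilities.

#' Sample a site from the base distribution implied by a PWM
#'
#' Draws each position independently from the pseudocounted base frequencies
#' the additive weights encode (`p[b] ~ background[b] * 2^weight[b]`),
#' rejection-sampling until the drawn word rescores at or above `min_score`.
#' After `max_tries` rejections the PWM consensus word is returned, so the
#' sampler always terminates.
#'
#' @param pwm A [build_pwm()] object.
#' @param min_score Minimum additive score of the returned word; must not
#'   exceed [pwm_max_score()].
#' @param max_tries Rejection bound before falling back to the consensus.
#' @return A DNA string of width `pwm$width`.
#' @export
sample_site <- function(pwm, min_score = -Inf, max_tries = 1000L) {
  if (min_score > pwm_max_score(pwm)) {
    stopf("min_score %.3f exceeds the maximum attainable score %.3f",
          min_score, pwm_max_score(pwm))
  }
  probs <- sweep(2^pwm$weights, 2, pwm$background, `*`)
  probs[!is.finite(probs)] <- 0
  probs <- probs / rowSums(probs)
  for (tries in seq_len(max_tries)) {
    codes <- vapply(seq_len(pwm$width), function(i)
      sample.int(4L, 1L, prob = probs[i, ]), integer(1))
    word <- paste(DNA_BASES[codes], collapse = "")
    if (score_at(pwm, word, 1L, "+") >= min_score) return(word)
  }
  pwm_consensus(pwm)
}

#' Specification for a planted-cluster synthetic genome
#'
#' @param n_regions Number of regions to generate.
#' @param region_length Region length in bp (default 500, the upstream
#'   search length).
#' @param cluster_fraction Fraction of regions receiving a planted cluster.
#' @param topology Planted arrangement: `"HMG_BETWEEN_HELPERS"` (Helpers
#'   split around the HMG site), `"OTHER"` (all Helpers upstream of the
#'   HMG), or `"MIXED"` (regions alternate).
#' @param helper_count Helper sites per planted cluster (>= 2).
#' @param spacing Integer range (min, max) of the gap in bp between
#'   consecutive planted sites.
#' @param background Background base composition (A,C,G,T); uniform default.
#' @param seed Integer seed; generation is byte-reproducible given the spec.
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(n_regions, region_length = 500L, cluster_fraction = 1,
                       topology = c("HMG_BETWEEN_HELPERS", "OTHER", "MIXED"),
                       helper_count = 2L, spacing = c(5L, 15L),
                       background = rep(0.25, 4), seed = 1L) {
  topology <- match.arg(topology)
  if (cluster_fraction < 0 || cluster_fraction > 1) {
    stopf("cluster_fraction must lie in [0, 1]")
  }
  if (helper_count < 2L) stopf("helper_count must be >= 2")
  if (length(spacing) != 2L || spacing[1] < 0L || spacing[2] < spacing[1]) {
    stopf("spacing must be a non-negative (min, max) range")
  }
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9) {
    stopf("background must be 4 positive frequencies summing to 1")
  }
  structure(
    list(n_regions = as.integer(n_regions),
         region_length = as.integer(region_length),
         cluster_fraction = cluster_fraction, topology = topology,
         helper_count = as.integer(helper_count),
         spacing = as.integer(spacing), background = background,
         seed = as.integer(seed)),
    class = "plant_spec"
  )
}

# Site order of one planted cluster for a topology.
planted_layout <- function(topology, helper_count) {
  if (topology == "HMG_BETWEEN_HELPERS") {
    n_before <- ceiling(helper_count / 2)
    c(rep("HELPER", n_before), "HMG", rep("HELPER", helper_count - n_before))
  } else {
    c(rep("HELPER", helper_count), "HMG")
  }
}

#' Generate a synthetic genome with planted HMG-Helper clusters
#'
#' Regions are i.i.d. background DNA of the spec's composition; a
#' `cluster_fraction` subset additionally carries `helper_count` Helper
#' instances and one HMG instance, sampled from the matrices at
#' `min_score = cutoff + min_score_margin`, placed left to right with gaps
#' drawn from the spacing range. Planted sites never overlap. Truth records
#' give the exact planted coordinates and strands. Identical specs produce
#' byte-identical output.
#'
#' @param spec A [plant_spec()].
#' @param hmg_pwm,helper_pwm Matrices with finite cutoffs, e.g. from
#'   [default_pwms()].
#' @param min_score_margin Added to each cutoff when sampling site words.
#' @param fasta,bed,tsv Optional output paths (region FASTA, truth BED6,
#'   truth TSV).
#' @return List with `regions` (named character vector of sequences),
#'   `truth` (data.frame: `region_id`, `motif`, `start`, `end`, `strand`,
#'   `site`) and `spec`.
#' @examples
#' pw <- default_pwms()
#' g <- plant_genome(plant_spec(3, seed = 7), pw$hmg, pw$helper)
#' nrow(g$truth)  # 3 regions x (2 Helpers + 1 HMG)
#' @export
plant_genome <- function(spec, hmg_pwm, helper_pwm, min_score_margin = 1,
                         fasta = NULL, bed = NULL, tsv = NULL) {
  layout <- planted_layout(
    if (spec$topology == "MIXED") "HMG_BETWEEN_HELPERS" else spec$topology,
    spec$helper_count)
  widths <- ifelse(layout == "HMG", hmg_pwm$width, helper_pwm$width)
  max_span <- sum(widths) + (length(widths) - 1L) * spec$spacing[2]
  if (max_span > spec$region_length) {
    stopf("region_length %d too short for the requested layout (up to %d bp)",
          spec$region_length, max_span)
  }
  with_seed(spec$seed, {
    n_planted <- round(spec$cluster_fraction * spec$n_regions)
    planted <- seq_len(spec$n_regions) <= n_planted
    regions <- character(spec$n_regions)
    truth <- list()
    for (r in seq_len(spec$n_regions)) {
      bg <- paste(sample(DNA_BASES, spec$region_length, replace = TRUE,
                         prob = spec$background), collapse = "")
      if (planted[r]) {
        topo <- if (spec$topology == "MIXED") {
          if (r %% 2L == 1L) "HMG_BETWEEN_HELPERS" else "OTHER"
        } else spec$topology
        lay <- planted_layout(topo, spec$helper_count)
        w <- ifelse(lay == "HMG", hmg_pwm$width, helper_pwm$width)
        gaps <- spec$spacing[1] - 1L +
          sample.int(spec$spacing[2] - spec$spacing[1] + 1L,
                     length(lay) - 1L, replace = TRUE)
        span <- sum(w) + sum(gaps)
        offset <- sample.int(spec$region_length - span + 1L, 1L)
        pos <- offset + cumsum(c(0L, (w + c(gaps, 0L))[-length(w)]))
        seq_chars <- strsplit(bg, "", fixed = TRUE)[[1]]
        for (k in seq_along(lay)) {
          pwm <- if (lay[k] == "HMG") hmg_pwm else helper_pwm
          word <- sample_site(pwm, min_score = pwm$cutoff + min_score_margin)
          substr_idx <- pos[k]:(pos[k] + w[k] - 1L)
          seq_chars[substr_idx] <- strsplit(word, "", fixed = TRUE)[[1]]
          truth[[length(truth) + 1L]] <- data.frame(
            region_id = sprintf("synthetic_region_%03d", r),
            motif = lay[k], start = pos[k], end = pos[k] + w[k] - 1L,
            strand = "+", site = word, stringsAsFactors = FALSE)
        }
        bg <- paste(seq_chars, collapse = "")
      }
      regions[r] <- bg
    }
    names(regions) <- sprintf("synthetic_region_%03d", seq_len(spec$n_regions))
    truth <- if (length(truth) > 0L) do.call(rbind, truth) else
      data.frame(region_id = character(), motif = character(),
                 start = integer(), end = integer(), strand = character(),
                 site = character(), stringsAsFactors = FALSE)
    out <- list(regions = regions, truth = truth, spec = spec)
    if (!is.null(fasta)) {
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(regions), fasta)
    }
    if (!is.null(bed)) {
      write_bed(data.frame(chrom = truth$region_id, start = truth$start,
                           end = truth$end, name = truth$motif, score = 1000,
                           strand = truth$strand, stringsAsFactors = FALSE),
                bed, track_name = "planted_truth", max_score = 1000)
    }
    if (!is.null(tsv)) {
      utils::write.table(truth, tsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    out
  })
}

#' Specification for a simulated defecation assay
#'
#' @param groups List of group specs, each a list with `label`, `n_animals`,
#'   `mean_period` and `sd_period` (seconds), optional `n_cycles` (default
#'   8, the standard scoring of eight consecutive cycles per animal) and
#'   `missed_expulsion_prob`.
#' @param seed Integer seed.
#' @return An object of class `defecation_sim_spec`.
#' @seealso [table1_sim_spec()] for the published genotype parameters.
#' @export
defecation_spec <- function(groups, seed = 1L) {
  groups <- lapply(groups, function(g) {
    g$n_cycles <- if (is.null(g$n_cycles)) 8L else as.integer(g$n_cycles)
    g$missed_expulsion_prob <-
      if (is.null(g$missed_expulsion_prob)) 0 else g$missed_expulsion_prob
    stopifnot(g$n_cycles >= 1L, g$sd_period >= 0,
              g$missed_expulsion_prob >= 0, g$missed_expulsion_prob <= 1)
    g
  })
  structure(list(groups = groups, seed = as.integer(seed)),
            class = "defecation_sim_spec")
}

#' Simulate per-animal defecation interval series
#'
#' Each animal contributes `n_cycles` cycle lengths (the interval between
#' consecutive pBocs) drawn from a normal distribution truncated at zero
#' (non-positive draws are resampled: periods are physical durations), and
#' per cycle a Bernoulli missed-expulsion flag.
#'
#' @param spec A [defecation_spec()].
#' @return Data.frame with `group`, `animal_id`, `cycle`, `period_s`,
#'   `expelled` (logical), one row per observed cycle.
#' @export
simulate_defecation <- function(spec) {
  with_seed(spec$seed, {
    rows <- lapply(spec$groups, function(g) {
      do.call(rbind, lapply(seq_len(g$n_animals), function(a) {
        periods <- numeric(g$n_cycles)
        for (i in seq_len(g$n_cycles)) {
          p <- stats::rnorm(1, g$mean_period, g$sd_period)
          while (p <= 0) p <- stats::rnorm(1, g$mean_period, g$sd_period)
          periods[i] <- p
        }
        data.frame(group = g$label,
                   animal_id = sprintf("%s_animal_%02d", g$label, a),
                   cycle = seq_len(g$n_cycles), period_s = periods,
                   expelled = stats::runif(g$n_cycles) >= g$missed_expulsion_prob,
                   stringsAsFactors = FALSE)
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
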