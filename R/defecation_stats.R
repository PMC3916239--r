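# Group summaries of defecation-cycle interval series: per-animal means
# first, then group statistics over those means; percent change versus
# control; missed-expulsion rates; Student's two-tailed t test.

#' Per-animal mean cycle lengths
#'
#' @param series Data.frame with `group`, `animal_id`, `period_s` (and
#'   optionally `expelled`), as produced by [simulate_defecation()] or read
#'   from a TSV of scored cycles.
#' @return Data.frame with `group`, `animal_id`, `n_cycles`, `mean_period`.
#' @export
animal_means <- function(series) {
  sp <- split(series, list(series$group, series$animal_id), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(group = d$group[1], animal_id = d$animal_id[1],
               n_cycles = nrow(d), mean_period = mean(d$period_s),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$group, out$animal_id), , drop = FALSE]
}

#' Summarize one group of interval series
#'
#' Animal means are computed first; the group mean, sample SD (n-1),
#' median and quartiles (linear interpolation) are taken over those
#' per-animal means. The missed-expulsion percentage is
#' `100 * missed / total_pbocs`.
#'
#' @param series Data.frame of scored cycles for a single group (columns
#'   `group`, `animal_id`, `period_s`, `expelled`).
#' @return One-row data.frame: `group`, `n_animals`, `mean_period`,
#'   `sd_period`, `median`, `q1`, `q3`, `min`, `max`, `total_pbocs`,
#'   `pct_missed`.
#' @examples
#' s <- data.frame(group = "g", animal_id = rep(c("a", "b", "c"), each = 2),
#'                 period_s = c(10, 10, 20, 20, 30, 30), expelled = TRUE)
#' summarize_group(s)  # mean 20, SD 10
#' @export
summarize_group <- function(series) {
  if (nrow(series) == 0L) stopf("empty group")
  if (length(unique(series$group)) != 1L) {
    stopf("summarize_group expects a single group; see summarize_groups()")
  }
  am <- animal_means(series)$mean_period
  expelled <- if ("expelled" %in% names(series)) series$expelled else
    rep(TRUE, nrow(series))
  q <- stats::quantile(am, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(
    group = series$group[1],
    n_animals = length(am),
    mean_period = mean(am),
    sd_period = if (length(am) > 1L) stats::sd(am) else 0,
    median = q[2], q1 = q[1], q3 = q[3],
    min = min(am), max = max(am),
    total_pbocs = nrow(series),
    pct_missed = 100 * sum(!expelled) / nrow(series),
    stringsAsFactors = FALSE
  )
}

#' @rdname summarize_group
#' @details `summarize_groups()` applies [summarize_group()] per group and
#'   binds the rows, mirroring a one-row-per-genotype summary table.
#' @export
summarize_groups <- function(series) {
  out <- do.call(rbind, lapply(split(series, series$group), summarize_group))
  rownames(out) <- NULL
  out
}

#' Percent change in mean cycle period versus control
#'
#' `100 * (treated - control) / control`, rounded half away from zero to
#' one decimal as conventionally reported.
#'
#' @param treated,control Either [summarize_group()] rows or bare numeric
#'   group means.
#' @return Numeric percent, one decimal.
#' @examples
#' percent_change(92.4, 67.5)  # 36.9
#' @export
percent_change <- function(treated, control) {
  tm <- if (is.data.frame(treated)) treated$mean_period else as.numeric(treated)
  cm <- if (is.data.frame(control)) control$mean_period else as.numeric(control)
  if (cm == 0) stopf("control mean is zero")
  round_half_away(100 * (tm - cm) / cm, 1L)
}

#' Student's two-tailed two-sample t test
#'
#' Classical pooled-variance Student's t on two samples of per-animal mean
#' periods, with the two-tailed p-value from the t distribution on
#' `n1 + n2 - 2` degrees of freedom. With zero pooled variance, equal means
#' give `p = 1` by convention and unequal means are an error (degenerate
#' input). A Welch variant is available via `var_equal = FALSE`.
#'
#' @param treated,control Numeric vectors (each of length >= 2).
#' @param var_equal Pool variances (Student's test, default) or not (Welch).
#' @return List with `t`, `df`, `p`.
#' @export
two_tailed_t <- function(treated, control, var_equal = TRUE) {
  if (length(treated) < 2L || length(control) < 2L) {
    stopf("each sample needs at least 2 observations")
  }
  if (stats::var(treated) == 0 && stats::var(control) == 0) {
    if (isTRUE(all.equal(mean(treated), mean(control)))) {
      return(list(t = 0, df = length(treated) + length(control) - 2L, p = 1))
    }
    stopf("zero pooled variance with unequal means: t statistic undefined")
  }
  fit <- stats::t.test(treated, control, var.equal = var_equal,
                       alternative = "two.sided")
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Published defecation assay group parameters
#'
#' The printed per-genotype defecation summary used as simulation input and
#' for the percent-change arithmetic: animals per group, mean and SD of the
#' pBoc period (seconds), total pBocs observed and percent missed
#' expulsions.
#'
#' @return Data.frame with columns `strain`, `n`, `mean_period`,
#'   `sd_period`, `total_pbocs`, `pct_missed`.
#' @export
table1_groups <- function() {
  data.frame(
    strain = c("N2", "pop-1(hu9)", "pop-1(q645)", "N2 (ctrl RNAi)",
               "N2 (pop-1 RNAi)", "OLB11 (ctrl RNAi)", "OLB11 (pop-1 RNAi)"),
    n = c(26L, 26L, 26L, 12L, 12L, 24L, 24L),
    mean_period = c(36.4, 40.6, 42.9, 49.8, 54.2, 67.5, 92.4),
    sd_period = c(3.5, 6.1, 10.8, 3.4, 5.1, 10.8, 49.5),
    total_pbocs = c(208L, 208L, 208L, 96L, 96L, 192L, 192L),
    pct_missed = c(0.0, 0.0, 6.7, 0.0, 0.0, 1.0, 13.0),
    stringsAsFactors = FALSE
  )
}

#' Simulation spec matching the published genotype parameters
#'
#' Builds a [defecation_spec()] whose groups reproduce the published assay
#' design: each animal scored for eight consecutive cycles, group sizes,
#' period means/SDs and missed-expulsion rates as printed.
#'
#' @param seed Integer seed.
#' @param strains Subset of strain labels (default all).
#' @return A [defecation_spec()].
#' @export
table1_sim_spec <- function(seed = 1L, strains = NULL) {
  tab <- table1_groups()
  if (!is.null(strains)) tab <- tab[tab$strain %in% strains, , drop = FALSE]
  groups <- lapply(seq_len(nrow(tab)), function(i) {
    list(label = tab$strain[i], n_animals = tab$n[i], n_cycles = 8L,
         mean_period = tab$mean_period[i], sd_period = tab$sd_period[i],
         missed_expulsion_prob = tab$pct_missed[i] / 100)
  })
  defecation_spec(groups, seed = seed)
}
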