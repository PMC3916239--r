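#' Aligned binding-site set
#'
#' Container for an alignment of equal-length functional binding sites used
#' to build a position weight matrix or derive an IUPAC consensus. Sites must
#' be over the strict ACGT alphabet; sequences are upper-cased on input.
#'
#' @param sites Character vector of equal-length DNA strings (ACGT only).
#' @param motif Motif kind, `"HMG"` or `"HELPER"`.
#' @param labels Optional provenance labels, recycled to `length(sites)`.
#' @return An object of class `site_set` with elements `motif`, `sites`,
#'   `labels` and `width`.
#' @examples
#' site_set(c("GCCGAAA", "GCCAACT"), motif = "HELPER")
#' @export
site_set <- function(sites, motif = c("HELPER", "HMG"), labels = NULL) {
  motif <- match.arg(motif)
  sites <- toupper(as_dna_character(sites))
  if (length(sites) == 0L) stopf("site set must contain at least one site")
  widths <- nchar(sites)
  if (length(unique(widths)) != 1L) {
    stopf("ragged site lengths (%s): sites must form a fixed-width alignment",
          paste(unique(widths), collapse = ", "))
  }
  if (widths[1] < 4L) stopf("site width must be at least 4 bp, got %d", widths[1])
  if (any(grepl("[^ACGT]", sites))) {
    stopf("sites must be over the strict ACGT alphabet")
  }
  if (is.null(labels)) labels <- sprintf("%s_site_%d", motif, seq_along(sites))
  labels <- rep_len(as.character(labels), length(sites))
  structure(
    list(motif = motif, sites = sites, labels = labels, width = widths[1]),
    class = "site_set"
  )
}

#' @export
print.site_set <- function(x, ...) {
  cat(sprintf("site_set: %d %s sites, width %d\n",
              length(x$sites), x$motif, x$width))
  for (i in seq_along(x$sites)) cat(sprintf("  %s  %s\n", x$sites[i], x$labels[i]))
  invisible(x)
}

# Per-position base counts of a site set: width x 4 integer matrix.
site_counts <- function(sites) {
  ss <- if (inherits(sites, "site_set")) sites$sites else toupper(sites)
  w <- nchar(ss[1])
  counts <- matrix(0L, nrow = w, ncol = 4L, dimnames = list(NULL, DNA_BASES))
  for (s in ss) {
    codes <- encode_dna(s)
    for (i in seq_len(w)) counts[i, codes[i]] <- counts[i, codes[i]] + 1L
  }
  counts
}

#' Build an additive log-odds position weight matrix
#'
#' Converts an aligned set of functional sites into an additive per-position,
#' per-base score matrix. The weight of base \eqn{b} at position \eqn{i} is
#' \deqn{w_{ib} = \log_2\frac{(n_{ib} + p\,q_b)/(N + p)}{q_b}}
#' where \eqn{n_{ib}} is the observed count, \eqn{N} the number of sites,
#' \eqn{p} the pseudocount and \eqn{q_b} the background frequency. A window
#' scores as the sum of its per-position weights and "fires" when the score
#' reaches the matrix cutoff.
#'
#' With `pseudocount = 0`, bases never observed at a position get weight
#' `-Inf`, so any window containing them can never fire.
#'
#' @param sites A [site_set()] or character vector of aligned sites.
#' @param pseudocount Non-negative pseudocount `p`; default 1.
#' @param background Base frequencies (A,C,G,T) summing to 1; default uniform.
#' @param cutoff Score threshold; `NA` leaves it unset for the caller.
#' @param motif Motif kind; taken from the site set when available.
#' @return An object of class `wre_pwm`: list with `motif`, `width`,
#'   `weights` (width x 4 matrix, columns A,C,G,T), `cutoff`, `background`
#'   and `pseudocount`.
#' @seealso [load_matrix()], [scan_pwm()], [derive_consensus()]
#' @examples
#' pwm <- build_pwm(site_set(c("ACGT", "ACGT", "ACGA")), pseudocount = 1)
#' pwm_max_score(pwm)
#' @export
build_pwm <- function(sites, pseudocount = 1, background = rep(0.25, 4),
                      cutoff = NA_real_, motif = NULL) {
  if (inherits(sites, "site_set")) {
    if (is.null(motif)) motif <- sites$motif
  } else {
    sites <- site_set(sites, motif = if (is.null(motif)) "HELPER" else motif)
    motif <- sites$motif
  }
  if (pseudocount < 0) stopf("pseudocount must be non-negative")
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0)) {
    stopf("background must be 4 strictly positive frequencies (A,C,G,T)")
  }
  if (abs(sum(background) - 1) > 1e-9) stopf("background must sum to 1")
  counts <- site_counts(sites)
  n <- length(sites$sites)
  freq <- sweep(counts, 2, pseudocount * background, `+`) / (n + pseudocount)
  weights <- log2(sweep(freq, 2, background, `/`))  # -Inf when count 0, p 0
  new_pwm(motif, weights, cutoff, background, pseudocount)
}

new_pwm <- function(motif, weights, cutoff, background, pseudocount = NA_real_) {
  colnames(weights) <- DNA_BASES
  pwm <- structure(
    list(motif = motif, width = nrow(weights), weights = weights,
         cutoff = cutoff, background = background, pseudocount = pseudocount),
    class = "wre_pwm"
  )
  validate_pwm(pwm)
}

validate_pwm <- function(pwm) {
  if (pwm$width != nrow(pwm$weights)) stopf("PWM width/weights mismatch")
  if (!is.na(pwm$cutoff) && pwm_max_score(pwm) < pwm$cutoff) {
    stopf("PWM cutoff %.3f exceeds the maximum attainable score %.3f: the matrix can never fire",
          pwm$cutoff, pwm_max_score(pwm))
  }
  pwm
}

#' @export
print.wre_pwm <- function(x, ...) {
  cat(sprintf("wre_pwm: %s, width %d, cutoff %s, max score %.3f\n",
              x$motif, x$width,
              ifelse(is.na(x$cutoff), "<unset>", format(x$cutoff)),
              pwm_max_score(x)))
  print(round(x$weights, 3))
  invisible(x)
}

#' Maximum attainable score of a PWM
#'
#' Sum of the per-position row maxima; the score of the consensus window.
#' @param pwm A [build_pwm()] object.
#' @return Numeric scalar.
#' @export
pwm_max_score <- function(pwm) sum(apply(pwm$weights, 1, max))

#' Consensus word of a PWM (per-position argmax)
#'
#' Ties break toward the alphabetically first base for determinism.
#' @param pwm A [build_pwm()] object.
#' @return A character string of length `pwm$width`.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$weights, 1, which.max)], collapse = "")
}

#' Score one window of a sequence
#'
#' Additive PWM score of the window of width `pwm$width` starting at the
#' 1-based position `start`. On the minus strand the reverse complement of
#' the window is scored. Windows containing any non-ACGT base (e.g. N)
#' score `-Inf` and can never fire.
#'
#' @param pwm A [build_pwm()] object.
#' @param seq DNA string (ACGTN).
#' @param start 1-based window start within `seq`.
#' @param strand `"+"` or `"-"`.
#' @return Numeric score.
#' @export
score_at <- function(pwm, seq, start, strand = c("+", "-")) {
  strand <- match.arg(strand)
  seq <- as_dna_character(seq)
  w <- pwm$width
  if (start < 1L || start + w - 1L > nchar(seq)) {
    stopf("window [%d, %d] out of range for sequence of length %d",
          start, start + w - 1L, nchar(seq))
  }
  window <- substr(seq, start, start + w - 1L)
  if (strand == "-") window <- revcomp(window)
  codes <- encode_dna(window)
  if (anyNA(codes)) return(-Inf)
  sum(pwm$weights[cbind(seq_len(w), codes)])
}

# Sliding-window scores of `weights` against integer codes; NA codes
# propagate to -Inf. Returns one score per window start.
slide_scores <- function(weights, codes) {
  w <- nrow(weights)
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric(0))
  scores <- numeric(n)
  bad <- logical(n)
  for (i in seq_len(w)) {
    ci <- codes[i:(i + n - 1L)]
    miss <- is.na(ci)
    bad <- bad | miss
    ci[miss] <- 1L
    scores <- scores + weights[i, ci]
  }
  scores[bad] <- -Inf
  scores
}

# Weight matrix that scores the reverse complement of a window read on the
# plus strand: rcw[i, b] = w[width - i + 1, complement(b)].
rc_weights <- function(weights) {
  weights[rev(seq_len(nrow(weights))), c(4L, 3L, 2L, 1L), drop = FALSE]
}

#' Scan a sequence for motif hits on both strands
#'
#' Reports all and only the windows whose additive score reaches the matrix
#' cutoff on either strand. Hit positions are 1-based window starts within
#' the region (the region-local convention in which position 1 of a 500-bp
#' upstream region is -500 from the anchor). Hits are ordered by start, then
#' `+` before `-`, then score descending.
#'
#' @param pwm A [build_pwm()] object with a finite `cutoff`.
#' @param seq DNA string, or a single row of an [extract_upstream()] frame.
#' @param region_id Identifier copied into the output.
#' @param cutoff Optional cutoff override.
#' @return A data.frame with columns `motif`, `region_id`, `start`, `strand`,
#'   `score`, `width` (zero rows when nothing fires).
#' @examples
#' pwm <- build_pwm(c("ACGTA", "ACGTA"), cutoff = 3)
#' scan_pwm(pwm, "TTACGTATT")
#' @export
scan_pwm <- function(pwm, seq, region_id = "region", cutoff = NULL) {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1L)
    region_id <- seq$region_id
    seq <- seq$sequence
  }
  seq <- as_dna_character(seq)
  if (is.null(cutoff)) cutoff <- pwm$cutoff
  if (is.na(cutoff)) stopf("PWM has no cutoff; supply one to scan")
  codes <- encode_dna(seq)
  plus <- slide_scores(pwm$weights, codes)
  minus <- slide_scores(rc_weights(pwm$weights), codes)
  hit_p <- which(plus >= cutoff)
  hit_m <- which(minus >= cutoff)
  n_hits <- length(hit_p) + length(hit_m)
  hits <- data.frame(
    motif = rep(pwm$motif, n_hits),
    region_id = rep(region_id, n_hits),
    start = as.integer(c(hit_p, hit_m)),
    strand = c(rep("+", length(hit_p)), rep("-", length(hit_m))),
    score = c(plus[hit_p], minus[hit_m]),
    width = rep(pwm$width, n_hits),
    stringsAsFactors = FALSE
  )
  hits[order(hits$start, hits$strand, -hits$score), , drop = FALSE]
}

IUPAC_FROM_SET <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S", "CT" = "Y", "GT" = "K",
  "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B", "ACGT" = "N"
)

#' Derive an IUPAC consensus from aligned sites
#'
#' Per position, all bases whose count fraction reaches `majority_fraction`
#' are collected and encoded as the smallest covering IUPAC letter; positions
#' where more than `max_letters` bases qualify collapse to the fully
#' degenerate lower-case `n`. The defaults (any observed base counts, at most
#' two letters per code) recover a consensus of the GCCRAnW form from eight
#' aligned Helper sites.
#'
#' @param sites A [site_set()] or character vector of aligned sites.
#' @param majority_fraction Minimum count fraction for a base to qualify.
#' @param max_letters Maximum qualifying bases before collapsing to `n`.
#' @return An object of class `consensus_model`: list with `iupac`,
#'   `per_position_counts` and `rule`.
#' @examples
#' derive_consensus(c("AAAA", "CCCC", "GGGG", "TTTT"))$iupac  # "nnnn"
#' @export
derive_consensus <- function(sites, majority_fraction = 1 / 8, max_letters = 2L) {
  if (!inherits(sites, "site_set")) sites <- site_set(sites)
  counts <- site_counts(sites)
  n <- length(sites$sites)
  iupac <- vapply(seq_len(nrow(counts)), function(i) {
    qual <- DNA_BASES[counts[i, ] > 0 & counts[i, ] / n >= majority_fraction]
    if (length(qual) > max_letters) "n"
    else IUPAC_FROM_SET[[paste(qual, collapse = "")]]
  }, character(1))
  structure(
    list(iupac = paste(iupac, collapse = ""),
         per_position_counts = counts,
         rule = list(majority_fraction = majority_fraction,
                     max_letters = max_letters)),
    class = "consensus_model"
  )
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf("consensus_model: %s (majority >= %.3g, max %d letters)\n",
              x$iupac, x$rule$majority_fraction, x$rule$max_letters))
  invisible(x)
}
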