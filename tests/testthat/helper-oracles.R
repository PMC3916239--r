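# Shared fixtures and independent brute-force oracles. The oracles avoid
# the package's sliding-window and window-merging code paths entirely:
# scoring is per-window lookup, cluster detection is literal enumeration
# of every window.

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(BASES, n, replace = TRUE, prob = prob), collapse = "")
}

brute_revcomp <- function(seq) {
  chars <- rev(strsplit(seq, "", fixed = TRUE)[[1]])
  paste(ifelse(chars %in% BASES, COMP[chars], chars), collapse = "")
}

# Score one window by direct per-position lookup.
brute_score <- function(weights, window) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  idx <- match(chars, BASES)
  if (anyNA(idx)) return(-Inf)
  sum(weights[cbind(seq_along(idx), idx)])
}

# Exhaustive both-strand scan: every offset, every strand.
brute_scan <- function(pwm, seq, cutoff = pwm$cutoff) {
  w <- pwm$width
  n <- nchar(seq)
  rows <- list()
  if (n >= w) {
    for (s in 1:(n - w + 1)) {
      win <- substr(seq, s, s + w - 1)
      for (st in c("+", "-")) {
        sc <- brute_score(pwm$weights,
                          if (st == "+") win else brute_revcomp(win))
        if (sc >= cutoff) {
          rows[[length(rows) + 1]] <-
            data.frame(start = s, strand = st, score = sc)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), strand = character(),
                      score = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand, -out$score), , drop = FALSE]
}

# Literal enumeration of qualifying windows over hit start positions,
# merged into maximal overlapping runs. Returns merged span matrix.
brute_cluster_spans <- function(helper_starts, hmg_starts, window = 50,
                                min_helpers = 2, min_hmg = 1) {
  if (length(helper_starts) == 0 || length(hmg_starts) == 0) {
    return(matrix(numeric(0), ncol = 2))
  }
  all <- c(helper_starts, hmg_starts)
  qual <- c()
  for (s in max(1, min(all) - window + 1):max(all)) {
    nh <- sum(helper_starts >= s & helper_starts <= s + window - 1)
    ng <- sum(hmg_starts >= s & hmg_starts <= s + window - 1)
    if (nh >= min_helpers && ng >= min_hmg) qual <- c(qual, s)
  }
  if (length(qual) == 0) return(matrix(numeric(0), ncol = 2))
  spans <- list()
  run_start <- qual[1]
  prev <- qual[1]
  for (s in qual[-1]) {
    if (s - prev > window - 1) {
      spans[[length(spans) + 1]] <- c(run_start, prev + window - 1)
      run_start <- s
    }
    prev <- s
  }
  spans[[length(spans) + 1]] <- c(run_start, prev + window - 1)
  do.call(rbind, spans)
}

# Small fixed PWMs for unit tests.
toy_helper_pwm <- function() {
  build_pwm(site_set(c("GCCGAAA", "GCCGATA", "GCCAATA"), motif = "HELPER"),
            pseudocount = 1, cutoff = 6)
}

make_hits <- function(motif, starts, strand = "+", score = 10,
                      width = if (motif == "HMG") 9L else 7L,
                      region_id = "r1") {
  if (length(starts) == 0) {
    return(data.frame(motif = character(), region_id = character(),
                      start = integer(), strand = character(),
                      score = numeric(), width = integer()))
  }
  data.frame(motif = motif, region_id = region_id, start = starts,
             strand = rep_len(strand, length(starts)),
             score = rep_len(score, length(starts)),
             width = width, stringsAsFactors = FALSE)
}
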