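# Window-based cluster detection, topology, proximal-Helper counting,
# oriented pairs and the ranked report.

test_that("the 50-bp criterion matches literal window enumeration on examples", {
  cfg <- scan_config()
  # Helpers at 1 and 60, HMG at 30: no single 50-bp stretch holds all three.
  expect_length(find_clusters(make_hits("HELPER", c(1L, 60L)),
                              make_hits("HMG", 30L), cfg), 0L)
  # Helpers at 1 and 40, HMG at 20: one cluster, HMG between Helpers.
  cl <- find_clusters(make_hits("HELPER", c(1L, 40L)),
                      make_hits("HMG", 20L), cfg)
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$topology, "HMG_BETWEEN_HELPERS")
  expect_identical(cl[[1]]$span_start, 1L)
  # No HMG hits: empty regardless of Helper density.
  expect_length(find_clusters(make_hits("HELPER", seq(1L, 91L, by = 10L)),
                              make_hits("HMG", integer(0)), cfg), 0L)
  expect_length(find_clusters(make_hits("HELPER", integer(0)),
                              make_hits("HMG", 10L), cfg), 0L)
})

test_that("cluster spans agree with the brute-force window oracle", {
  cfg <- scan_config()
  withr::with_seed(41, {
    for (i in 1:300) {
      hs <- sort(sample.int(450, sample(0:6, 1)))
      gs <- sort(sample.int(450, sample(0:3, 1)))
      got <- find_clusters(make_hits("HELPER", hs), make_hits("HMG", gs), cfg)
      want <- brute_cluster_spans(hs, gs)
      expect_length(got, nrow(want))
      if (length(got) > 0) {
        # Member hits are exactly the hits inside each merged window union.
        for (k in seq_along(got)) {
          members <- got[[k]]$hits$start
          expect_setequal(members,
                          c(hs[hs >= want[k, 1] & hs <= want[k, 2]],
                            gs[gs >= want[k, 1] & gs <= want[k, 2]]))
        }
      }
    }
  })
})

test_that("relaxing thresholds never removes clusters (monotonicity)", {
  base_cfg <- scan_config()
  withr::with_seed(43, {
    for (i in 1:50) {
      hs <- sort(sample.int(400, 5))
      gs <- sort(sample.int(400, 2))
      n_base <- length(find_clusters(make_hits("HELPER", hs),
                                     make_hits("HMG", gs), base_cfg))
      # Tighter minimum never adds clusters.
      n_tight <- length(find_clusters(make_hits("HELPER", hs),
                                      make_hits("HMG", gs),
                                      scan_config(min_helpers = 3)))
      expect_lte(n_tight, n_base)
      # Wider window never removes them.
      n_wide <- length(find_clusters(make_hits("HELPER", hs),
                                     make_hits("HMG", gs),
                                     scan_config(window = 80)))
      expect_gte(n_wide, n_base)
    }
  })
})

test_that("translating all hits translates cluster spans (shift invariance)", {
  cfg <- scan_config()
  hs <- c(5L, 30L)
  gs <- 18L
  for (k in c(0L, 7L, 113L)) {
    cl <- find_clusters(make_hits("HELPER", hs + k),
                        make_hits("HMG", gs + k), cfg)
    expect_length(cl, 1L)
    expect_identical(cl[[1]]$span_start, 5L + k)
  }
})

test_that("opposite-strand Helper hits at one locus count once", {
  cfg <- scan_config()
  # A palindromic-like site firing on both strands 1 bp apart must not
  # satisfy the two-Helper minimum on its own.
  both <- rbind(make_hits("HELPER", 10L, strand = "+"),
                make_hits("HELPER", 11L, strand = "-"))
  expect_length(find_clusters(both, make_hits("HMG", 20L), cfg), 0L)
  # Distinct loci on opposite strands do count as two sites.
  apart <- rbind(make_hits("HELPER", 10L, strand = "+"),
                 make_hits("HELPER", 30L, strand = "-"))
  expect_length(find_clusters(apart, make_hits("HMG", 20L), cfg), 1L)
})

test_that("topology classification follows the between-Helpers definition", {
  cfg <- scan_config()
  cl <- find_clusters(make_hits("HELPER", c(5L, 45L)),
                      make_hits("HMG", 25L), cfg)[[1]]
  expect_identical(classify_topology(cl), "HMG_BETWEEN_HELPERS")
  cl2 <- find_clusters(make_hits("HELPER", c(5L, 15L)),
                       make_hits("HMG", 40L), cfg)[[1]]
  expect_identical(classify_topology(cl2), "OTHER")
})

test_that("topology is preserved under reverse complement of the region", {
  pw <- default_pwms()
  cfg <- scan_config()
  genome <- plant_genome(plant_spec(6, seed = 99, helper_count = 3,
                                    topology = "MIXED"),
                         pw$hmg, pw$helper)
  for (rid in names(genome$regions)) {
    seq <- genome$regions[[rid]]
    fwd <- find_clusters(scan_pwm(pw$helper, seq), scan_pwm(pw$hmg, seq), cfg)
    rev <- find_clusters(scan_pwm(pw$helper, brute_revcomp(seq)),
                         scan_pwm(pw$hmg, brute_revcomp(seq)), cfg)
    expect_identical(vapply(fwd, classify_topology, character(1)),
                     rev(vapply(rev, classify_topology, character(1))))
  }
})

test_that("proximal-Helper counting respects the 50-bp radius boundary", {
  cfg <- scan_config(window = 200)  # wide window so all hits share a cluster
  cl <- find_clusters(make_hits("HELPER", c(49L, 151L)),
                      make_hits("HMG", 100L), cfg)
  expect_length(cl, 1L)
  # Helpers at exactly HMG +/- 51: outside the 50-bp radius.
  expect_identical(count_proximal_helpers(cl[[1]], radius = 50L), 0L)
  expect_identical(count_proximal_helpers(cl[[1]], radius = 51L), 2L)
  # Single adjacent Helper.
  cl2 <- find_clusters(make_hits("HELPER", c(90L, 180L)),
                       make_hits("HMG", 100L), scan_config(window = 200))
  expect_identical(count_proximal_helpers(cl2[[1]], radius = 50L), 1L)
})

test_that("oriented-pair detection honors order and strand", {
  cfg <- scan_config()
  ref <- list(order = "helper_downstream", same_strand = TRUE)
  cl <- find_clusters(
    rbind(make_hits("HELPER", 22L, strand = "+"),
          make_hits("HELPER", 40L, strand = "-")),
    make_hits("HMG", 10L, strand = "+"), cfg)[[1]]
  expect_true(detect_oriented_pair(cl, ref))
  # Same geometry but the downstream Helper on the minus strand only.
  cl2 <- find_clusters(
    rbind(make_hits("HELPER", 22L, strand = "-"),
          make_hits("HELPER", 40L, strand = "-")),
    make_hits("HMG", 10L, strand = "+"), cfg)[[1]]
  expect_false(detect_oriented_pair(cl2, ref))
  expect_true(detect_oriented_pair(cl2, list(order = "helper_downstream",
                                             same_strand = FALSE)))
  # For a minus-strand HMG hit, downstream means a smaller start.
  cl3 <- find_clusters(
    rbind(make_hits("HELPER", 5L, strand = "-"),
          make_hits("HELPER", 40L, strand = "-")),
    make_hits("HMG", 20L, strand = "-"), cfg)[[1]]
  expect_true(detect_oriented_pair(cl3, ref))
})

test_that("the ranked report sorts topology first and writes a TSV", {
  cfg <- scan_config()
  between <- find_clusters(make_hits("HELPER", c(1L, 40L), score = 6),
                           make_hits("HMG", 20L, score = 7), cfg)
  other <- find_clusters(make_hits("HELPER", c(1L, 10L), score = 20,
                                   region_id = "r2"),
                         make_hits("HMG", 45L, score = 20,
                                   region_id = "r2"), cfg)
  report <- rank_and_report(c(other, between))
  expect_identical(report$topology, c("HMG_BETWEEN_HELPERS", "OTHER"))
  expect_identical(report$region_id, c("r1", "r2"))
  f <- withr::local_tempfile(fileext = ".tsv")
  rank_and_report(c(other, between), path = f)
  tab <- utils::read.delim(f)
  expect_identical(nrow(tab), 2L)
  # Empty cluster list: header-only TSV.
  f2 <- withr::local_tempfile(fileext = ".tsv")
  rank_and_report(list(), path = f2)
  expect_identical(nrow(utils::read.delim(f2)), 0L)
  expect_length(readLines(f2), 1L)
})
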