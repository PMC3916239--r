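# Upstream-region extraction from genome FASTA + GFF3 annotation, and BED
# output. Internal coordinates are 1-based inclusive; BED conversion happens
# only at the output boundary.

#' Extract fixed-length upstream regions for annotated starts
#'
#' For every annotated translational start (TlSS: the first CDS codon of an
#' mRNA) and/or transcriptional start (TSS: the transcript 5' end), extracts
#' the `length`-bp region immediately 5' of the anchor. Sequences are
#' oriented 5' to 3' relative to the gene, so position `length` is -1 from
#' the anchor and position 1 is `-length`; minus-strand regions are
#' reverse-complemented. Regions identical in (chrom, interval, strand) are
#' deduplicated with merged gene labels. Anchors closer than `length` to a
#' contig edge yield truncated regions with a warning, never an error.
#'
#' @param genome A `DNAStringSet` or path to a (multi-)FASTA file. Sequence
#'   names are the first whitespace-delimited word of each header.
#' @param annotation A `GRanges` (as returned by [rtracklayer::import()]) or
#'   path to a GFF3 file with `mRNA` and `CDS` features.
#' @param length Upstream length in bp (default 500).
#' @param anchors Which anchors to emit; both by default, matching a search
#'   over the union of TlSS- and TSS-anchored promoters.
#' @return A data.frame with one row per region: `region_id`, `gene_id`,
#'   `anchor_kind`, `chrom`, `genomic_start`, `genomic_end`, `gene_strand`,
#'   `sequence`, `truncated`.
#' @examples
#' \dontrun{
#' regions <- extract_upstream("genome.fa", "annotation.gff3")
#' }
#' @export
extract_upstream <- function(genome, annotation, length = 500L,
                             anchors = c("TlSS", "TSS")) {
  anchors <- match.arg(anchors, several.ok = TRUE)
  len <- as.integer(length)
  if (len < 0L) stopf("length must be non-negative")
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  if (is.character(annotation)) {
    annotation <- rtracklayer::import(annotation, format = "gff3")
  }
  anchor_tab <- gff_anchors(annotation, anchors)
  if (nrow(anchor_tab) == 0L) {
    return(empty_regions_frame())
  }
  missing_contigs <- setdiff(unique(anchor_tab$chrom), names(genome))
  if (base::length(missing_contigs) > 0L) {
    stopf("contig(s) absent from genome FASTA: %s",
          paste(missing_contigs, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(anchor_tab)), function(i) {
    a <- anchor_tab[i, ]
    clen <- length(genome[[a$chrom]])
    if (a$strand == "+") {
      gs <- a$anchor - len
      ge <- a$anchor - 1L
      trunc <- gs < 1L
      gs <- max(gs, 1L)
      if (ge < gs) { gs <- 1L; ge <- 0L }  # length 0 or anchor at contig start
      seq <- if (ge >= gs) {
        as.character(Biostrings::subseq(genome[[a$chrom]], gs, ge))
      } else ""
    } else {
      gs <- a$anchor + 1L
      ge <- a$anchor + len
      trunc <- ge > clen
      ge <- min(ge, clen)
      if (ge < gs) { gs <- 1L; ge <- 0L }
      seq <- if (ge >= gs) {
        revcomp(as.character(Biostrings::subseq(genome[[a$chrom]], gs, ge)))
      } else ""
    }
    if (len == 0L) trunc <- FALSE
    data.frame(gene_id = a$gene_id, anchor_kind = a$anchor_kind,
               chrom = a$chrom, genomic_start = gs, genomic_end = ge,
               gene_strand = a$strand, sequence = seq, truncated = trunc,
               stringsAsFactors = FALSE)
  })
  regions <- do.call(rbind, rows)
  if (any(regions$truncated)) {
    warnf("%d region(s) truncated at contig edges", sum(regions$truncated))
  }
  # Deduplicate identical intervals, merging gene labels.
  key <- paste(regions$chrom, regions$genomic_start, regions$genomic_end,
               regions$gene_strand, regions$anchor_kind, sep = ":")
  if (anyDuplicated(key)) {
    merged <- tapply(regions$gene_id, key, function(g)
      paste(sort(unique(g)), collapse = ";"))
    regions <- regions[!duplicated(key), , drop = FALSE]
    regions$gene_id <- as.character(merged[paste(
      regions$chrom, regions$genomic_start, regions$genomic_end,
      regions$gene_strand, regions$anchor_kind, sep = ":")])
  }
  regions$region_id <- make.unique(
    paste(regions$gene_id, regions$anchor_kind, sep = "|"), sep = "#")
  rownames(regions) <- NULL
  regions[, c("region_id", "gene_id", "anchor_kind", "chrom", "genomic_start",
              "genomic_end", "gene_strand", "sequence", "truncated")]
}

empty_regions_frame <- function() {
  data.frame(region_id = character(), gene_id = character(),
             anchor_kind = character(), chrom = character(),
             genomic_start = integer(), genomic_end = integer(),
             gene_strand = character(), sequence = character(),
             truncated = logical(), stringsAsFactors = FALSE)
}

# One row per (gene_id, anchor): chrom, anchor genomic position, strand.
gff_anchors <- function(gr, anchors) {
  md <- S4Vectors::mcols(gr)
  feat_id <- function(x) {
    id <- if ("ID" %in% names(S4Vectors::mcols(x))) S4Vectors::mcols(x)$ID else NULL
    nm <- if ("Name" %in% names(S4Vectors::mcols(x))) S4Vectors::mcols(x)$Name else NULL
    out <- id
    if (is.null(out)) out <- nm
    if (is.null(out)) out <- rep(NA_character_, base::length(x))
    out <- as.character(out)
    out[is.na(out)] <- sprintf("feature_%d", which(is.na(out)))
    out
  }
  parent_of <- function(x) {
    if (!"Parent" %in% names(S4Vectors::mcols(x))) {
      return(rep(NA_character_, base::length(x)))
    }
    p <- S4Vectors::mcols(x)$Parent
    vapply(as.list(p), function(v)
      if (base::length(v) == 0L) NA_character_ else as.character(v[[1]]),
      character(1))
  }
  rows <- list()
  mrna <- gr[tolower(as.character(md$type)) %in% c("mrna", "transcript")]
  if ("TSS" %in% anchors && base::length(mrna) > 0L) {
    plus <- as.character(BiocGenerics::strand(mrna)) != "-"
    rows[["tss"]] <- data.frame(
      gene_id = feat_id(mrna),
      anchor_kind = "TSS",
      chrom = as.character(GenomicRanges::seqnames(mrna)),
      anchor = ifelse(plus, BiocGenerics::start(mrna), BiocGenerics::end(mrna)),
      strand = ifelse(plus, "+", "-"),
      stringsAsFactors = FALSE)
  }
  if ("TlSS" %in% anchors) {
    cds <- gr[tolower(as.character(md$type)) == "cds"]
    if (base::length(cds) > 0L) {
      parent <- parent_of(cds)
      parent[is.na(parent)] <- feat_id(cds)[is.na(parent)]
      plus <- as.character(BiocGenerics::strand(cds)) != "-"
      anchor <- ifelse(plus, BiocGenerics::start(cds), BiocGenerics::end(cds))
      first <- tapply(seq_along(cds), parent, function(idx) {
        if (plus[idx[1]]) idx[which.min(anchor[idx])] else idx[which.max(anchor[idx])]
      })
      first <- unlist(first)
      rows[["tlss"]] <- data.frame(
        gene_id = parent[first],
        anchor_kind = "TlSS",
        chrom = as.character(GenomicRanges::seqnames(cds))[first],
        anchor = anchor[first],
        strand = ifelse(plus[first], "+", "-"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(), anchor_kind = character(),
                      chrom = character(), anchor = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Map a region-local position to its genomic coordinate
#'
#' Position `k` (1-based within the extracted sequence) of a plus-strand
#' region maps to `genomic_start + k - 1`; of a minus-strand region to
#' `genomic_end - k + 1`. [genomic_to_region()] is the inverse.
#'
#' @param region One row of an [extract_upstream()] frame.
#' @param k Region-local 1-based position(s).
#' @return Genomic coordinate(s), 1-based.
#' @export
region_to_genomic <- function(region, k) {
  if (region$gene_strand == "+") region$genomic_start + k - 1L
  else region$genomic_end - k + 1L
}

#' @rdname region_to_genomic
#' @param g Genomic coordinate(s), 1-based.
#' @export
genomic_to_region <- function(region, g) {
  if (region$gene_strand == "+") g - region$genomic_start + 1L
  else region$genomic_end - g + 1L
}

#' Write intervals as a 6-column BED file
#'
#' Takes a data.frame of 1-based inclusive intervals (`chrom`, `start`,
#' `end`, `name`, `score`, `strand`) and writes standard BED6 (0-based,
#' half-open) preceded by a track line. Scores are scaled by
#' `1000 / max_score` and clamped to the BED 0-1000 range.
#'
#' @param x Data.frame of intervals as above (zero rows allowed).
#' @param path Output path.
#' @param track_name Name used in the track line.
#' @param max_score Score mapped to 1000; defaults to the largest finite
#'   score in `x` (or 1 when empty).
#' @return `path`, invisibly.
#' @seealso [hits_to_intervals()], [clusters_to_intervals()]
#' @export
write_bed <- function(x, path, track_name = "wrescan", max_score = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf('track name="%s" useScore=1', track_name), con)
  if (nrow(x) == 0L) return(invisible(path))
  if (is.null(max_score)) {
    finite <- x$score[is.finite(x$score)]
    max_score <- if (length(finite) > 0L && max(finite) > 0) max(finite) else 1
  }
  bed_score <- pmax(0L, pmin(1000L, as.integer(round(1000 * x$score / max_score))))
  bed <- data.frame(chrom = x$chrom, start = x$start - 1L, end = x$end,
                    name = x$name, score = bed_score, strand = x$strand)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert motif hits or clusters to genomic BED-ready intervals
#'
#' Maps region-local hit/cluster coordinates onto the genome via the region
#' table and returns the 1-based inclusive interval frame that [write_bed()]
#' consumes. For minus-strand genes the region-local window is flipped onto
#' the plus-strand genomic interval; the BED strand column records the hit
#' strand relative to the genome.
#'
#' @param hits A [scan_pwm()] hit frame.
#' @param regions An [extract_upstream()] frame covering `hits$region_id`.
#' @return Data.frame with `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
hits_to_intervals <- function(hits, regions) {
  if (nrow(hits) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  idx <- match(hits$region_id, regions$region_id)
  if (anyNA(idx)) stopf("hits reference unknown region(s)")
  out <- lapply(seq_len(nrow(hits)), function(i) {
    r <- regions[idx[i], ]
    g1 <- region_to_genomic(r, hits$start[i])
    g2 <- region_to_genomic(r, hits$start[i] + hits$width[i] - 1L)
    gstrand <- if (r$gene_strand == "+") hits$strand[i]
               else c("+" = "-", "-" = "+")[[hits$strand[i]]]
    data.frame(chrom = r$chrom, start = min(g1, g2), end = max(g1, g2),
               name = sprintf("%s_%s", hits$motif[i], hits$region_id[i]),
               score = hits$score[i], strand = gstrand,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @rdname hits_to_intervals
#' @param clusters A list of clusters from [find_clusters()].
#' @export
clusters_to_intervals <- function(clusters, regions) {
  if (length(clusters) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- lapply(clusters, function(cl) {
    r <- regions[match(cl$region_id, regions$region_id), ]
    g1 <- region_to_genomic(r, cl$span_start)
    g2 <- region_to_genomic(r, cl$span_end)
    data.frame(chrom = r$chrom, start = min(g1, g2), end = max(g1, g2),
               name = sprintf("cluster_%s_%s", cl$region_id, cl$topology),
               score = cl$aggregate_score, strand = ".",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
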