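# Quantification: FPKM, gene-locus coverage, abundance bin summaries, and
# read-mapping / alignment-score statistics.

#' Fragments per kilobase of exon per million mapped fragments
#'
#' `count / ((length/1000) * (total/1e6))`.  Vectorized over `count` and
#' `transcript_length_bp`.
#'
#' @param count non-negative fragment count(s).
#' @param transcript_length_bp summed exon length(s) in bp (> 0).
#' @param total_mapped_fragments total mapped fragments in the sample (> 0).
#' @return FPKM value(s); zero exactly where `count` is zero.
#' @examples
#' compute_fpkm(10, 1000, 1e6) # 10
#' @export
compute_fpkm <- function(count, transcript_length_bp, total_mapped_fragments) {
  if (any(transcript_length_bp <= 0)) {
    contract_error("transcript length must be positive")
  }
  if (any(total_mapped_fragments <= 0)) {
    contract_error("total mapped fragments must be positive")
  }
  if (any(count < 0)) contract_error("counts must be non-negative")
  count / ((transcript_length_bp / 1000) * (total_mapped_fragments / 1e6))
}

#' Fraction of a gene locus covered by reads
#'
#' The fraction of locus bases overlapped by at least one read interval
#' (the union of read intervals intersected with the locus).  All
#' coordinates are 0-based half-open; a coverage of 1 means the locus is
#' fully covered.
#'
#' @param locus_start,locus_end locus interval (half-open, `end > start`).
#' @param read_starts,read_ends parallel vectors of read intervals on the
#'   same chromosome.
#' @return coverage in `[0, 1]`.
#' @examples
#' compute_locus_coverage(0, 100, c(0, 20), c(30, 60)) # 0.6
#' @export
compute_locus_coverage <- function(locus_start, locus_end,
                                   read_starts = integer(),
                                   read_ends = integer()) {
  if (locus_end <= locus_start) contract_error("empty gene locus")
  if (length(read_starts) == 0) {
    return(0)
  }
  locus <- IRanges::IRanges(start = locus_start + 1L, end = locus_end)
  reads <- IRanges::reduce(
    IRanges::IRanges(start = read_starts + 1L, end = read_ends)
  )
  covered <- sum(IRanges::width(IRanges::intersect(reads, locus)))
  covered / (locus_end - locus_start)
}

#' Per-gene locus coverage from a read table
#'
#' Convenience wrapper: gene loci are the spans of their exon models and
#' reads a BED-style interval table.
#'
#' @param models exon table.
#' @param reads data frame `chrom`, `start`, `end` (0-based half-open).
#' @return data frame `gene_id`, `coverage`.
#' @export
gene_coverage <- function(models, reads) {
  genes <- unique(models$gene_id)
  out <- vapply(genes, function(g) {
    ex <- models[models$gene_id == g, ]
    r <- reads[reads$chrom == ex$chrom[1], ]
    compute_locus_coverage(min(ex$start), max(ex$end), r$start, r$end)
  }, numeric(1))
  data.frame(gene_id = genes, coverage = unname(out), stringsAsFactors = FALSE)
}

#' Build a three-sample expression table from counts
#'
#' Adds per-sample FPKM columns to a count table using each sample's total
#' mapped fragments as the denominator.
#'
#' @param counts data frame `transcript_id`, `gene_id`, `count_H`,
#'   `count_P1`, `count_P2`.
#' @param models exon table (source of transcript lengths).
#' @return the count table with `length`, `fpkm_H`, `fpkm_P1`, `fpkm_P2`
#'   appended.
#' @export
expression_table <- function(counts, models) {
  tl <- transcript_lengths(models)
  x <- merge(counts, tl[, c("transcript_id", "length")],
    by = "transcript_id", sort = FALSE
  )
  x <- x[match(counts$transcript_id, x$transcript_id), ]
  for (s in c("H", "P1", "P2")) {
    cc <- x[[paste0("count_", s)]]
    total <- sum(cc)
    if (total <= 0) contract_error(sprintf("sample %s has no fragments", s))
    x[[paste0("fpkm_", s)]] <- compute_fpkm(cc, x$length, total)
  }
  rownames(x) <- NULL
  x
}

#' Abundance and coverage bin summary
#'
#' Per-sample detection counts and bins in the layout of the study's
#' abundance table: transcripts/genes detected (`FPKM > 0`), detected in
#' that sample only, low-abundance (`FPKM < 1`) and high-abundance
#' (`FPKM > 100`) transcripts, low (`< 0.2`) and high (`> 0.8`) gene-locus
#' coverage, plus union and intersection sizes across the three samples.
#'
#' @param expression table from [expression_table()].
#' @param coverage optional data frame `gene_id`, `sample`, `coverage`
#'   with `sample` in `H`, `P1`, `P2`.
#' @return list with `transcripts` and `genes` summary data frames (one
#'   row per sample) and `overall` (union/intersection sizes).
#' @export
summarize_abundance <- function(expression, coverage = NULL) {
  samples <- c("H", "P1", "P2")
  fp <- sapply(samples, function(s) expression[[paste0("fpkm_", s)]])
  detected <- fp > 0
  n_det <- colSums(detected)
  unique_t <- colSums(detected & rowSums(detected) == 1)
  lo <- colSums(detected & fp < 1)
  hi <- colSums(fp > 100)
  tr <- data.frame(
    sample = samples, all = n_det, unique = unique_t,
    fpkm_lt1 = lo, fpkm_gt100 = hi, stringsAsFactors = FALSE
  )
  gene_det <- rowsum((detected) * 1, expression$gene_id) > 0
  ng <- colSums(gene_det)
  ug <- colSums(gene_det & rowSums(gene_det) == 1)
  genes <- data.frame(
    sample = samples, all = ng, unique = ug,
    cov_lt0.2 = NA_integer_, cov_gt0.8 = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (!is.null(coverage)) {
    for (i in seq_along(samples)) {
      cv <- coverage$coverage[coverage$sample == samples[i]]
      genes$cov_lt0.2[i] <- sum(cv < 0.2)
      genes$cov_gt0.8[i] <- sum(cv > 0.8)
    }
  }
  overall <- data.frame(
    transcripts_union = sum(rowSums(detected) > 0),
    transcripts_intersection = sum(rowSums(detected) == ncol(detected)),
    genes_union = sum(rowSums(gene_det) > 0),
    genes_intersection = sum(rowSums(gene_det) == ncol(gene_det))
  )
  rownames(tr) <- rownames(genes) <- NULL
  list(transcripts = tr, genes = genes, overall = overall)
}

#' Read alignment score
#'
#' `score = len - nm * (1 + mp) - jp`, with the junction penalty `jp`
#' applied only to reads flagged as junction alignments.  `len` is the
#' number of alignment hits and `nm` the mismatch count.
#'
#' @param len alignment hit count(s).
#' @param nm mismatch count(s).
#' @param mp mapping-mismatch penalty (default 1).
#' @param jp junction-alignment penalty (default 0).
#' @param junction logical flag(s); `jp` is charged where `TRUE`.
#' @return numeric score(s).
#' @examples
#' alignment_score(50, 2, mp = 1) # 46
#' @export
alignment_score <- function(len, nm, mp = 1, jp = 0, junction = FALSE) {
  if (any(len < 0) || any(nm < 0)) contract_error("len and nm must be >= 0")
  if (any(mp < 0) || any(jp < 0)) config_error("mp and jp must be >= 0")
  len - nm * (1 + mp) - ifelse(junction, jp, 0)
}

#' Cumulative score distribution
#'
#' For each threshold `t`, the fraction of scores `>= t` (a survival
#' function, non-increasing in `t`).
#'
#' @param scores non-empty numeric vector.
#' @param thresholds numeric vector of thresholds.
#' @return data frame `threshold`, `fraction`.
#' @export
score_cdf <- function(scores, thresholds) {
  if (length(scores) == 0) contract_error("'scores' is empty")
  data.frame(
    threshold = thresholds,
    fraction = vapply(
      thresholds, function(t) mean(scores >= t), numeric(1)
    )
  )
}

#' Read-mapping statistics
#'
#' Mapping rate (mapped/generated), uniquely-mapping rate (unique/mapped)
#' and total sequenced bases, with rates reported as percentages.
#'
#' @param reads_generated,reads_mapped,reads_unique read counts obeying
#'   `unique <= mapped <= generated`; vectorized over samples.
#' @param read_length read length in bp.
#' @return data frame `reads_generated`, `reads_mapped`, `reads_unique`,
#'   `mapping_rate`, `unique_rate` (percent), `total_bases`.
#' @examples
#' mapping_stats(82479484, 41074430, 31028999)
#' @export
mapping_stats <- function(reads_generated, reads_mapped, reads_unique,
                          read_length = 50) {
  if (any(reads_unique > reads_mapped) ||
    any(reads_mapped > reads_generated) || any(reads_unique < 0)) {
    contract_error(
      "need reads_unique <= reads_mapped <= reads_generated, all >= 0"
    )
  }
  data.frame(
    reads_generated = reads_generated,
    reads_mapped = reads_mapped,
    reads_unique = reads_unique,
    mapping_rate = 100 * reads_mapped / reads_generated,
    unique_rate = 100 * reads_unique / reads_mapped,
    total_bases = reads_generated * read_length
  )
}
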