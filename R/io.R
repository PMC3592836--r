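# Readers/writers at the file-format boundary.  Internally everything is
# 0-based half-open; GTF's 1-based closed convention is converted here.

#' Write transcript models as GTF
#'
#' Emits one `transcript` feature plus one `exon` feature per exon, with
#' `gene_id`/`transcript_id` attributes.  Input coordinates are 0-based
#' half-open and are converted to GTF's 1-based closed convention.
#'
#' @param models exon table (`transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  attr_str <- sprintf(
    "gene_id \"%s\"; transcript_id \"%s\";",
    models$gene_id, models$transcript_id
  )
  exon_lines <- sprintf(
    "%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\t%s",
    models$chrom, models$start + 1L, models$end, models$strand, attr_str
  )
  first <- !duplicated(models$transcript_id)
  t_start <- tapply(models$start, models$transcript_id, min)
  t_end <- tapply(models$end, models$transcript_id, max)
  tid <- models$transcript_id[first]
  tx_lines <- sprintf(
    "%s\tsynthetic\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
    models$chrom[first], as.integer(t_start[tid]) + 1L,
    as.integer(t_end[tid]), models$strand[first], attr_str[first]
  )
  # transcript line first, then its exons, in input transcript order
  ord <- order(match(models$transcript_id, tid), models$start)
  grouped <- split(exon_lines[ord], match(models$transcript_id[ord], tid))
  lines <- unlist(lapply(seq_along(tid), function(i) {
    c(tx_lines[i], grouped[[as.character(i)]])
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read transcript models from GTF
#'
#' Imports a GTF with `rtracklayer` and returns the exon table used
#' throughout the package (0-based half-open coordinates).
#'
#' @param path GTF file.
#' @return data frame `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end`.
#' @export
read_transcript_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  data.frame(
    transcript_id = gr$transcript_id,
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Read BED intervals
#'
#' @param path BED3+ file (0-based half-open, as BED is defined).
#' @return data frame `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path,
    sep = "\t", header = FALSE,
    stringsAsFactors = FALSE
  )[, 1:3]
  names(bed) <- c("chrom", "start", "end")
  bed
}
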