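# Coverage-based accounting of germline sequence complexity and per-element
# (transposon) coverage. RPKM = reads per kb of sequence per million mapped
# library reads; a contig counts as "covered" at >= 2 RPKM, and only contigs
# longer than 1 kb enter the complexity sums.

#' Count primary mapped reads per contig
#'
#' Counts primary alignments (mates counted independently), consistent with
#' the boundary classifier's uniqueness conventions.
#'
#' @param path SAM or BAM file.
#' @param mapq_min Minimum mapping quality (default 0: count all mapped
#'   primaries).
#' @return List with `counts` (named integer, one entry per header contig)
#'   and `total` (mapped primary reads in the library).
#' @export
count_mapped_reads <- function(path, mapq_min = 0L) {
  aln <- read_alignments(path)
  rec <- aln$records
  keep <- !is.na(rec$pos) & !is.na(rec$mapq) & rec$mapq >= mapq_min &
    bitwAnd(rec$flag, 0x4) == 0L &
    bitwAnd(rec$flag, 0x100) == 0L & bitwAnd(rec$flag, 0x800) == 0L
  counts <- table(factor(rec$rname[keep], levels = aln$contigs))
  counts <- stats::setNames(as.integer(counts), aln$contigs)
  list(counts = counts, total = sum(counts))
}

#' Per-contig RPKM records
#'
#' `rpkm = count / (length/1000) / (library_mapped_total/1e6)`.
#'
#' @param counts Named integer vector of mapped read counts per contig.
#' @param lengths Named integer vector of contig lengths (bp).
#' @param library_mapped_total Mapped reads in the library (denominator).
#' @return `data.frame`: `id`, `length`, `count`, `rpkm`.
#' @export
contig_rpkm <- function(counts, lengths, library_mapped_total) {
  if (library_mapped_total <= 0) {
    stop("library_mapped_total must be > 0", call. = FALSE)
  }
  ids <- names(lengths)
  stopifnot(!is.null(ids))
  if (any(lengths <= 0)) {
    stop("zero-length contig(s): ",
         paste(ids[lengths <= 0], collapse = ", "), call. = FALSE)
  }
  cnt <- counts[ids]
  cnt[is.na(cnt)] <- 0L
  data.frame(
    id = ids,
    length = as.integer(lengths),
    count = as.integer(cnt),
    rpkm = as.numeric(cnt) / (lengths / 1000) / (library_mapped_total / 1e6),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Covered sequence complexity in Mb
#'
#' Sums the lengths of contigs longer than `min_len` whose coverage reaches
#' `cutoff` RPKM.
#'
#' @param records Output of [contig_rpkm()].
#' @param cutoff RPKM cutoff (default 2).
#' @param min_len Minimum contig length in bp (default 1000, exclusive).
#' @return Covered complexity in Mb.
#' @export
covered_complexity <- function(records, cutoff = 2, min_len = 1000) {
  sum(records$length[records$length > min_len &
                       records$rpkm >= cutoff]) / 1e6
}

#' Contigs not covered by a control sample
#'
#' Selects contig ids whose control coverage is below the cutoff —
#' germline-specific sequence not collinear with somatic chromosomes.
#'
#' @param control_records [contig_rpkm()] records for the control sample.
#' @param cutoff RPKM cutoff (default 2).
#' @return Character vector of contig ids.
#' @export
subset_not_covered_by <- function(control_records, cutoff = 2) {
  control_records$id[control_records$rpkm < cutoff]
}

#' Per-element coverage (RPKM)
#'
#' Coverage of individual elements (e.g. transposon copies), normalized by
#' an externally supplied library size — conventionally the number of reads
#' the sample maps to the somatic reference genome, not to the element set.
#'
#' @param alignments SAM/BAM of the sample's reads against the element FASTA.
#' @param element_lengths Named integer vector of element lengths.
#' @param library_mapped_total Library-size denominator (reads mapped to the
#'   somatic reference).
#' @return `data.frame` as in [contig_rpkm()].
#' @export
element_coverage <- function(alignments, element_lengths,
                             library_mapped_total) {
  counted <- count_mapped_reads(alignments)
  missing <- setdiff(names(element_lengths), names(counted$counts))
  if (length(missing)) {
    stop("element(s) absent from alignment header: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  contig_rpkm(counted$counts, element_lengths, library_mapped_total)
}

#' One-line complexity report
#'
#' @param records [contig_rpkm()] records.
#' @param reference_name Label for the reference contig set.
#' @param cutoff,min_len As in [covered_complexity()].
#' @return List with the parameters, total and covered Mb.
#' @export
complexity_report <- function(records, reference_name = "reference",
                              cutoff = 2, min_len = 1000) {
  total <- sum(records$length[records$length > min_len]) / 1e6
  covered <- covered_complexity(records, cutoff = cutoff, min_len = min_len)
  stopifnot(covered <= total)
  list(reference = reference_name, cutoff_rpkm = cutoff,
       min_contig_length = min_len, total_mb = total, covered_mb = covered)
}
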