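# Classify uniquely aligned reads at IES boundaries.
#
# On the MAC reference a read supports excision (IES-) when it spans the
# junction TA with `anchor` matched bases around it; on the MAC+IES
# reference a read supports retention (IES+) when it spans the left or right
# IES boundary. Each boundary window mirrors the MAC junction window (the
# boundary TA plus `anchor` flanking bases, 2*anchor + 2 bp in total), so a
# retained and an excised molecule offer the same number of classifiable
# read positions per locus. The per-IES IES+ tally is the average of the two
# boundary tallies: a read spanning both ends of a short IES contributes to
# both boundary tallies and therefore still counts exactly once, and the
# expected RS equals the IES-bearing molecule fraction irrespective of IES
# length ("counted at IES ends" removes length bias).

#' Classifier configuration
#'
#' @param anchor Minimum matched bases required on each side of a boundary.
#'   The default 5 exceeds the 2 bp ambiguity of the shared TA (a read ending
#'   inside the TA cannot distinguish the retained from the excised form).
#' @param mapq_min Minimum mapping quality; aligner-flagged multi-mappers at
#'   MAPQ 0 are excluded by the default of 1.
#' @param require_no_indel Disallow indels inside the boundary window.
#' @return A list of class `ies_classifier_config`.
#' @export
classifier_config <- function(anchor = 5L, mapq_min = 1L,
                              require_no_indel = TRUE) {
  if (anchor < 1L) stop("anchor must be >= 1", call. = FALSE)
  structure(list(anchor = as.integer(anchor),
                 mapq_min = as.integer(mapq_min),
                 require_no_indel = isTRUE(require_no_indel)),
            class = "ies_classifier_config")
}

# Matched (M) reference ranges of one CIGAR/pos pair, merged across
# insertions when indels are tolerated.
matched_ranges <- function(cigar, pos, require_no_indel) {
  rng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = "M")[[1L]]
  if (!require_no_indel) rng <- IRanges::reduce(rng)
  rng
}

window_in_ranges <- function(w_start, w_end, rng) {
  any(IRanges::start(rng) <= w_start & IRanges::end(rng) >= w_end)
}

qualifies <- function(alignment, cfg) {
  flag <- alignment$flag %||% 0L
  !is.na(alignment$pos) &&
    (alignment$mapq %||% 60L) >= cfg$mapq_min &&
    bitwAnd(flag, 0x4) == 0L && bitwAnd(flag, 0x100) == 0L &&
    bitwAnd(flag, 0x800) == 0L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify one MAC alignment at a junction
#'
#' IES- iff the alignment covers the junction window
#' `[junction_pos - anchor + 1, junction_pos + 1 + anchor]` (the TA plus
#' `anchor` bases on each side) with matched bases, without indels in the
#' window when required.
#'
#' @param alignment A list with `pos`, `cigar` and optionally `mapq`, `flag`.
#' @param junction_pos MAC position of the first base of the junction TA.
#' @param cfg A [classifier_config()].
#' @return `"IES_MINUS"` or `"NONE"`.
#' @export
classify_on_mac <- function(alignment, junction_pos, cfg = classifier_config()) {
  if (!qualifies(alignment, cfg)) return("NONE")
  rng <- matched_ranges(alignment$cigar, alignment$pos, cfg$require_no_indel)
  w1 <- junction_pos - cfg$anchor + 1L
  w2 <- junction_pos + 1L + cfg$anchor
  if (window_in_ranges(w1, w2, rng)) "IES_MINUS" else "NONE"
}

#' Classify one MAC+IES alignment at the boundaries of an IES
#'
#' IES+ iff the alignment spans the left boundary (last somatic base | IES
#' leading TA) or the right boundary (last IES base | retained somatic TA)
#' with matched bases across the boundary window. Each window mirrors the
#' MAC junction window: the boundary TA plus `anchor` flanking bases
#' (`[g - anchor + 1, g + 1 + anchor]` for the left boundary at IES start
#' `g`; `[e - anchor + 2, e + 2 + anchor]` for the right boundary at IES end
#' `e`, whose TA sits at `e + 1`). A read spanning both boundaries is
#' IES_PLUS and counts once.
#'
#' @param alignment A list with `pos`, `cigar` and optionally `mapq`, `flag`.
#' @param ies_bounds_lifted `c(start, end)` of the IES on the MAC+IES contig.
#' @param cfg A [classifier_config()].
#' @return `"IES_PLUS"` or `"NONE"`.
#' @export
classify_on_mac_plus_ies <- function(alignment, ies_bounds_lifted,
                                     cfg = classifier_config()) {
  if (!qualifies(alignment, cfg)) return("NONE")
  rng <- matched_ranges(alignment$cigar, alignment$pos, cfg$require_no_indel)
  g <- ies_bounds_lifted[1L]
  e <- ies_bounds_lifted[2L]
  a <- cfg$anchor
  left <- window_in_ranges(g - a + 1L, g + 1L + a, rng)
  right <- window_in_ranges(e - a + 2L, e + 2L + a, rng)
  if (left || right) "IES_PLUS" else "NONE"
}

#' Read alignments from SAM or BAM
#'
#' SAM input is converted on the fly with `Rsamtools::asBam`. Returns the
#' fields the boundary classifier needs plus the header contig names.
#'
#' @param path SAM or BAM file.
#' @return A list with `records` (data.frame: qname, flag, rname, pos, mapq,
#'   cigar) and `contigs` (header sequence names).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("no such alignment file: ", path, call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE))
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar")))[[1L]]
  records <- data.frame(
    qname = res$qname, flag = res$flag,
    rname = as.character(res$rname), pos = res$pos,
    mapq = res$mapq, cigar = res$cigar,
    stringsAsFactors = FALSE
  )
  list(records = records, contigs = names(hdr))
}

# Vectorized window classification: which (window, record) pairs have the
# window fully inside one matched run (or inside the indel-merged runs).
window_hits <- function(records, windows, cfg) {
  if (nrow(records) == 0L || length(windows) == 0L) {
    return(data.frame(window = integer(), record = integer()))
  }
  mr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    records$cigar, pos = records$pos, ops = "M")
  if (!cfg$require_no_indel) mr <- IRanges::reduce(mr)
  nper <- S4Vectors::elementNROWS(mr)
  flat <- unlist(mr, use.names = FALSE)
  rec_of <- rep.int(seq_len(nrow(records)), nper)
  gr <- GenomicRanges::GRanges(records$rname[rec_of], flat)
  hits <- GenomicRanges::findOverlaps(windows, gr, type = "within")
  data.frame(window = S4Vectors::queryHits(hits),
             record = rec_of[S4Vectors::subjectHits(hits)])
}

primary_mapped <- function(records, cfg) {
  keep <- !is.na(records$pos) &
    !is.na(records$mapq) & records$mapq >= cfg$mapq_min &
    bitwAnd(records$flag, 0x4) == 0L &
    bitwAnd(records$flag, 0x100) == 0L &
    bitwAnd(records$flag, 0x800) == 0L
  records <- records[keep, , drop = FALSE]
  mate <- ifelse(bitwAnd(records$flag, 0x40) > 0L, "/1",
                 ifelse(bitwAnd(records$flag, 0x80) > 0L, "/2", ""))
  records$read_id <- paste0(records$qname, mate)
  records
}

#' Count IES+ and IES- reads per IES
#'
#' Classifies primary, uniquely mapped reads (MAPQ >= `mapq_min`) from
#' alignments against the MAC reference (IES-) and the MAC+IES reference
#' (IES+). IES+ support is tallied per boundary (left and right windows of
#' identical width to the MAC junction window) and averaged, so a retained
#' and an excised molecule contribute classifiable reads at the same rate
#' and the expected RS equals the IES-bearing molecule fraction for every
#' IES length. Each read identifier contributes at most once per boundary
#' (a both-ends-spanning read contributes once to each boundary tally, i.e.
#' once to the averaged count); a read classified as both IES+ and IES- for
#' the same IES is dropped and reported in the `dropped` attribute.
#'
#' @param mac_alignments Path to SAM/BAM against the MAC reference.
#' @param mac_plus_ies_alignments Path to SAM/BAM against MAC+IES.
#' @param annotations Validated IES annotation.
#' @param map Coordinate map from [build_mac_plus_ies()].
#' @param cfg A [classifier_config()].
#' @return `data.frame` with `ies_id`, `ies_plus`, `ies_minus`, one row per
#'   annotated IES; attribute `dropped` lists conflicting read/IES pairs.
#' @export
count_boundaries <- function(mac_alignments, mac_plus_ies_alignments,
                             annotations, map,
                             cfg = classifier_config()) {
  mac <- read_alignments(mac_alignments)
  plus <- read_alignments(mac_plus_ies_alignments)
  missing_mac <- setdiff(unique(annotations$contig), mac$contigs)
  if (length(missing_mac)) {
    stop("contig(s) missing from MAC alignment header: ",
         paste(missing_mac, collapse = ", "), call. = FALSE)
  }
  missing_plus <- setdiff(unique(map$contig), plus$contigs)
  if (length(missing_plus)) {
    stop("contig(s) missing from MAC+IES alignment header: ",
         paste(missing_plus, collapse = ", "), call. = FALSE)
  }
  a <- cfg$anchor
  ord <- match(annotations$ies_id, map$ies_id)
  stopifnot(!anyNA(ord))
  g <- map$lifted_start[ord]
  e <- g + map$ies_length[ord] - 1L

  mac_rec <- primary_mapped(mac$records, cfg)
  plus_rec <- primary_mapped(plus$records, cfg)

  minus_windows <- GenomicRanges::GRanges(
    annotations$contig,
    IRanges::IRanges(annotations$mac_junction - a + 1L,
                     annotations$mac_junction + 1L + a))
  left_windows <- GenomicRanges::GRanges(
    annotations$contig, IRanges::IRanges(g - a + 1L, g + 1L + a))
  right_windows <- GenomicRanges::GRanges(
    annotations$contig, IRanges::IRanges(e - a + 2L, e + 2L + a))

  minus_hits <- window_hits(mac_rec, minus_windows, cfg)
  left_hits <- window_hits(plus_rec, left_windows, cfg)
  right_hits <- window_hits(plus_rec, right_windows, cfg)

  minus_pairs <- unique(data.frame(
    ies = minus_hits$window,
    read_id = mac_rec$read_id[minus_hits$record],
    stringsAsFactors = FALSE))
  left_pairs <- unique(data.frame(
    ies = left_hits$window,
    read_id = plus_rec$read_id[left_hits$record],
    stringsAsFactors = FALSE))
  right_pairs <- unique(data.frame(
    ies = right_hits$window,
    read_id = plus_rec$read_id[right_hits$record],
    stringsAsFactors = FALSE))

  plus_pairs <- unique(rbind(left_pairs, right_pairs))
  conflict <- merge(minus_pairs, plus_pairs, by = c("ies", "read_id"))
  if (nrow(conflict)) {
    key_c <- paste(conflict$ies, conflict$read_id)
    minus_pairs <- minus_pairs[
      !(paste(minus_pairs$ies, minus_pairs$read_id) %in% key_c), ,
      drop = FALSE]
    left_pairs <- left_pairs[
      !(paste(left_pairs$ies, left_pairs$read_id) %in% key_c), ,
      drop = FALSE]
    right_pairs <- right_pairs[
      !(paste(right_pairs$ies, right_pairs$read_id) %in% key_c), ,
      drop = FALSE]
  }
  nb <- nrow(annotations)
  plus_avg <- (tabulate(left_pairs$ies, nbins = nb) +
                 tabulate(right_pairs$ies, nbins = nb)) / 2
  out <- data.frame(
    ies_id = annotations$ies_id,
    # round half to even so the averaged tally stays unbiased
    ies_plus = as.integer(round(plus_avg)),
    ies_minus = tabulate(minus_pairs$ies, nbins = nb),
    stringsAsFactors = FALSE
  )
  attr(out, "dropped") <- if (nrow(conflict)) {
    data.frame(ies_id = annotations$ies_id[conflict$ies],
               read_id = conflict$read_id, stringsAsFactors = FALSE)
  } else {
    data.frame(ies_id = character(), read_id = character(),
               stringsAsFactors = FALSE)
  }
  out
}

#' Write boundary counts as TSV
#'
#' @param counts Counts table from [count_boundaries()].
#' @param path Output file.
#' @export
write_boundary_counts <- function(counts, path) write_tsv(counts, path)
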