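# Genome model: somatic (MAC) reference, IES annotation, germline-like
# MAC+IES reference, and the coordinate map linking the two systems.
#
# Conventions: 1-based fully closed coordinates (GFF3). An IES sequence
# INCLUDES its leading TA; it is inserted immediately before the MAC junction
# TA, so the germline locus reads ...TA-body-TA... and excision is deletion of
# `length` bp starting at the lifted junction.

#' Load a somatic (MAC) reference genome
#'
#' Reads a FASTA file into a `DNAStringSet` and validates it as a MAC
#' reference: unique contig names, non-empty sequences, alphabet restricted to
#' A/C/G/T/N.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A `DNAStringSet` with `metadata(x)$flavor == "MAC"`.
#' @export
load_mac_reference <- function(fasta_path) {
  genome <- tryCatch(
    Biostrings::readDNAStringSet(fasta_path),
    error = function(e) stop("malformed FASTA '", fasta_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  # FASTA descriptions may carry comments after the name; keep the first word
  names(genome) <- sub("\\s.*$", "", names(genome))
  validate_reference(genome, flavor = "MAC")
}

#' Validate a reference genome object
#'
#' @param genome A `DNAStringSet`.
#' @param flavor `"MAC"` or `"MAC_PLUS_IES"`.
#' @return The validated genome with its flavor recorded in `metadata()`.
#' @export
validate_reference <- function(genome, flavor = c("MAC", "MAC_PLUS_IES")) {
  flavor <- match.arg(flavor)
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (length(genome) == 0L) {
    stop("reference contains no sequences", call. = FALSE)
  }
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("all contigs must be named", call. = FALSE)
  }
  if (anyDuplicated(names(genome))) {
    dup <- unique(names(genome)[duplicated(names(genome))])
    stop("duplicate contig name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(Biostrings::width(genome) == 0L)) {
    stop("empty sequence for contig(s): ",
         paste(names(genome)[Biostrings::width(genome) == 0L], collapse = ", "),
         call. = FALSE)
  }
  freq <- Biostrings::alphabetFrequency(genome, collapse = TRUE)
  bad <- freq[setdiff(names(freq), c("A", "C", "G", "T", "N"))]
  if (sum(bad) > 0) {
    stop("alphabet restricted to ACGTN; found: ",
         paste(names(bad)[bad > 0], collapse = ", "), call. = FALSE)
  }
  S4Vectors::metadata(genome)$flavor <- flavor
  genome
}

#' Construct an IES annotation table
#'
#' @param ies_id Character vector of unique IES identifiers.
#' @param contig MAC contig carrying each junction.
#' @param mac_junction 1-based MAC position of the first base of the junction
#'   TA dinucleotide.
#' @param sequence IES sequence including the leading TA.
#' @return A `data.frame` with columns `ies_id`, `contig`, `mac_junction`,
#'   `length`, `sequence`, sorted by contig and junction.
#' @export
ies_annotation <- function(ies_id, contig, mac_junction, sequence) {
  ann <- data.frame(
    ies_id = as.character(ies_id),
    contig = as.character(contig),
    mac_junction = as.integer(mac_junction),
    length = nchar(sequence),
    sequence = toupper(as.character(sequence)),
    stringsAsFactors = FALSE
  )
  ann[order(ann$contig, ann$mac_junction), , drop = FALSE]
}

#' Validate an IES annotation against its MAC reference
#'
#' Checks, per record: the sequence starts with TA; the MAC contig carries TA
#' at the junction; `length == nchar(sequence)`; junctions are unique per
#' contig. Elements shorter than 26 bp raise a warning (the shortest known
#' elements are 26 bp) but are kept.
#'
#' @param ann Annotation `data.frame` (see [ies_annotation()]).
#' @param genome MAC reference `DNAStringSet`.
#' @return The validated, sorted annotation.
#' @export
validate_ies_annotation <- function(ann, genome) {
  stopifnot(is.data.frame(ann))
  needed <- c("ies_id", "contig", "mac_junction", "length", "sequence")
  missing_cols <- setdiff(needed, names(ann))
  if (length(missing_cols)) {
    stop("annotation lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(S4Vectors::metadata(genome)$flavor) &&
      S4Vectors::metadata(genome)$flavor != "MAC") {
    stop("annotations validate against a MAC-flavor reference", call. = FALSE)
  }
  if (anyDuplicated(ann$ies_id)) {
    stop("duplicate ies_id(s): ",
         paste(unique(ann$ies_id[duplicated(ann$ies_id)]), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(ann$contig, names(genome))
  if (length(unknown)) {
    stop("annotation refers to unknown contig(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(ann$length != nchar(ann$sequence))) {
    bad <- ann$ies_id[ann$length != nchar(ann$sequence)]
    stop("length != nchar(sequence) for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  not_ta <- substr(ann$sequence, 1L, 2L) != "TA"
  if (any(not_ta)) {
    stop("IES sequence must begin with TA; violated by: ",
         paste(ann$ies_id[not_ta], collapse = ", "), call. = FALSE)
  }
  widths <- Biostrings::width(genome)[match(ann$contig, names(genome))]
  oob <- ann$mac_junction < 1L | ann$mac_junction + 1L > widths
  if (any(oob)) {
    stop("junction outside contig for: ",
         paste(ann$ies_id[oob], collapse = ", "), call. = FALSE)
  }
  mac_ta <- vapply(seq_len(nrow(ann)), function(i) {
    as.character(Biostrings::subseq(genome[[ann$contig[i]]],
                                    ann$mac_junction[i],
                                    ann$mac_junction[i] + 1L))
  }, character(1))
  if (any(mac_ta != "TA")) {
    bad <- ann$ies_id[mac_ta != "TA"]
    stop("MAC junction does not carry TA for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ann <- ann[order(ann$contig, ann$mac_junction), , drop = FALSE]
  dup_junc <- duplicated(ann[, c("contig", "mac_junction")])
  if (any(dup_junc)) {
    stop("two IESs at identical junction: ",
         paste(ann$ies_id[dup_junc], collapse = ", "), call. = FALSE)
  }
  if (any(ann$length < 26L)) {
    warning("IES(s) shorter than 26 bp: ",
            paste(ann$ies_id[ann$length < 26L], collapse = ", "),
            call. = FALSE)
  }
  rownames(ann) <- NULL
  ann
}

#' Load an IES annotation from GFF3
#'
#' Expects features of type `internal_eliminated_sequence` with attributes
#' `ID` and `sequence`; `start` is the MAC junction position (first base of
#' the junction TA).
#'
#' @param gff3_path Path to the GFF3 file.
#' @param genome MAC reference to validate against.
#' @return Validated annotation `data.frame`.
#' @export
load_ies_annotation <- function(gff3_path, genome) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  gr <- gr[as.character(gr$type) == "internal_eliminated_sequence"]
  if (length(gr) == 0L) {
    stop("no internal_eliminated_sequence features in ", gff3_path,
         call. = FALSE)
  }
  if (is.null(gr$sequence) || any(is.na(gr$sequence))) {
    stop("every IES feature needs a 'sequence' attribute", call. = FALSE)
  }
  ann <- ies_annotation(
    ies_id = gr$ID,
    contig = as.character(GenomicRanges::seqnames(gr)),
    mac_junction = GenomicRanges::start(gr),
    sequence = gr$sequence
  )
  validate_ies_annotation(ann, genome)
}

#' Write an IES annotation to GFF3
#'
#' @param ann Annotation `data.frame`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ies_annotation <- function(ann, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$contig,
    ranges = IRanges::IRanges(start = ann$mac_junction,
                              end = ann$mac_junction + 1L),
    type = "internal_eliminated_sequence",
    source = "iesret",
    ID = ann$ies_id,
    sequence = ann$sequence
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Build the MAC+IES reference and its coordinate map
#'
#' Inserts every IES sequence immediately before its junction TA so the
#' germline locus reads `...TA-body-TA...`; removing `length` bp at each
#' lifted junction restores the MAC byte-for-byte.
#'
#' @param genome MAC reference `DNAStringSet`.
#' @param ann Validated IES annotation.
#' @return A list with `genome` (flavor `MAC_PLUS_IES`) and `map`, the
#'   coordinate map `data.frame` (`contig`, `ies_id`, `mac_junction`,
#'   `ies_length`, `lifted_start`).
#' @export
build_mac_plus_ies <- function(genome, ann) {
  ann <- validate_ies_annotation(ann, genome)
  seqs <- as.character(genome)
  map_rows <- vector("list", length(genome))
  names(map_rows) <- names(genome)
  out <- seqs
  for (ctg in unique(ann$contig)) {
    rows <- ann[ann$contig == ctg, , drop = FALSE]
    shift <- c(0L, cumsum(rows$length))[seq_len(nrow(rows))]
    lifted <- rows$mac_junction + shift
    mac <- seqs[[ctg]]
    # splice: MAC pieces between successive junctions, IES before each TA
    cuts <- c(1L, rows$mac_junction, nchar(mac) + 1L)
    pieces <- character(2L * nrow(rows) + 1L)
    for (i in seq_len(nrow(rows))) {
      pieces[2L * i - 1L] <- substr(mac, cuts[i], rows$mac_junction[i] - 1L)
      pieces[2L * i] <- rows$sequence[i]
    }
    pieces[2L * nrow(rows) + 1L] <-
      substr(mac, rows$mac_junction[nrow(rows)], nchar(mac))
    out[[ctg]] <- paste(pieces, collapse = "")
    map_rows[[ctg]] <- data.frame(
      contig = ctg, ies_id = rows$ies_id, mac_junction = rows$mac_junction,
      ies_length = rows$length, lifted_start = lifted,
      stringsAsFactors = FALSE
    )
  }
  built <- Biostrings::DNAStringSet(out)
  expected <- Biostrings::width(genome) +
    vapply(names(genome), function(ctg) {
      sum(ann$length[ann$contig == ctg])
    }, integer(1))
  stopifnot(all(Biostrings::width(built) == expected))
  map <- do.call(rbind, c(map_rows[!vapply(map_rows, is.null, logical(1))],
                          list(make.row.names = FALSE)))
  if (is.null(map)) {
    map <- data.frame(contig = character(), ies_id = character(),
                      mac_junction = integer(), ies_length = integer(),
                      lifted_start = integer(), stringsAsFactors = FALSE)
  }
  list(genome = validate_reference(built, "MAC_PLUS_IES"), map = map)
}

#' Lift a MAC coordinate into the MAC+IES system
#'
#' Positions at or after a junction shift by that IES's length (the junction
#' TA itself sits after the inserted IES).
#'
#' @param map Coordinate map from [build_mac_plus_ies()].
#' @param contig Contig name.
#' @param mac_pos 1-based MAC position(s).
#' @return Lifted position(s) on the MAC+IES contig.
#' @export
lift_coordinate <- function(map, contig, mac_pos) {
  stopifnot(length(contig) == 1L)
  if (any(mac_pos < 1L)) stop("mac_pos must be >= 1", call. = FALSE)
  rows <- map[map$contig == contig, , drop = FALSE]
  if (nrow(rows) == 0L) return(as.integer(mac_pos))
  shift <- vapply(mac_pos, function(p) {
    sum(rows$ies_length[rows$mac_junction <= p])
  }, numeric(1))
  as.integer(mac_pos + shift)
}

#' Map a MAC+IES coordinate back to the MAC system
#'
#' Only positions outside IES intervals are mappable; positions inside an IES
#' raise an error.
#'
#' @inheritParams lift_coordinate
#' @param lifted_pos 1-based MAC+IES position(s).
#' @export
unlift_coordinate <- function(map, contig, lifted_pos) {
  stopifnot(length(contig) == 1L)
  rows <- map[map$contig == contig, , drop = FALSE]
  if (nrow(rows) == 0L) return(as.integer(lifted_pos))
  vapply(lifted_pos, function(p) {
    inside <- p >= rows$lifted_start & p <= rows$lifted_start +
      rows$ies_length - 1L
    if (any(inside)) {
      stop("position ", p, " lies inside IES ",
           rows$ies_id[which(inside)[1L]], call. = FALSE)
    }
    as.integer(p - sum(rows$ies_length[rows$lifted_start + rows$ies_length -
                                         1L < p]))
  }, integer(1))
}

#' Excise every annotated IES from a MAC+IES genome
#'
#' Removes `ies_length` bp at each lifted junction; the result must equal the
#' MAC reference the map was built from.
#'
#' @param mac_plus_ies `DNAStringSet`, flavor MAC_PLUS_IES.
#' @param map Coordinate map.
#' @return A MAC-flavor `DNAStringSet`.
#' @export
excise_all_ies <- function(mac_plus_ies, map) {
  seqs <- as.character(mac_plus_ies)
  for (ctg in unique(map$contig)) {
    rows <- map[map$contig == ctg, , drop = FALSE]
    rows <- rows[order(rows$lifted_start), , drop = FALSE]
    s <- seqs[[ctg]]
    keep_start <- c(1L, rows$lifted_start + rows$ies_length)
    keep_end <- c(rows$lifted_start - 1L, nchar(s))
    seqs[[ctg]] <- paste(substring(s, keep_start, keep_end), collapse = "")
  }
  validate_reference(Biostrings::DNAStringSet(seqs), "MAC")
}

#' Write a reference genome as 60-column FASTA
#'
#' @param genome `DNAStringSet`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reference <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

#' Dump a coordinate map as TSV
#'
#' @param map Coordinate map `data.frame`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_coordinate_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
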