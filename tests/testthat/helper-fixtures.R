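# Shared fixtures, built in code at test time.

# Write a FASTA file and return its path.
write_fasta_fixture <- function(named_seqs, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".fasta")
  writeLines(paste0(">", names(named_seqs), "\n", named_seqs), path)
  path
}

# The 8 bp toy from the annotation examples: TA junction at position 4.
toy_mac <- function() {
  validate_reference(Biostrings::DNAStringSet(c(c1 = "CCCTAGGG")), "MAC")
}

toy_annotation <- function() {
  ies_annotation("ies1", "c1", 4L, "TATTGC")
}

# Write a SAM file from a record data.frame (qname, flag, rname, pos, mapq,
# cigar); sequences are omitted ("*"), which the classifier never reads.
write_sam_fixture <- function(records, contig_lengths, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                  records$qname, records$flag, records$rname,
                  records$pos, records$mapq, records$cigar)
  writeLines(c(hdr, body), path)
  path
}

# One-IES fixture genome for classifier tests: 400 bp contig, 28 bp IES
# whose junction TA sits at MAC position 200.
fixture_one_ies <- function(seed = 11) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  mac <- paste(sample(bases, 400, replace = TRUE, prob = c(.36, .14, .14, .36)),
               collapse = "")
  substr(mac, 200, 201) <- "TA"
  genome <- validate_reference(Biostrings::DNAStringSet(c(chr = mac)), "MAC")
  ann <- ies_annotation("iesA", "chr", 200L,
                        paste0("TA", paste(sample(bases, 26, replace = TRUE),
                                           collapse = "")))
  built <- build_mac_plus_ies(genome, ann)
  list(mac = genome, ann = ann, plus = built$genome, map = built$map)
}

# Small simulated world shared by several tests.
small_sim <- function(seed = 5, n_ies = 30, contig_length = 20000L,
                      depth = 20, contamination = 0) {
  cfg <- simulation_config(n_contigs = 2L, contig_length = contig_length,
                           n_ies = n_ies, depth = depth,
                           contamination = contamination, seed = seed)
  simulate_genome(cfg)
}
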