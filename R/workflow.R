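# End-to-end commands tying the stages together: simulate a fixture bundle,
# score an experiment against a control, and report cohort summaries.

#' Simulate a complete fixture bundle
#'
#' Generates a genome, truth table and reads, and writes the whole bundle
#' (FASTA x2, GFF3, coordinate map, FASTQ pair, truth TSV, ideal-alignment
#' SAM x2) plus a checksum manifest. Deterministic per `config$seed`.
#'
#' @param config An [simulation_config()].
#' @param out_dir Output directory.
#' @param retention Per-IES molecular retention fraction(s), recycled over
#'   IESs.
#' @param contamination Maternal-MAC molecule fraction.
#' @param prefix File-name prefix.
#' @param read_seed Optional separate seed for the read-level randomness
#'   (see [simulate_reads()]).
#' @return List with `sim`, `truth`, `paths` (all outputs) and `manifest`.
#' @export
run_simulation <- function(config, out_dir, retention = 0,
                           contamination = config$contamination,
                           prefix = "sim", read_seed = NULL) {
  stopifnot(inherits(config, "ies_sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(config)
  truth <- simulation_truth(sim$annotations, retention, contamination)
  reads <- simulate_reads(sim, truth, out_dir, prefix = prefix,
                          seed = read_seed)
  paths <- c(
    list(
      mac_fasta = file.path(out_dir, paste0(prefix, "_mac.fasta")),
      mac_plus_ies_fasta = file.path(out_dir,
                                     paste0(prefix, "_mac_plus_ies.fasta")),
      gff3 = file.path(out_dir, paste0(prefix, "_ies.gff3")),
      coordinate_map = file.path(out_dir, paste0(prefix, "_coord_map.tsv"))
    ),
    reads$paths
  )
  write_reference(sim$mac, paths$mac_fasta)
  write_reference(sim$mac_plus_ies, paths$mac_plus_ies_fasta)
  write_ies_annotation(sim$annotations, paths$gff3)
  write_coordinate_map(sim$map, paths$coordinate_map)
  files <- unlist(paths, use.names = FALSE)
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  manifest_path <- file.path(out_dir, paste0(prefix, "_manifest.tsv"))
  write_tsv(manifest, manifest_path)
  paths$manifest <- manifest_path
  list(sim = sim, truth = truth, paths = paths, manifest = manifest,
       n_fragments = reads$n_fragments)
}

#' Score an experiment against a control
#'
#' Runs [call_significant()] and assembles the headline summary: IESs
#' tested, IESs significantly retained, mean RS overall and among the
#' significant set.
#'
#' @param experiment,control Boundary-count tables.
#' @param cfg A [test_config()].
#' @param out_dir Optional output directory for the records TSV and summary
#'   JSON.
#' @param prefix File-name prefix.
#' @return List with `records` and `summary`.
#' @export
run_score <- function(experiment, control, cfg = test_config(),
                      out_dir = NULL, prefix = "score") {
  if (!is.data.frame(experiment) || nrow(experiment) == 0L) {
    stop("empty experiment table", call. = FALSE)
  }
  records <- call_significant(experiment, control, cfg)
  sig <- records$significant & !is.na(records$rs)
  summary <- list(
    n_ies = nrow(records),
    n_tested = sum(!is.na(records$pvalue)),
    n_significant = sum(records$significant, na.rm = TRUE),
    mean_rs = mean(records$rs, na.rm = TRUE),
    mean_rs_significant = if (any(sig)) mean(records$rs[sig]) else NA_real_
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_retention_records(records,
                            file.path(out_dir, paste0(prefix, "_records.tsv")))
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(summary,
                           file.path(out_dir, paste0(prefix, "_summary.json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  list(records = records, summary = summary)
}

#' Cohort report over one or more retention-record tables
#'
#' Produces size-group summaries and significant-proportion curves per
#' sample, and (for two or more samples) the overlap cells of the
#' significant sets.
#'
#' @param records_list Named list of retention-record tables.
#' @param lengths `data.frame` with `ies_id`, `length`.
#' @param bins Size binning.
#' @param out_dir Optional output directory for TSVs.
#' @return List with per-sample `group_summaries`, `proportions`, and
#'   `overlap` (NULL for a single sample).
#' @export
run_report <- function(records_list, lengths, bins = default_size_bins(),
                       out_dir = NULL) {
  stopifnot(is.list(records_list), length(records_list) >= 1L,
            !is.null(names(records_list)))
  summaries <- lapply(records_list, group_summaries, lengths = lengths,
                      bins = bins)
  proportions <- lapply(records_list, proportion_significant_by_group,
                        lengths = lengths, bins = bins)
  overlap <- NULL
  if (length(records_list) >= 2L) {
    sets <- lapply(records_list, function(r) {
      r$ies_id[!is.na(r$significant) & r$significant]
    })
    overlap <- overlap_sets(sets)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(summaries)) {
      write_tsv(summaries[[nm]],
                file.path(out_dir, paste0(nm, "_group_summary.tsv")))
      write_tsv(proportions[[nm]],
                file.path(out_dir, paste0(nm, "_proportion_significant.tsv")))
    }
    if (!is.null(overlap)) {
      write_tsv(overlap$cells, file.path(out_dir, "overlap_cells.tsv"))
    }
  }
  list(group_summaries = summaries, proportions = proportions,
       overlap = overlap)
}
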