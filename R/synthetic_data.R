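# Synthetic-data generator: AT-rich genomes carrying TA-anchored IESs, and a
# paired-end read simulator whose molecules are a mixture of a fully excised
# maternal-MAC pool (fraction c) and new-MAC molecules that retain each IES
# independently with probability r_i. Besides FASTQ, the simulator emits
# "ideal aligner" SAM against both references, derived from each fragment's
# known block structure, so the downstream classifier can be exercised
# without an external aligner.

#' Default IES length distribution
#'
#' A mixture over the periodic peaks of the genome-wide IES size
#' distribution: peaks every ~10 bp starting at 26 bp (first peak 26-32 bp,
#' which holds roughly a third of all elements), with weights decaying
#' towards the rare kb-scale elements. Lengths are uniform within a peak.
#'
#' @return A `data.frame` with columns `lower`, `upper`, `weight`.
#' @export
default_ies_length_distribution <- function() {
  data.frame(
    lower  = c(26L, 33L, 43L, 53L, 63L, 73L, 83L, 93L, 103L, 153L, 333L),
    upper  = c(32L, 42L, 52L, 62L, 72L, 82L, 92L, 102L, 152L, 332L, 1200L),
    weight = c(0.40, 0.05, 0.15, 0.10, 0.08, 0.06, 0.05, 0.04, 0.04,
               0.02, 0.01)
  )
}

validate_length_distribution <- function(distribution) {
  if (!is.data.frame(distribution) || nrow(distribution) == 0L) {
    stop("length distribution must be a non-empty data.frame", call. = FALSE)
  }
  needed <- c("lower", "upper", "weight")
  if (!all(needed %in% names(distribution))) {
    stop("length distribution needs columns lower, upper, weight",
         call. = FALSE)
  }
  if (abs(sum(distribution$weight) - 1) > 1e-8) {
    stop("length distribution weights must sum to 1", call. = FALSE)
  }
  if (any(distribution$weight < 0)) {
    stop("length distribution weights must be non-negative", call. = FALSE)
  }
  if (any(distribution$lower < 26L)) {
    stop("IES lengths below 26 bp are not generated", call. = FALSE)
  }
  if (any(distribution$upper < distribution$lower)) {
    stop("bin upper < lower in length distribution", call. = FALSE)
  }
  distribution
}

#' Sample IES lengths from a peak mixture
#'
#' @param distribution A `data.frame` as returned by
#'   [default_ies_length_distribution()].
#' @param n Number of lengths to draw.
#' @return Integer vector of lengths, all >= 26.
#' @export
sample_ies_length <- function(distribution, n = 1L) {
  distribution <- validate_length_distribution(distribution)
  bin <- sample.int(nrow(distribution), size = n, replace = TRUE,
                    prob = distribution$weight)
  lo <- distribution$lower[bin]
  hi <- distribution$upper[bin]
  as.integer(lo + floor(stats::runif(n) * (hi - lo + 1L)))
}

#' Build a simulation configuration
#'
#' Defaults state the world the simulator emulates: an AT-rich genome
#' (GC 0.28), 100 bp paired-end reads with ~250 bp inserts, 25x depth and a
#' 0.5% per-base substitution error rate. `contamination` is the fraction of
#' sequenced molecules drawn from the fully excised maternal-MAC pool.
#'
#' @param n_contigs Number of MAC contigs.
#' @param contig_length Length of each MAC contig (bp).
#' @param gc_fraction GC content of the simulated genome.
#' @param n_ies Total number of IESs, spread evenly over contigs.
#' @param ies_length_distribution Peak mixture for IES lengths.
#' @param read_length Read length (bp).
#' @param insert_mean,insert_sd Fragment (insert) size distribution.
#' @param depth Mean sequencing depth over the MAC+IES genome.
#' @param substitution_error_rate Per-base substitution error probability.
#' @param contamination Maternal-MAC molecule fraction, in `[0, 1]`.
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @return A list of class `ies_sim_config`.
#' @export
simulation_config <- function(n_contigs = 2L,
                              contig_length = 50000L,
                              gc_fraction = 0.28,
                              n_ies = 100L,
                              ies_length_distribution =
                                default_ies_length_distribution(),
                              read_length = 100L,
                              insert_mean = 250,
                              insert_sd = 30,
                              depth = 25,
                              substitution_error_rate = 0.005,
                              contamination = 0,
                              seed = 1L) {
  cfg <- list(
    n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    gc_fraction = gc_fraction,
    n_ies = as.integer(n_ies),
    ies_length_distribution =
      validate_length_distribution(ies_length_distribution),
    read_length = as.integer(read_length),
    insert_mean = insert_mean,
    insert_sd = insert_sd,
    depth = depth,
    substitution_error_rate = substitution_error_rate,
    contamination = contamination,
    seed = as.integer(seed)
  )
  if (cfg$gc_fraction < 0 || cfg$gc_fraction > 1) {
    stop("gc_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$contamination < 0 || cfg$contamination > 1) {
    stop("contamination must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$depth <= 0) stop("depth must be positive", call. = FALSE)
  if (cfg$n_contigs < 1L || cfg$contig_length < 1L || cfg$read_length < 1L) {
    stop("all lengths must be positive", call. = FALSE)
  }
  if (cfg$insert_mean < cfg$read_length) {
    stop("insert size must be >= read length", call. = FALSE)
  }
  if (cfg$substitution_error_rate < 0 || cfg$substitution_error_rate > 1) {
    stop("substitution_error_rate must lie in [0, 1]", call. = FALSE)
  }
  class(cfg) <- "ies_sim_config"
  cfg
}

# Random DNA of length n at the configured GC content.
random_dna <- function(n, gc_fraction) {
  if (n == 0L) return("")
  probs <- c((1 - gc_fraction) / 2, gc_fraction / 2,
             gc_fraction / 2, (1 - gc_fraction) / 2)
  codes <- c(65L, 67L, 71L, 84L)  # A C G T
  intToUtf8(codes[sample.int(4L, n, replace = TRUE, prob = probs)])
}

#' Simulate a MAC genome with annotated IESs
#'
#' Generates `n_contigs` random MAC contigs, plants `n_ies` TA junctions
#' (junctions keep a 2 bp TA forced into the MAC sequence, spaced evenly with
#' a junction-free margin at contig ends), draws IES lengths from the peak
#' mixture, and builds the MAC+IES reference.
#'
#' @param config An `ies_sim_config`.
#' @return A list with `mac`, `annotations`, `mac_plus_ies`, `map`, `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "ies_sim_config"))
  with_seed(config$seed, {
    margin <- as.integer(config$insert_mean + 3 * config$insert_sd +
                           config$read_length)
    per_contig <- diff(round(seq(0, config$n_ies,
                                 length.out = config$n_contigs + 1L)))
    avail <- config$contig_length - 2L * margin
    if (config$n_ies > 0L && (avail < 1L ||
        any(per_contig > 0L & avail / pmax(per_contig, 1L) < 100))) {
      stop("n_ies too large for contig_length (junctions need >= 100 bp ",
           "spacing plus a ", margin, " bp margin)", call. = FALSE)
    }
    contig_names <- sprintf("contig_%02d", seq_len(config$n_contigs))
    seqs <- vapply(contig_names, function(nm) {
      random_dna(config$contig_length, config$gc_fraction)
    }, character(1))
    ann_list <- list()
    for (ci in seq_len(config$n_contigs)) {
      k <- per_contig[ci]
      if (k == 0L) next
      spacing <- avail %/% k
      base <- margin + spacing * (seq_len(k) - 1L) +
        sample.int(min(20L, spacing - 99L), k, replace = TRUE)
      s <- seqs[[ci]]
      for (j in base) substr(s, j, j + 1L) <- "TA"
      seqs[[ci]] <- s
      lens <- sample_ies_length(config$ies_length_distribution, k)
      bodies <- vapply(lens, function(L) {
        paste0("TA", random_dna(L - 2L, config$gc_fraction))
      }, character(1))
      ann_list[[ci]] <- data.frame(
        contig = contig_names[ci], mac_junction = base,
        sequence = bodies, stringsAsFactors = FALSE
      )
    }
    mac <- validate_reference(Biostrings::DNAStringSet(seqs), "MAC")
    if (length(ann_list)) {
      raw <- do.call(rbind, ann_list)
      ann <- ies_annotation(
        ies_id = sprintf("IES.%s.%d", raw$contig, raw$mac_junction),
        contig = raw$contig, mac_junction = raw$mac_junction,
        sequence = raw$sequence
      )
      ann <- validate_ies_annotation(ann, mac)
    } else {
      ann <- ies_annotation(character(), character(), integer(), character())
    }
    built <- build_mac_plus_ies(mac, ann)
    list(mac = mac, annotations = ann, mac_plus_ies = built$genome,
         map = built$map, config = config)
  })
}

#' Build a simulation truth table
#'
#' @param annotations IES annotation `data.frame`.
#' @param retention Per-IES molecular retention fraction r_i (recycled).
#' @param contamination Maternal-MAC molecule fraction c.
#' @return A `data.frame` `ies_id`, `retention_fraction`, `contamination`;
#'   the expected IES-bearing molecule fraction at a locus is `(1 - c) * r_i`.
#' @export
simulation_truth <- function(annotations, retention, contamination = 0) {
  stopifnot(all(retention >= 0 & retention <= 1),
            contamination >= 0, contamination <= 1)
  data.frame(
    ies_id = annotations$ies_id,
    retention_fraction = rep_len(retention, nrow(annotations)),
    contamination = contamination,
    stringsAsFactors = FALSE
  )
}

# Walk one fragment through a contig: start x (MAC+IES coordinates), insert m.
# Returns the kept MAC+IES intervals (matrix cols a, b) or NULL if the walk
# runs off the contig end. Retention is drawn per junction encountered;
# maternal molecules never retain.
walk_fragment <- function(x, m, maternal, glift, gend, rvec, contig_len) {
  a <- integer(8L); b <- integer(8L); nb <- 0L
  pos <- x; rem <- m
  nJ <- length(glift)
  repeat {
    k <- findInterval(pos, glift)
    if (k >= 1L && pos <= gend[k]) {         # inside IES k (retained)
      lim <- gend[k]
    } else if (k < nJ) {
      lim <- glift[k + 1L] - 1L
    } else {
      lim <- contig_len
    }
    take <- min(lim - pos + 1L, rem)
    if (nb > 0L && b[nb] + 1L == pos) {
      b[nb] <- pos + take - 1L
    } else {
      nb <- nb + 1L
      if (nb > length(a)) { a <- c(a, integer(8L)); b <- c(b, integer(8L)) }
      a[nb] <- pos; b[nb] <- pos + take - 1L
    }
    rem <- rem - take
    pos <- pos + take
    if (rem == 0L) break
    if (pos > contig_len) return(NULL)
    nk <- findInterval(pos, glift)
    if (nk >= 1L && pos == glift[nk]) {      # at an IES start: retain or skip
      retained <- !maternal && stats::runif(1) < rvec[nk]
      if (!retained) {
        pos <- gend[nk] + 1L
        if (pos > contig_len) return(NULL)
      }
    }
  }
  cbind(a = a[seq_len(nb)], b = b[seq_len(nb)])
}

# Slice block intervals (molecule order) to molecule positions [from, to].
slice_blocks <- function(blocks, from, to) {
  w <- blocks[, "b"] - blocks[, "a"] + 1L
  cw <- cumsum(w)
  first <- which(cw >= from)[1L]
  last <- which(cw >= to)[1L]
  out <- blocks[first:last, , drop = FALSE]
  prev <- c(0L, cw)[first:last]
  off <- from - prev[1L]
  out[1L, "a"] <- out[1L, "a"] + (from - prev[1L] - 1L)
  nlast <- nrow(out)
  out[nlast, "b"] <- blocks[last, "a"] + (to - c(0L, cw)[last] - 1L)
  # read offset of each block within the slice
  w2 <- out[, "b"] - out[, "a"] + 1L
  cbind(out, off = c(1L, 1L + cumsum(w2))[seq_len(nlast)])
}

# MAC-space match runs for a slice: subtract IES intervals, map through the
# cumulative-length shift, merge runs adjacent in both read and reference.
mac_runs <- function(slice, glift, gend, cumL) {
  ra <- integer(0); rlen <- integer(0); roff <- integer(0)
  for (i in seq_len(nrow(slice))) {
    A <- slice[i, "a"]; B <- slice[i, "b"]; o <- slice[i, "off"]
    k1 <- findInterval(A - 1L, gend) + 1L    # first IES not entirely before A
    k2 <- findInterval(B, glift)             # last IES starting at/before B
    cur <- A
    ks <- if (k1 <= k2) k1:k2 else integer(0)
    for (k in ks) {
      ps <- max(A, glift[k])
      if (cur <= ps - 1L) {
        shift <- cumL[findInterval(cur - 1L, gend) + 1L]
        ra <- c(ra, cur - shift); rlen <- c(rlen, ps - cur)
        roff <- c(roff, o + (cur - A))
      }
      cur <- min(B, gend[k]) + 1L
    }
    if (cur <= B) {
      shift <- cumL[findInterval(cur - 1L, gend) + 1L]
      ra <- c(ra, cur - shift); rlen <- c(rlen, B - cur + 1L)
      roff <- c(roff, o + (cur - A))
    }
  }
  if (length(ra) == 0L) return(NULL)
  # merge runs contiguous on MAC and in the read (i.e. across excised sites)
  keep_a <- ra[1L]; keep_len <- rlen[1L]; keep_off <- roff[1L]
  if (length(ra) > 1L) {
    for (i in 2L:length(ra)) {
      n <- length(keep_a)
      if (keep_a[n] + keep_len[n] == ra[i] &&
          keep_off[n] + keep_len[n] == roff[i]) {
        keep_len[n] <- keep_len[n] + rlen[i]
      } else {
        keep_a <- c(keep_a, ra[i]); keep_len <- c(keep_len, rlen[i])
        keep_off <- c(keep_off, roff[i])
      }
    }
  }
  cbind(a = keep_a, len = keep_len, off = keep_off)
}

#' Simulate paired-end reads from a molecule mixture
#'
#' Fragments are drawn uniformly along molecules that are maternal (fully
#' excised) with probability `contamination`, otherwise new-MAC molecules
#' retaining each IES independently with its truth `retention_fraction`.
#' Substitution errors are i.i.d. per base; mates are FR-oriented. Outputs:
#' a FASTQ pair (`/1`, `/2` suffixes, constant Q30), the truth TSV, and
#' ideal-alignment SAM files against both references (soft-clips at junction
#' discontinuities, MAPQ 60).
#'
#' @param sim Result of [simulate_genome()].
#' @param truth Result of [simulation_truth()].
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param emit_sequences Write read sequences (FASTQ pair and SAM SEQ/QUAL
#'   columns). With `FALSE`, no FASTQ is written and SAM SEQ/QUAL are `*`:
#'   substitution errors only alter reported base strings, never the
#'   truth-derived alignments, so large classification-only runs can skip
#'   the string work.
#' @param seed Seed for the read-level randomness; defaults to a value
#'   derived from `config$seed`. Give different seeds to draw independent
#'   samples (e.g. control vs experiment) from one simulated genome.
#' @return A list with the output `paths` and `n_fragments`.
#' @export
simulate_reads <- function(sim, truth, out_dir, prefix = "sim",
                           emit_sequences = TRUE, seed = NULL) {
  config <- sim$config
  if (config$insert_mean < config$read_length) {
    stop("insert size must be >= read length", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cvec <- unique(truth$contamination)
  stopifnot(length(cvec) == 1L)
  contam <- cvec
  rl <- config$read_length
  macies <- sim$mac_plus_ies
  contigs <- names(macies)
  widths <- Biostrings::width(macies)
  macies_str <- as.character(macies)
  # per-contig junction tables in MAC+IES coordinates
  per <- lapply(contigs, function(ctg) {
    rows <- sim$map[sim$map$contig == ctg, , drop = FALSE]
    rows <- rows[order(rows$lifted_start), , drop = FALSE]
    r <- truth$retention_fraction[match(rows$ies_id, truth$ies_id)]
    list(glift = rows$lifted_start,
         gend = rows$lifted_start + rows$ies_length - 1L,
         L = rows$ies_length, r = r,
         cumL = c(0L, cumsum(rows$ies_length)))
  })
  names(per) <- contigs

  if (is.null(seed)) seed <- config$seed + 500009L
  with_seed(seed, {
    n_frag <- max(1L, round(config$depth * sum(widths) / (2 * rl)))
    qname <- sprintf("%s:f%07d", prefix, seq_len(n_frag))
    ctg_i <- sample.int(length(contigs), n_frag, replace = TRUE,
                        prob = widths / sum(widths))
    m <- pmax(rl, as.integer(round(stats::rnorm(n_frag, config$insert_mean,
                                                config$insert_sd))))
    m <- pmin(m, widths[ctg_i] - 1L)
    x <- as.integer(floor(stats::runif(n_frag) * (widths[ctg_i] - m + 1))) + 1L
    maternal <- stats::runif(n_frag) < contam

    # classify fragments: simple = no overlap with any IES interval
    complex <- logical(n_frag)
    shift0 <- integer(n_frag)
    for (ci in seq_along(contigs)) {
      idx <- which(ctg_i == ci)
      p <- per[[ci]]
      if (length(p$glift) == 0L || length(idx) == 0L) next
      i1 <- findInterval(x[idx] + m[idx] - 1L, p$glift)
      i2 <- findInterval(x[idx] - 1L, p$gend)
      complex[idx] <- i1 > i2
      shift0[idx] <- p$cumL[i2 + 1L]
    }

    keep <- rep(TRUE, n_frag)
    # per fragment, per read (1/2), per reference: pos, left offset, M length
    na_i <- rep(NA_integer_, n_frag)
    pos_p1 <- na_i; lo_p1 <- na_i; len_p1 <- na_i   # read1 vs MAC+IES
    pos_p2 <- na_i; lo_p2 <- na_i; len_p2 <- na_i   # read2 vs MAC+IES
    pos_m1 <- na_i; lo_m1 <- na_i; len_m1 <- na_i   # read1 vs MAC
    pos_m2 <- na_i; lo_m2 <- na_i; len_m2 <- na_i   # read2 vs MAC
    seq1 <- rep("*", n_frag); seq2 <- rep("*", n_frag)
    qual <- if (emit_sequences) strrep("?", rl) else "*"

    # simple fragments: identical on both references, full-length matches
    si <- which(!complex)
    if (length(si)) {
      pos_p1[si] <- x[si]; pos_p2[si] <- x[si] + m[si] - rl
      pos_m1[si] <- x[si] - shift0[si]; pos_m2[si] <- pos_p2[si] - shift0[si]
      lo_p1[si] <- lo_p2[si] <- lo_m1[si] <- lo_m2[si] <- 0L
      len_p1[si] <- len_p2[si] <- len_m1[si] <- len_m2[si] <- rl
      if (emit_sequences) {
        frag_seq <- substring(macies_str[ctg_i[si]], x[si],
                              x[si] + m[si] - 1L)
        seq1[si] <- substring(frag_seq, 1L, rl)
        seq2[si] <- substring(frag_seq, m[si] - rl + 1L, m[si])
      }
    }

    # complex fragments: walk blocks, slice reads, derive ideal alignments
    min_match <- 15L
    for (i in which(complex)) {
      ci <- ctg_i[i]
      p <- per[[ci]]
      ctg_len <- widths[ci]
      blocks <- NULL
      for (try in 1:50) {
        xi <- x[i]
        k0 <- findInterval(xi, p$glift)
        if (k0 >= 1L && xi <= p$gend[k0]) {
          # start inside IES k0: position exists only in retaining molecules
          if (stats::runif(1) >= (1 - contam) * p$r[k0]) {
            x[i] <- as.integer(floor(stats::runif(1) *
                                       (ctg_len - m[i] + 1))) + 1L
            next
          }
          maternal[i] <- FALSE
        }
        blocks <- walk_fragment(xi, m[i], maternal[i], p$glift, p$gend,
                                p$r, ctg_len)
        break
      }
      if (is.null(blocks)) { keep[i] <- FALSE; next }
      s1 <- slice_blocks(blocks, 1L, rl)
      s2 <- slice_blocks(blocks, m[i] - rl + 1L, m[i])
      if (emit_sequences) {
        seq1[i] <- paste(substring(macies_str[ci], s1[, "a"], s1[, "b"]),
                         collapse = "")
        seq2[i] <- paste(substring(macies_str[ci], s2[, "a"], s2[, "b"]),
                         collapse = "")
      }
      # MAC+IES: kept intervals are themselves the contiguous match runs
      w1 <- s1[, "b"] - s1[, "a"] + 1L
      j <- which.max(w1)
      if (w1[j] >= min_match) {
        pos_p1[i] <- s1[j, "a"]; lo_p1[i] <- s1[j, "off"] - 1L
        len_p1[i] <- w1[j]
      }
      w2 <- s2[, "b"] - s2[, "a"] + 1L
      j <- which.max(w2)
      if (w2[j] >= min_match) {
        pos_p2[i] <- s2[j, "a"]; lo_p2[i] <- s2[j, "off"] - 1L
        len_p2[i] <- w2[j]
      }
      r1 <- mac_runs(s1, p$glift, p$gend, p$cumL)
      if (!is.null(r1)) {
        j <- which.max(r1[, "len"])
        if (r1[j, "len"] >= min_match) {
          pos_m1[i] <- r1[j, "a"]; lo_m1[i] <- r1[j, "off"] - 1L
          len_m1[i] <- r1[j, "len"]
        }
      }
      r2 <- mac_runs(s2, p$glift, p$gend, p$cumL)
      if (!is.null(r2)) {
        j <- which.max(r2[, "len"])
        if (r2[j, "len"] >= min_match) {
          pos_m2[i] <- r2[j, "a"]; lo_m2[i] <- r2[j, "off"] - 1L
          len_m2[i] <- r2[j, "len"]
        }
      }
    }

    # substitution errors, applied identically to FASTQ and SAM sequences
    err <- config$substitution_error_rate
    if (emit_sequences && err > 0) {
      bases <- c("A", "C", "G", "T")
      for (sv in c("seq1", "seq2")) {
        seqs <- get(sv)
        ne <- stats::rbinom(n_frag, rl, err)
        ne[!keep] <- 0L
        reps <- rep.int(seq_len(n_frag), ne)
        if (length(reps)) {
          at <- sample.int(rl, length(reps), replace = TRUE)
          hop <- sample.int(3L, length(reps), replace = TRUE)
          while (length(reps)) {
            first <- !duplicated(reps)
            r <- reps[first]; a <- at[first]; h <- hop[first]
            s <- seqs[r]
            cur <- substr(s, a, a)
            idx4 <- match(cur, bases)
            idx4[is.na(idx4)] <- 1L      # N bases: substitute from A
            substr(s, a, a) <- bases[(idx4 + h - 1L) %% 4L + 1L]
            seqs[r] <- s
            reps <- reps[!first]; at <- at[!first]; hop <- hop[!first]
          }
        }
        assign(sv, seqs)
      }
    }

    paths <- list(
      truth = file.path(out_dir, paste0(prefix, "_truth.tsv")),
      mac_sam = file.path(out_dir, paste0(prefix, "_mac.sam")),
      mac_plus_ies_sam = file.path(out_dir,
                                   paste0(prefix, "_mac_plus_ies.sam"))
    )
    ki <- which(keep)
    if (emit_sequences) {
      paths$fastq1 <- file.path(out_dir, paste0(prefix, "_R1.fastq"))
      paths$fastq2 <- file.path(out_dir, paste0(prefix, "_R2.fastq"))
      writeLines(paste0("@", qname[ki], "/1\n", seq1[ki], "\n+\n", qual),
                 paths$fastq1)
      writeLines(paste0("@", qname[ki], "/2\n", revcomp(seq2[ki]), "\n+\n",
                        qual), paths$fastq2)
    }
    write_tsv(truth, paths$truth)

    rn <- contigs[ctg_i]
    sam_body <- function(pos, lo, len, flag, seqs) {
      ok <- keep & !is.na(len)
      ro <- rl - lo[ok] - len[ok]
      cigar <- paste0(ifelse(lo[ok] > 0L, paste0(lo[ok], "S"), ""),
                      len[ok], "M",
                      ifelse(ro > 0L, paste0(ro, "S"), ""))
      sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
              qname[ok], flag, rn[ok], pos[ok], cigar, seqs[ok], qual)
    }
    hdr_plus <- c("@HD\tVN:1.6\tSO:unknown",
                  sprintf("@SQ\tSN:%s\tLN:%d", contigs, widths))
    mac_widths <- Biostrings::width(sim$mac)
    hdr_mac <- c("@HD\tVN:1.6\tSO:unknown",
                 sprintf("@SQ\tSN:%s\tLN:%d", names(sim$mac), mac_widths))
    writeLines(c(hdr_mac,
                 sam_body(pos_m1, lo_m1, len_m1, 99L, seq1),
                 sam_body(pos_m2, lo_m2, len_m2, 147L, seq2)),
               paths$mac_sam)
    writeLines(c(hdr_plus,
                 sam_body(pos_p1, lo_p1, len_p1, 99L, seq1),
                 sam_body(pos_p2, lo_p2, len_p2, 147L, seq2)),
               paths$mac_plus_ies_sam)
    list(paths = paths, n_fragments = length(ki))
  })
}
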