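# Boundary classification: window rules on single alignments, and per-IES
# counting from SAM fixtures.

test_that("MAC junction classification follows the anchor window", {
  cfg <- classifier_config(anchor = 5L)
  j <- 200L
  centered <- list(pos = 150L, cigar = "100M", mapq = 60L, flag = 0L)
  expect_identical(classify_on_mac(centered, j, cfg), "IES_MINUS")

  ends_at_junction <- list(pos = 101L, cigar = "100M", mapq = 60L, flag = 0L)
  expect_identical(classify_on_mac(ends_at_junction, j, cfg), "NONE")

  # insertion inside the 12 bp window breaks the match
  ins_inside <- list(pos = 150L, cigar = "52M2I46M", mapq = 60L, flag = 0L)
  expect_identical(classify_on_mac(ins_inside, j, cfg), "NONE")
  cfg_tol <- classifier_config(anchor = 5L, require_no_indel = FALSE)
  expect_identical(classify_on_mac(ins_inside, j, cfg_tol), "IES_MINUS")

  # a deletion removes reference coverage regardless of the indel rule
  del_inside <- list(pos = 150L, cigar = "52M3D45M", mapq = 60L, flag = 0L)
  expect_identical(classify_on_mac(del_inside, j, cfg_tol), "NONE")

  # low MAPQ and non-primary alignments never classify
  expect_identical(classify_on_mac(modifyList(centered, list(mapq = 0L)),
                                   j, cfg), "NONE")
  expect_identical(classify_on_mac(modifyList(centered, list(flag = 256L)),
                                   j, cfg), "NONE")
})

test_that("MAC+IES boundary classification counts only IES ends", {
  cfg <- classifier_config(anchor = 5L)
  bounds <- c(1000L, 1299L)  # 300 bp IES

  left_2080 <- list(pos = 981L, cigar = "100M", mapq = 60L, flag = 0L)
  expect_identical(classify_on_mac_plus_ies(left_2080, bounds, cfg),
                   "IES_PLUS")

  inside <- list(pos = 1100L, cigar = "100M", mapq = 60L, flag = 0L)
  expect_identical(classify_on_mac_plus_ies(inside, bounds, cfg), "NONE")

  right_only <- list(pos = 1250L, cigar = "100M", mapq = 60L, flag = 0L)
  expect_identical(classify_on_mac_plus_ies(right_only, bounds, cfg),
                   "IES_PLUS")

  # soft-clipped bases never count toward anchors
  clipped <- list(pos = 998L, cigar = "8S92M", mapq = 60L, flag = 0L)
  expect_identical(classify_on_mac_plus_ies(clipped, bounds, cfg), "NONE")

  # both boundaries of a short IES in one read
  short_bounds <- c(1000L, 1027L)
  spanning <- list(pos = 970L, cigar = "100M", mapq = 60L, flag = 0L)
  expect_identical(classify_on_mac_plus_ies(spanning, short_bounds, cfg),
                   "IES_PLUS")
})

test_that("hand-built SAM fixture counts as manually classified", {
  fx <- fixture_one_ies()
  g <- fx$map$lifted_start[1]           # 200
  e <- g + fx$map$ies_length[1] - 1L    # 227
  # 3 junction-spanning MAC records
  mac_rec <- data.frame(
    qname = c("m1", "m2", "m3"), flag = c(0L, 0L, 0L), rname = "chr",
    pos = c(150L, 160L, 196L), mapq = 60L, cigar = "100M",
    stringsAsFactors = FALSE)
  # 2 records each spanning BOTH boundaries of the 28 bp IES: each counts
  # once in each boundary tally, i.e. once in the averaged IES+ count
  plus_rec <- data.frame(
    qname = c("p1", "p2"), flag = c(0L, 0L), rname = "chr",
    pos = c(170L, 180L), mapq = 60L, cigar = "100M",
    stringsAsFactors = FALSE)
  mac_sam <- write_sam_fixture(mac_rec, c(chr = 400L))
  plus_sam <- write_sam_fixture(plus_rec, c(chr = 428L))
  cnt <- count_boundaries(mac_sam, plus_sam, fx$ann, fx$map)
  expect_equal(cnt$ies_plus, 2L)
  expect_equal(cnt$ies_minus, 3L)
})

test_that("counts are invariant under record order and respect uniqueness", {
  fx <- fixture_one_ies()
  mac_rec <- data.frame(
    qname = sprintf("r%d", 1:6),
    flag = c(0L, 0L, 256L, 0L, 4L, 0L), rname = "chr",
    pos = c(150L, 160L, 170L, 180L, 190L, 196L),
    mapq = c(60L, 60L, 60L, 0L, 60L, 60L), cigar = "100M",
    stringsAsFactors = FALSE)
  # r3 secondary, r4 mapq 0, r5 unmapped -> only r1, r2, r6 count
  plus_rec <- data.frame(qname = "p1", flag = 0L, rname = "chr",
                         pos = 170L, mapq = 60L, cigar = "100M",
                         stringsAsFactors = FALSE)
  plus_sam <- write_sam_fixture(plus_rec, c(chr = 428L))

  cnt_a <- count_boundaries(write_sam_fixture(mac_rec, c(chr = 400L)),
                            plus_sam, fx$ann, fx$map)
  cnt_b <- count_boundaries(
    write_sam_fixture(mac_rec[sample.int(6), ], c(chr = 400L)),
    plus_sam, fx$ann, fx$map)
  expect_equal(cnt_a$ies_minus, 3L)
  expect_identical(cnt_a[, c("ies_plus", "ies_minus")],
                   cnt_b[, c("ies_plus", "ies_minus")])

  # the same mate of the same read never counts twice per IES
  dup_rec <- mac_rec[c(1, 1), ]
  cnt_c <- count_boundaries(write_sam_fixture(dup_rec, c(chr = 400L)),
                            plus_sam, fx$ann, fx$map)
  expect_equal(cnt_c$ies_minus, 1L)
})

test_that("a read in both categories for one IES is dropped and logged", {
  fx <- fixture_one_ies()
  shared <- data.frame(qname = "dup", flag = 0L, rname = "chr",
                       pos = 170L, mapq = 60L, cigar = "100M",
                       stringsAsFactors = FALSE)
  other_minus <- data.frame(qname = "solo", flag = 0L, rname = "chr",
                            pos = 196L, mapq = 60L, cigar = "100M",
                            stringsAsFactors = FALSE)
  cnt <- count_boundaries(
    write_sam_fixture(rbind(shared, other_minus), c(chr = 400L)),
    write_sam_fixture(shared, c(chr = 428L)),
    fx$ann, fx$map)
  expect_equal(cnt$ies_minus, 1L)   # only "solo" survives
  expect_equal(cnt$ies_plus, 0L)
  dropped <- attr(cnt, "dropped")
  expect_equal(dropped$read_id, "dup")
})

test_that("missing contigs in the alignment header raise a named error", {
  fx <- fixture_one_ies()
  rec <- data.frame(qname = "x", flag = 0L, rname = "other",
                    pos = 10L, mapq = 60L, cigar = "50M",
                    stringsAsFactors = FALSE)
  sam_wrong <- write_sam_fixture(rec, c(other = 1000L))
  expect_error(count_boundaries(sam_wrong, sam_wrong, fx$ann, fx$map), "chr")
})

test_that("simulated truth recovers through the classifier (r = 1, r = 0)", {
  sim <- small_sim(seed = 71, n_ies = 25, contig_length = 20000L, depth = 25)
  t_ret <- simulation_truth(sim$annotations, retention = 1)
  rd <- simulate_reads(sim, t_ret, tempfile(), emit_sequences = FALSE)
  cnt <- count_boundaries(rd$paths$mac_sam, rd$paths$mac_plus_ies_sam,
                          sim$annotations, sim$map)
  expect_true(all(cnt$ies_minus == 0L))

  t_exc <- simulation_truth(sim$annotations, retention = 0)
  rd0 <- simulate_reads(sim, t_exc, tempfile(), emit_sequences = FALSE)
  cnt0 <- count_boundaries(rd0$paths$mac_sam, rd0$paths$mac_plus_ies_sam,
                           sim$annotations, sim$map)
  expect_true(all(cnt0$ies_plus == 0L))
})
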