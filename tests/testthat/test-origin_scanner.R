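# ORB scanning, AT-rich cores, inverted-pair candidates, enhancers,
# titration clusters, and initiator-adjacency classification.

test_that("a poly-A genome has no ORB hits", {
  g <- genome_assembly(replicon("chr", strrep("A", 10000)))
  expect_equal(nrow(scan_orbs(g)), 0L)
})

test_that("scan_orbs matches the brute-force Hamming oracle", {
  consensus <- "TTCCAGTGGRAACGAAAGGG"  # degenerate position exercises IUPAC
  withr::with_seed(101, {
    for (rep in 1:6) {
      s <- planted_scan_sequence(5000L, consensus)
      g <- genome_assembly(replicon("chr", s))
      got <- scan_orbs(g, consensus = consensus, max_mismatch = 3L)
      want <- oracle_resolve_overlaps(
        oracle_hamming_scan(s, consensus, 3L))
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$strand, want$strand)
      expect_equal(got$mismatches, want$mismatches)
    }
  })
})

test_that("Ns in the genome never match the consensus", {
  cons <- default_orb_consensus()
  seq_ok <- paste0(strrep("A", 100), cons, strrep("A", 100))
  seq_n <- seq_ok
  substr(seq_n, 105, 108) <- "NNNN"
  expect_equal(nrow(scan_orbs(genome_assembly(replicon("c", seq_ok)),
                              max_mismatch = 0L)), 1L)
  expect_equal(nrow(scan_orbs(genome_assembly(replicon("c", seq_n)),
                              max_mismatch = 3L)), 0L)
})

test_that("scanning the reverse-complemented genome mirrors the hit set", {
  withr::with_seed(113, s <- planted_scan_sequence(4000L,
                                                   default_orb_consensus()))
  L <- nchar(s)
  h_fwd <- scan_orbs(genome_assembly(replicon("chr", s)))
  h_rev <- scan_orbs(genome_assembly(replicon("chr", oracle_revcomp(s))))
  mirrored <- data.frame(start = sort(L - h_rev$end))
  expect_equal(sort(h_fwd$start), mirrored$start)
  key <- function(h) {
    o <- order(h$start)
    paste(h$mismatches[o], collapse = ",")
  }
  h_rev$start <- L - h_rev$end
  expect_equal(key(h_fwd), key(h_rev))
})

test_that("hits across the circular seam are found once", {
  cons <- default_orb_consensus()
  # split the motif across the end/start junction
  s <- paste0(substr(cons, 11, 20), strrep("A", 500), substr(cons, 1, 10))
  h <- scan_orbs(genome_assembly(replicon("chr", s)), max_mismatch = 0L)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 510L)
})

test_that("G-strings are detected strand-aware and ablated by mutation", {
  g <- build_mimic_genome("hhis_oriC1_mimic")
  hits <- scan_orbs(g)
  locus <- g$ground_truth[g$ground_truth$type == "origin_locus", ]
  at_locus <- hits[hits$start >= locus$start & hits$end <= locus$end, ]
  expect_equal(nrow(at_locus), 2L)
  expect_true(all(at_locus$has_gstring))
  # planted run is 8 G; a random flanking G may extend the measured run
  expect_true(all(at_locus$gstring_len >= 8L))
  # ablating either G-string removes exactly one gstring-bearing ORB
  for (site in c("oriC1m.gstring_I", "oriC1m.gstring_II")) {
    row <- g$ground_truth[g$ground_truth$element_id == site, ]
    repl <- strrep(if (row$strand == "+") "A" else "T", row$end - row$start)
    gm <- apply_site_mutation(g, site, repl)
    hm <- scan_orbs(gm)
    expect_equal(sum(hm$has_gstring), sum(hits$has_gstring) - 1L)
    expect_equal(nrow(hm), nrow(hits))  # the boxes themselves remain
  }
})

test_that("find_at_rich recovers planted cores and saturates on all-AT", {
  all_at <- replicon("x", strrep("AT", 500))
  r <- find_at_rich(all_at)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(0L, 1000L))
  # planted 150 bp core at 85% AT in a 60% GC background
  withr::with_seed(211, {
    bg <- random_dna(3000, gc = 0.6)
    core <- paste(sample(c("A", "T", "G"), 150, replace = TRUE,
                         prob = c(0.45, 0.4, 0.15)), collapse = "")
    substr(bg, 1501, 1650) <- core
  })
  regions <- find_at_rich(replicon("chr", bg))
  hit <- regions$start < 1650 & regions$end > 1500
  expect_true(any(hit))
  # the planted core is the dominant region
  expect_equal(which.max(regions$at_fraction), which(hit))
})

test_that("inverted pairing finds planted loci and rejects strand chaos", {
  # no opposite-strand pair -> no candidates
  h <- data.frame(replicon_id = "chr", start = c(0L, 500L),
                  end = c(20L, 520L), strand = c("+", "+"),
                  mismatches = 0L, has_gstring = TRUE, gstring_len = 8L)
  expect_equal(nrow(pair_inverted_orbs(h, data.frame(start = 0L, end = 600L,
                                                     at_fraction = 0.9))),
               0L)
  g <- build_mimic_genome("hhis_oriC1_mimic")
  cands <- pair_inverted_orbs(scan_orbs(g),
                              lapply(g$replicons, find_at_rich))
  locus <- g$ground_truth[g$ground_truth$type == "origin_locus", ]
  expect_equal(nrow(cands), 1L)
  expect_lte(cands$start, locus$start)
  expect_gte(cands$end, locus$end)
})

test_that("candidate lists recover both chromosomal origin analogs", {
  specs <- list(origin_architecture("ori1", enhancer_arm = "GGGGAGGGGG"),
                origin_architecture("ori2", titration_orb_count = 11L,
                                    titration_region_len = 722L))
  g <- build_genome(specs, c(chr = 120000L), seed = 55,
                    spec_replicon = c(1, 1),
                    origin_positions = c(30000L, 90000L))
  cands <- classify_candidates(
    pair_inverted_orbs(scan_orbs(g), lapply(g$replicons, find_at_rich)), g)
  expect_equal(nrow(cands), 2L)
  loci <- g$ground_truth[g$ground_truth$type == "origin_locus", ]
  for (i in 1:2) {
    expect_true(any(cands$start <= loci$start[i] &
                      cands$end >= loci$end[i]))
  }
  expect_true(all(cands$classification == "ori_cdc6"))
})

test_that("find_enhancer reports the planted G-rich repeat exactly", {
  g <- build_mimic_genome("hhis_oriC1_mimic")
  seqchr <- g$replicons$chr_mimic$sequence
  cands <- pair_inverted_orbs(scan_orbs(g),
                              lapply(g$replicons, find_at_rich))
  enh <- find_enhancer(cands[1, ], seqchr)
  expect_equal(enh$arm_len, 10L)
  left <- substr(seqchr, enh$left_start + 1, enh$left_end)
  right <- substr(seqchr, enh$right_start + 1, enh$right_end)
  expect_identical(left, "GGGGAGGGGG")
  expect_identical(right, "CCCCCTCCCC")
  expect_identical(right, revcomp(left))
  expect_gte(enh$g_fraction, 0.8)
  # poly-A interval has none
  expect_null(find_enhancer(interval_candidate(strrep("A", 200)),
                            strrep("A", 200)))
})

test_that("mutating either enhancer arm abolishes the call", {
  g <- build_mimic_genome("hhis_oriC1_mimic")
  for (case in list(c("oriC1m.enhancer_III", "AAAAGAAAAA"),
                    c("oriC1m.enhancer_IV", "TTTTTCTTTT"))) {
    gm <- apply_site_mutation(g, case[1], case[2])
    cands <- pair_inverted_orbs(scan_orbs(gm),
                                lapply(gm$replicons, find_at_rich))
    expect_equal(nrow(cands), 1L)
    expect_null(find_enhancer(cands[1, ], gm$replicons$chr_mimic$sequence))
  }
})

test_that("find_enhancer matches the all-substring-pairs oracle", {
  withr::with_seed(307, {
    for (rep in 1:8) {
      s <- random_dna(150)
      if (rep %% 2 == 0) {
        # plant a G-rich inverted repeat with a random loop
        arm <- paste(sample(c("G", "A"), 11, replace = TRUE,
                            prob = c(0.9, 0.1)), collapse = "")
        substr(s, 20, 30) <- arm
        substr(s, 90, 100) <- oracle_revcomp(arm)
      }
      got <- find_enhancer(interval_candidate(s), s)
      want <- oracle_longest_gir(s)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got$arm_len, want$arm_len)
        expect_equal(got$left_start, want$left_start)
        expect_equal(got$right_start, want$right_start)
        expect_equal(got$g_fraction, want$g_fraction)
      }
    }
  })
})

test_that("titration clusters are counted and located correctly", {
  g11 <- build_mimic_genome("hhis_oriC2_mimic")
  hits <- scan_orbs(g11)
  cands <- pair_inverted_orbs(hits, lapply(g11$replicons, find_at_rich))
  titr <- find_titration_regions(hits, cands, g11$features)
  expect_equal(nrow(titr), 1L)
  expect_equal(titr$orb_count, 11L)
  expect_true(titr$intergenic)
  gene <- g11$ground_truth[g11$ground_truth$type == "cdc6_gene", ]
  expect_gt(titr$start, gene$end)  # downstream of the cdc6-analog
  g3 <- build_mimic_genome("hla_oriC2_mimic")
  h3 <- scan_orbs(g3)
  t3 <- find_titration_regions(
    h3, pair_inverted_orbs(h3, lapply(g3$replicons, find_at_rich)),
    g3$features)
  expect_equal(t3$orb_count, 3L)
  # a genome without a planted cluster yields none
  g0 <- build_mimic_genome("hhis_oriC1_mimic")
  h0 <- scan_orbs(g0)
  t0 <- find_titration_regions(
    h0, pair_inverted_orbs(h0, lapply(g0$replicons, find_at_rich)),
    g0$features)
  expect_equal(nrow(t0), 0L)
})

test_that("classification keys on circular initiator adjacency", {
  g <- build_mimic_genome("hhis_oriC1_mimic")
  cands <- classify_candidates(
    pair_inverted_orbs(scan_orbs(g), lapply(g$replicons, find_at_rich)), g)
  expect_equal(cands$classification, "ori_cdc6")
  expect_lte(cands$initiator_distance, 2000)
  # strip the initiator: candidate becomes an orphan with no distance
  g_no <- g
  g_no$features <- empty_features <- g$features[0, ]
  cands2 <- classify_candidates(
    pair_inverted_orbs(scan_orbs(g_no),
                       lapply(g_no$replicons, find_at_rich)), g_no)
  expect_equal(cands2$classification, "orphan")
  expect_true(is.na(cands2$initiator_distance))
})

test_that("seven loci across three replicons are all recovered", {
  mk <- function(nm, ...) origin_architecture(nm, ...)
  specs <- list(mk("c1", enhancer_arm = "GGGGAGGGGG"),
                mk("c2", titration_orb_count = 11L,
                   titration_region_len = 722L),
                mk("m4"), mk("m5"), mk("m6"), mk("m7"), mk("p1"))
  g <- build_genome(specs,
                    c(chromosome = 120000L, minichromosome = 100000L,
                      pHH400 = 30000L),
                    seed = 77, spec_replicon = c(1, 1, 2, 2, 2, 2, 3))
  cands <- classify_candidates(
    pair_inverted_orbs(scan_orbs(g), lapply(g$replicons, find_at_rich)), g)
  expect_equal(nrow(cands), 7L)
  expect_true(all(cands$classification == "ori_cdc6"))
  loci <- g$ground_truth[g$ground_truth$type == "origin_locus", ]
  for (i in seq_len(nrow(loci))) {
    expect_true(any(cands$replicon_id == loci$replicon_id[i] &
                      cands$start <= loci$start[i] &
                      cands$end >= loci$end[i]))
  }
})
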