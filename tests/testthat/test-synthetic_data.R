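# Genome builder, site mutagenesis, probe designer, and the population
# marker-frequency simulator.

test_that("architecture specs validate their invariants", {
  expect_error(origin_architecture("x", at_core_fraction = 0.4), "0.5")
  expect_error(origin_architecture("x", titration_orb_count = 11,
                                   titration_region_len = 100),
               "too small")
  expect_error(origin_architecture("x", orb_consensus = "ACGT"), ">= 10")
})

test_that("build_genome is deterministic under a fixed seed", {
  sp <- origin_architecture("o")
  g1 <- build_genome(sp, c(chr = 20000L), seed = 42)
  g2 <- build_genome(sp, c(chr = 20000L), seed = 42)
  g3 <- build_genome(sp, c(chr = 20000L), seed = 43)
  expect_identical(g1$replicons$chr$sequence, g2$replicons$chr$sequence)
  expect_identical(g1$ground_truth, g2$ground_truth)
  expect_false(identical(g1$replicons$chr$sequence,
                         g3$replicons$chr$sequence))
})

test_that("minimal locus plants ORB / AT core / inverted ORB in order", {
  sp <- origin_architecture("o")  # no enhancer, no titration cluster
  g <- build_genome(sp, c(chr = 20000L), seed = 5)
  gt <- g$ground_truth
  expect_false(any(gt$type %in% c("enhancer_arm", "titration_orb",
                                  "titration_region")))
  orbs <- gt[gt$type == "orb", ]
  core <- gt[gt$type == "at_core", ]
  expect_equal(nrow(orbs), 2L)
  expect_identical(orbs$strand, c("+", "-"))
  expect_true(orbs$end[1] < core$start && core$end < orbs$start[2])
  # the planted core really is AT-rich at the configured fraction
  core_seq <- substr(g$replicons$chr$sequence, core$start + 1, core$end)
  at <- mean(strsplit(core_seq, "")[[1]] %in% c("A", "T"))
  expect_gt(at, 0.75)
})

test_that("the titration-cluster fixture plants 11 ORBs in 722 bp", {
  g <- build_mimic_genome("hhis_oriC2_mimic")
  gt <- g$ground_truth
  expect_equal(sum(gt$type == "titration_orb"), 11L)
  reg <- gt[gt$type == "titration_region", ]
  expect_equal(reg$end - reg$start, 722L)
  torb <- gt[gt$type == "titration_orb", ]
  expect_true(all(torb$start >= reg$start & torb$end <= reg$end))
  # downstream of the cdc6 gene, and non-overlapping
  gene <- gt[gt$type == "cdc6_gene", ]
  expect_gt(reg$start, gene$end)
  torb <- torb[order(torb$start), ]
  expect_true(all(torb$start[-1] >= torb$end[-nrow(torb)]))
})

test_that("build_genome rejects loci that do not fit or overlap", {
  sp <- origin_architecture("o")
  expect_error(build_genome(sp, c(chr = 1000L), seed = 1), "does not fit")
  expect_error(
    build_genome(list(sp, origin_architecture("p")), c(chr = 50000L),
                 seed = 1, spec_replicon = c(1, 1),
                 origin_positions = c(10000L, 10100L)),
    "overlap")
})

test_that("apply_site_mutation changes exactly the site's bases", {
  g <- build_mimic_genome("hhis_oriC1_mimic")
  gt <- g$ground_truth
  site <- gt[gt$element_id == "oriC1m.gstring_I", ]
  width <- site$end - site$start
  gm <- apply_site_mutation(g, "oriC1m.gstring_I", strrep("A", width))
  s0 <- strsplit(g$replicons$chr_mimic$sequence, "")[[1]]
  s1 <- strsplit(gm$replicons$chr_mimic$sequence, "")[[1]]
  diffs <- which(s0 != s1)
  expect_equal(length(diffs), width)  # positionwise diff oracle
  expect_true(all(diffs > site$start & diffs <= site$end))
  # identity replacement leaves the assembly unchanged
  orig <- substr(g$replicons$chr_mimic$sequence, site$start + 1, site$end)
  expect_identical(
    apply_site_mutation(g, "oriC1m.gstring_I", orig)$replicons,
    g$replicons)
  expect_error(apply_site_mutation(g, "oriC1m.gstring_I", "AAA"), "length")
  expect_error(apply_site_mutation(g, "no_such_site", "AAA"), "unknown")
})

test_that("probe designer yields constant-length probes at density", {
  # gene-free 100 kb replicon: at least one 60-mer per kb
  g <- genome_assembly(replicon("chr", random_dna(100000)))
  d <- withr::with_seed(3, design_probes(g, seed = 3))
  expect_gte(nrow(d), 100L)
  expect_true(all(d$length == 60L))
  # 1 kb replicon still gets a probe
  g1 <- genome_assembly(replicon("mini", random_dna(1000)))
  expect_gte(nrow(design_probes(g1, seed = 1)), 1L)
  # exhaustive circular 1-kb window check
  L <- 100000L
  pos <- sort(d$position)
  for (s in seq(0, L - 1, by = 250)) {
    e <- s + 1000
    n_in <- if (e <= L) sum(pos >= s & pos < e)
            else sum(pos >= s) + sum(pos < e - L)
    expect_gte(n_in, 1L)
  }
})

test_that("instant-fork limit gives ratio 2 at every probe", {
  g <- genome_assembly(replicon("chr", random_dna(20000)))
  d <- design_probes(g, seed = 2)
  prog <- replication_program(
    data.frame(position = 10000, firing_prob = 1),
    fork_speed = 1e12, doubling_time = 60,
    replicon_id = "chr", replicon_length = 20000)
  sig <- simulate_marker_frequency(prog, d, n_cells = 2000, noise_cv = 0,
                                   n_replicates = 1, seed = 9)
  prof <- make_profile(sig)
  expect_true(all(abs(prof$ratio - 2) < 1e-6))
})

test_that("simulated means converge to the closed form as cells grow", {
  L <- 50000L
  tau <- 60
  v <- (L / 2) / tau  # terminus replicates exactly at tau
  g <- genome_assembly(replicon("chr", random_dna(L)))
  d <- design_probes(g, seed = 4)
  prog <- replication_program(
    data.frame(position = 25000, firing_prob = 1),
    fork_speed = v, doubling_time = tau,
    replicon_id = "chr", replicon_length = L)
  m_closed <- 2^(1 - (circular_distance(d$position, 25000, L) / v) / tau)
  devs <- vapply(c(500L, 2000L, 8000L), function(n) {
    sig <- simulate_marker_frequency(prog, d, n_cells = n, noise_cv = 0,
                                     n_replicates = 1, seed = n)
    max(abs(make_profile(sig)$ratio - m_closed))
  }, numeric(1))
  # Monte-Carlo error scales as 1/sqrt(n): bounded at each n, and smaller
  # at the largest n than at the smallest
  expect_true(all(devs <= 3.5 * 0.5 / sqrt(c(500, 2000, 8000))))
  expect_lt(devs[3], devs[1])
})

test_that("noiseless log2 profiles decay linearly at slope 1/(v tau)", {
  L <- 60000L
  tau <- 80
  v <- 400
  g <- genome_assembly(replicon("chr", random_dna(L)))
  d <- design_probes(g, seed = 6)
  prog <- replication_program(
    data.frame(position = 0, firing_prob = 1),
    fork_speed = v, doubling_time = tau,
    replicon_id = "chr", replicon_length = L)
  sig <- simulate_marker_frequency(prog, d, n_cells = 60000, noise_cv = 0,
                                   n_replicates = 1, seed = 8)
  prof <- make_profile(sig)
  flank <- prof$positions > 2000 & prof$positions < 28000  # one replichore
  fit <- lm(log2(prof$ratio[flank]) ~ prof$positions[flank])
  expect_equal(unname(coef(fit)[2]), -1 / (v * tau), tolerance = 0.05)
})

test_that("the simulator is deterministic under a fixed seed", {
  g <- genome_assembly(replicon("chr", random_dna(10000)))
  d <- design_probes(g, seed = 1)
  prog <- replication_program(
    data.frame(position = 5000, firing_prob = 1),
    fork_speed = 100, doubling_time = 60,
    replicon_id = "chr", replicon_length = 10000)
  s1 <- simulate_marker_frequency(prog, d, 500, 0.1, 2, seed = 77)
  s2 <- simulate_marker_frequency(prog, d, 500, 0.1, 2, seed = 77)
  expect_identical(s1, s2)
})

test_that("programs with nothing able to fire are rejected", {
  expect_error(
    replication_program(data.frame(position = 0, firing_prob = 0),
                        100, 60, "chr", 1000),
    "all firing probabilities are 0")
  expect_warning(
    replication_program(data.frame(position = 0, firing_prob = 0.5),
                        100, 60, "chr", 1000),
    "never replicate")
})
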