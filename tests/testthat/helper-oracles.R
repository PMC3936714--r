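# Independent brute-force oracles and small fixture builders. These
# re-derive results from first principles (plain character vectors, no
# Biostrings) so that they stay independent of the implementation paths
# they check.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

COMP_MAP <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
              R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
              B = "V", V = "B", D = "H", H = "D")

oracle_revcomp <- function(s) {
  paste(rev(COMP_MAP[strsplit(s, "")[[1]]]), collapse = "")
}

# Positionwise Hamming scan of an IUPAC pattern over a circular sequence,
# both strands; subject N never matches. Returns all raw hits.
oracle_hamming_scan <- function(sequence, consensus, max_mismatch) {
  L <- nchar(sequence)
  cl <- nchar(consensus)
  chv <- strsplit(sequence, "")[[1]]
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") consensus else oracle_revcomp(consensus)
    sets <- IUPAC_SETS[strsplit(pat, "")[[1]]]
    mm <- integer(L)
    for (k in seq_len(cl)) {
      idx <- ((seq_len(L) - 1L + k - 1L) %% L) + 1L
      mm <- mm + !(chv[idx] %in% sets[[k]])
    }
    ok <- which(mm <= max_mismatch) - 1L
    if (length(ok)) {
      hits[[strand]] <- data.frame(start = ok, end = ok + cl,
                                   strand = strand,
                                   mismatches = mm[ok + 1L],
                                   stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  }
  do.call(rbind, hits)
}

# The documented overlap-resolution rule, re-implemented independently:
# per strand, keep lowest-mismatch first (ties leftmost), greedily
# non-overlapping.
oracle_resolve_overlaps <- function(hits) {
  keep <- logical(nrow(hits))
  for (s in unique(hits$strand)) {
    idx <- which(hits$strand == s)
    ord <- idx[order(hits$mismatches[idx], hits$start[idx])]
    taken <- NULL
    for (i in ord) {
      if (is.null(taken) ||
          !any(hits$start[i] < taken[, 2] & taken[, 1] < hits$end[i])) {
        keep[i] <- TRUE
        taken <- rbind(taken, c(hits$start[i], hits$end[i]))
      }
    }
  }
  h <- hits[keep, , drop = FALSE]
  h <- h[order(h$start, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# All-substring-pairs search for the longest perfect G-rich inverted repeat
# in a linear interval: for each arm length (longest first), compare every
# left arm against the reverse complement of every right arm.
oracle_longest_gir <- function(s, arm_min = 8L, g_rich_min = 0.8) {
  n <- nchar(s)
  best <- NULL
  for (arm in rev(seq.int(arm_min, n %/% 2))) {
    starts <- seq_len(n - arm + 1L)
    arms <- substring(s, starts, starts + arm - 1L)
    rc <- vapply(arms, oracle_revcomp, character(1), USE.NAMES = FALSE)
    eq <- outer(arms, rc, "==")  # eq[i, j]: arm at i == revcomp(arm at j)
    for (i in starts) {
      js <- which(eq[i, ])
      js <- js[js >= i + arm]  # non-overlapping, left before right
      if (!length(js)) next
      ch <- strsplit(arms[i], "")[[1]]
      gf <- max(mean(ch == "G"), mean(ch == "C"))
      if (gf < g_rich_min) next
      j <- min(js)
      best <- list(arm_len = arm, left_start = i - 1L,
                   right_start = j - 1L, g_fraction = gf)
      break
    }
    if (!is.null(best)) break
  }
  best
}

# Stepwise walk in both directions around the circle.
oracle_circular_distance <- function(a, b, L) {
  fwd <- 0L
  x <- a
  while (x != b) {
    x <- (x + 1L) %% L
    fwd <- fwd + 1L
  }
  bwd <- 0L
  x <- a
  while (x != b) {
    x <- (x - 1L) %% L
    bwd <- bwd + 1L
  }
  min(fwd, bwd)
}

# Brute-force centred circular moving average.
oracle_circular_ma <- function(y, window) {
  n <- length(y)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(y[((i - 1L + seq.int(-h, h)) %% n) + 1L])
  }, numeric(1))
}

# Random sequence with ORB-like variants planted at known sites, so that
# scanner/oracle comparisons exercise hits on both sides of the mismatch
# threshold.
planted_scan_sequence <- function(L = 5000L, consensus, n_plant = 8L) {
  s <- random_dna(L)
  cl <- nchar(consensus)
  starts <- round(seq(100L, L - cl - 100L, length.out = n_plant))
  for (i in seq_len(n_plant)) {
    inst <- strsplit(consensus, "")[[1]]
    inst[inst == "R"] <- sample(c("A", "G"), sum(inst == "R"),
                                replace = TRUE)
    nmut <- sample(0:5, 1)
    if (nmut > 0) {
      at <- sample(cl, nmut)
      for (k in at) inst[k] <- sample(setdiff(c("A", "C", "G", "T"),
                                              inst[k]), 1)
    }
    inst <- paste(inst, collapse = "")
    if (runif(1) < 0.5) inst <- oracle_revcomp(inst)
    substr(s, starts[i], starts[i] + cl - 1L) <- inst
  }
  s
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# A bare candidate row whose inter-ORB interval is exactly [0, nchar(s)),
# for exercising find_enhancer on an arbitrary interval.
interval_candidate <- function(s) {
  list(orb_left_end = 0L, orb_left_gstring_len = 0L,
       orb_right_start = nchar(s), orb_right_gstring_len = 0L)
}

# A minimal single-replicon signal table built by hand.
manual_signals <- function(positions, exp_signal, stat_signal,
                           replicate = 1L, replicon_id = "chr",
                           replicon_length = NULL) {
  df <- data.frame(replicon_id = replicon_id, position = positions,
                   exp_signal = exp_signal, stat_signal = stat_signal,
                   replicate = replicate, stringsAsFactors = FALSE)
  attr(df, "replicon_length") <-
    if (is.null(replicon_length)) max(positions) + 1000L else replicon_length
  df
}
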