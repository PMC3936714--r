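# Sequence-level detection of the haloarchaeal origin architecture: ORB
# motif hits with G-string extensions, AT-rich cores, inverted ORB pairs,
# G-rich inverted-repeat enhancers, ORB-rich titration clusters, and
# cdc6-adjacency classification.

# Mismatches between a concrete subject window and an IUPAC pattern.
# Degenerate pattern codes match their base sets; a subject N never matches.
iupac_mismatches <- function(window, pattern_sets) {
  w <- strsplit(window, "")[[1]]
  sum(!mapply(function(b, set) b %in% set, w, pattern_sets,
              USE.NAMES = FALSE))
}

# Longest run of `base` reading rightwards from 0-based `start` (circular).
run_length_at <- function(sequence, start, base, max_run = 50L) {
  win <- strsplit(seq_window(sequence, start, max_run), "")[[1]]
  n <- match(FALSE, win == base, nomatch = max_run + 1L) - 1L
  as.integer(n)
}

#' Scan a genome for ORB elements
#'
#' Slides an IUPAC consensus over both strands of every replicon (the minus
#' strand via the reverse-complemented consensus) and reports every position
#' with at most `max_mismatch` mismatches. Degenerate consensus codes match
#' their base sets; an `N` in the genome never matches. Overlapping hits on
#' the same strand are resolved by keeping the lowest-mismatch hit (ties:
#' leftmost). Circular replicons are additionally scanned across the origin
#' seam.
#'
#' Each hit's strand-aware 3' flank is inspected for the halophile-specific
#' G-string: `has_gstring` is `TRUE` when at least `gstring_min` consecutive
#' guanines (on the hit's own strand) follow the box, and `gstring_len`
#' records the full run length.
#'
#' @param assembly A [genome_assembly()].
#' @param consensus IUPAC consensus, G-rich strand, length >= 10.
#' @param max_mismatch Maximum mismatches per hit.
#' @param gstring_min Minimum G-run length to call a G-string.
#' @return An `ORBHit` data frame: `replicon_id`, `start`, `end` (0-based
#'   half-open), `strand`, `mismatches`, `has_gstring`, `gstring_len`.
#' @export
scan_orbs <- function(assembly, consensus = default_orb_consensus(),
                      max_mismatch = 3L, gstring_min = 6L) {
  stopifnot(inherits(assembly, "GenomeAssembly"))
  consensus <- toupper(consensus)
  if (!nzchar(consensus)) stop("empty consensus", call. = FALSE)
  if (nchar(consensus) < 10L) stop("consensus must be >= 10 nt", call. = FALSE)
  cl <- nchar(consensus)
  pats <- list(`+` = consensus, `-` = iupac_revcomp(consensus))
  pat_sets <- lapply(pats, function(p) {
    strsplit(Biostrings::IUPAC_CODE_MAP[strsplit(p, "")[[1]]], "")
  })

  hits <- list()
  for (r in assembly$replicons) {
    L <- r$length
    circ <- r$topology == "circular"
    subj_str <- if (circ && L > cl) {
      paste0(r$sequence, substr(r$sequence, 1L, cl - 1L))
    } else {
      r$sequence
    }
    subj <- Biostrings::DNAString(subj_str)
    for (strand in c("+", "-")) {
      m <- Biostrings::matchPattern(
        Biostrings::DNAString(pats[[strand]]), subj,
        max.mismatch = max_mismatch,
        fixed = c(pattern = FALSE, subject = TRUE))
      if (!length(m)) next
      starts <- Biostrings::start(m) - 1L
      keep <- starts < L
      starts <- starts[keep]
      if (!length(starts)) next
      mm <- vapply(starts, function(s0) {
        iupac_mismatches(seq_window(r$sequence, s0, cl, circ),
                         pat_sets[[strand]])
      }, numeric(1))
      if (strand == "+") {
        runs <- vapply(starts, function(s0) {
          run_length_at(r$sequence, (s0 + cl) %% L, "G")
        }, integer(1))
      } else {
        # minus-strand 3' flank lies to the left on the plus strand, read as
        # a C-run ending just before the hit.
        runs <- vapply(starts, function(s0) {
          left <- strsplit(seq_window(r$sequence, (s0 - 50L) %% L, 50L),
                           "")[[1]]
          n <- match(FALSE, rev(left) == "C", nomatch = 51L) - 1L
          as.integer(n)
        }, integer(1))
      }
      hits[[length(hits) + 1L]] <- data.frame(
        replicon_id = r$id, start = starts, end = starts + cl,
        strand = strand, mismatches = as.integer(mm),
        has_gstring = runs >= gstring_min, gstring_len = runs,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(replicon_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), has_gstring = logical(),
                      gstring_len = integer(), stringsAsFactors = FALSE))
  }
  h <- do.call(rbind, hits)

  # resolve overlaps per replicon and strand: lowest mismatches, then leftmost
  keep <- logical(nrow(h))
  for (grp in split(seq_len(nrow(h)),
                    paste(h$replicon_id, h$strand))) {
    ord <- grp[order(h$mismatches[grp], h$start[grp])]
    taken <- matrix(numeric(0), ncol = 2)
    for (i in ord) {
      if (!nrow(taken) ||
          !any(h$start[i] < taken[, 2] & taken[, 1] < h$end[i])) {
        keep[i] <- TRUE
        taken <- rbind(taken, c(h$start[i], h$end[i]))
      }
    }
  }
  h <- h[keep, , drop = FALSE]
  h <- h[order(h$replicon_id, h$start, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  class(h) <- c("ORBHit", "data.frame")
  h
}

#' Find AT-rich regions
#'
#' Slides windows (default 100 bp every 10 bp, wrapping on circular
#' replicons) and merges overlapping windows whose AT fraction reaches
#' `min_at` into maximal regions. The default threshold is the replicon's
#' background AT fraction plus 0.10, so "AT-rich" is always relative to the
#' genome's own composition -- haloarchaeal genomes are strongly GC-rich, and
#' an absolute threshold would misfire.
#'
#' @param replicon A [replicon()].
#' @param window Window size in bp.
#' @param min_at AT-fraction threshold; `NULL` for background + 0.10.
#' @param step Window step in bp.
#' @return Data frame `start`, `end`, `at_fraction` (merged regions; `end`
#'   may exceed the replicon length when a region wraps the origin seam).
#' @export
find_at_rich <- function(replicon, window = 100L, min_at = NULL, step = 10L) {
  stopifnot(inherits(replicon, "Replicon"), window <= replicon$length,
            step >= 1L)
  L <- replicon$length
  circ <- replicon$topology == "circular"
  ch <- strsplit(replicon$sequence, "")[[1]]
  at <- as.integer(ch %in% c("A", "T"))
  pre <- c(0L, cumsum(at))
  bg <- pre[L + 1L] / L
  if (is.null(min_at)) min_at <- min(bg + 0.10, 1)

  starts <- seq.int(0L, L - 1L, by = step)
  if (!circ) starts <- starts[starts + window <= L]
  cnt <- vapply(starts, function(s) {
    e <- s + window
    if (e <= L) pre[e + 1L] - pre[s + 1L]
    else (pre[L + 1L] - pre[s + 1L]) + pre[e - L + 1L]
  }, integer(1))
  ok <- which(cnt / window >= min_at)
  if (!length(ok)) {
    return(data.frame(start = integer(), end = integer(),
                      at_fraction = numeric()))
  }
  ws <- starts[ok]
  we <- ws + window
  # merge overlapping qualifying windows
  o <- order(ws)
  ws <- ws[o]; we <- we[o]
  ms <- ws[1]; me <- we[1]
  regions <- list()
  for (i in seq_along(ws)[-1]) {
    if (ws[i] <= me) {
      me <- max(me, we[i])
    } else {
      regions[[length(regions) + 1L]] <- c(ms, me)
      ms <- ws[i]; me <- we[i]
    }
  }
  regions[[length(regions) + 1L]] <- c(ms, me)
  # circular: join a region running past the seam with one starting at 0
  if (circ && length(regions) > 1L) {
    last <- regions[[length(regions)]]
    first <- regions[[1L]]
    if (last[2] > L && first[1] <= last[2] - L) {
      regions[[1L]] <- c(last[1], first[2] + L)
      regions[[length(regions)]] <- NULL
    }
  }
  out <- do.call(rbind, lapply(regions, function(rg) {
    s <- rg[1]; e <- min(rg[2], rg[1] + L)
    n_at <- sum(at[((s:(e - 1L)) %% L) + 1L])
    data.frame(start = s, end = e, at_fraction = n_at / (e - s))
  }))
  # full coverage collapses to one replicon-wide region
  if (sum(out$end - out$start) >= L) {
    out <- data.frame(start = 0L, end = L,
                      at_fraction = pre[L + 1L] / L)
  }
  rownames(out) <- NULL
  out
}

#' Pair inverted ORB hits into origin candidates
#'
#' The haloarchaeal origin core is an AT-rich stretch flanked by two ORBs in
#' inverted orientation facing inward: a plus-strand box on the left and a
#' minus-strand box on the right. Opposite-strand hit pairs whose inner gap
#' lies in `[min_gap, max_gap]` and whose gap contains at least one AT-rich
#' region become candidates; each hit joins at most one candidate (greedy by
#' smallest gap).
#'
#' Two specificity requirements keep ORB-rich titration clusters from
#' masquerading as origins: the inner gap must contain no other ORB hit (a
#' genuine origin core is ORB-free), and the AT-rich evidence must overlap
#' the gap by at least `min_at_overlap` bp -- a real core's worth of AT
#' sequence, not a marginal window grazing the gap.
#'
#' @param hits An `ORBHit` frame from [scan_orbs()].
#' @param at_regions Per-replicon AT-rich regions: a data frame as returned
#'   by [find_at_rich()] (single replicon), or a named list of them.
#' @param min_gap,max_gap Allowed inner gap (bp) between the paired boxes.
#' @param min_at_overlap Minimum overlap (bp) between an AT-rich region and
#'   the inner gap; keep equal to the [find_at_rich()] window.
#' @return An `OriginCandidate` data frame (one row per candidate) with the
#'   paired hit coordinates, the AT core, and unset classification fields.
#' @export
pair_inverted_orbs <- function(hits, at_regions, min_gap = 20L,
                               max_gap = 500L, min_at_overlap = 100L) {
  empty <- data.frame(
    replicon_id = character(), start = integer(), end = integer(),
    orb_left_start = integer(), orb_left_end = integer(),
    orb_left_gstring = logical(), orb_left_gstring_len = integer(),
    orb_right_start = integer(), orb_right_end = integer(),
    orb_right_gstring = logical(), orb_right_gstring_len = integer(),
    gap = integer(), at_start = integer(), at_end = integer(),
    at_fraction = numeric(), classification = character(),
    nearest_initiator = character(), initiator_distance = numeric(),
    stringsAsFactors = FALSE)
  if (!nrow(hits)) return(structure(empty,
                                    class = c("OriginCandidate",
                                              "data.frame")))
  if (is.data.frame(at_regions)) {
    at_regions <- setNames(list(at_regions), unique(hits$replicon_id)[1])
  }
  out <- list()
  for (rid in unique(hits$replicon_id)) {
    h <- hits[hits$replicon_id == rid, , drop = FALSE]
    plus <- h[h$strand == "+", , drop = FALSE]
    minus <- h[h$strand == "-", , drop = FALSE]
    if (!nrow(plus) || !nrow(minus)) next
    at <- at_regions[[rid]]
    if (is.null(at)) at <- data.frame(start = integer(), end = integer(),
                                      at_fraction = numeric())
    pairs <- expand.grid(i = seq_len(nrow(plus)), j = seq_len(nrow(minus)))
    pairs$gap <- minus$start[pairs$j] - plus$end[pairs$i]
    pairs <- pairs[pairs$gap >= min_gap & pairs$gap <= max_gap, ,
                   drop = FALSE]
    if (!nrow(pairs)) next
    # the inner gap of a genuine origin contains no other ORB hit
    clean <- vapply(seq_len(nrow(pairs)), function(q) {
      gs <- plus$end[pairs$i[q]]
      ge <- minus$start[pairs$j[q]]
      !any(h$start < ge & h$end > gs)
    }, logical(1))
    pairs <- pairs[clean, , drop = FALSE]
    if (!nrow(pairs)) next
    # AT-rich region substantially inside the inner gap
    pairs$at_idx <- vapply(seq_len(nrow(pairs)), function(q) {
      gs <- plus$end[pairs$i[q]]
      ge <- minus$start[pairs$j[q]]
      ov <- pmin(at$end, ge) - pmax(at$start, gs)
      cand <- which(ov >= min_at_overlap)
      if (!length(cand)) return(NA_integer_)
      cand[which.max(ov[cand])]
    }, integer(1))
    pairs <- pairs[!is.na(pairs$at_idx), , drop = FALSE]
    if (!nrow(pairs)) next
    pairs <- pairs[order(pairs$gap), , drop = FALSE]
    used_i <- used_j <- integer()
    for (q in seq_len(nrow(pairs))) {
      i <- pairs$i[q]; j <- pairs$j[q]
      if (i %in% used_i || j %in% used_j) next
      used_i <- c(used_i, i); used_j <- c(used_j, j)
      a <- pairs$at_idx[q]
      out[[length(out) + 1L]] <- data.frame(
        replicon_id = rid,
        start = plus$start[i], end = minus$end[j],
        orb_left_start = plus$start[i], orb_left_end = plus$end[i],
        orb_left_gstring = plus$has_gstring[i],
        orb_left_gstring_len = plus$gstring_len[i],
        orb_right_start = minus$start[j], orb_right_end = minus$end[j],
        orb_right_gstring = minus$has_gstring[j],
        orb_right_gstring_len = minus$gstring_len[j],
        gap = pairs$gap[q],
        at_start = at$start[a], at_end = at$end[a],
        at_fraction = at$at_fraction[a],
        classification = NA_character_,
        nearest_initiator = NA_character_,
        initiator_distance = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(structure(empty,
                                     class = c("OriginCandidate",
                                               "data.frame")))
  res <- do.call(rbind, out)
  res <- res[order(res$replicon_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("OriginCandidate", "data.frame")
  res
}

#' Find the G-rich inverted-repeat enhancer inside an origin candidate
#'
#' Searches the interval between the paired ORBs -- excluding each box's
#' G-string extension, which belongs to the ORB itself -- for the longest
#' perfect inverted repeat whose arms are G-rich: arm length at least
#' `arm_min` and G fraction of the G-rich strand arm at least `g_rich_min`.
#' Such repeats act as initiation enhancers at the haloarchaeal conserved
#' chromosomal origin.
#'
#' @param candidate One row of a [pair_inverted_orbs()] frame.
#' @param sequence Plus-strand sequence of the candidate's replicon.
#' @param arm_min Minimum arm length (bp).
#' @param g_rich_min Minimum G fraction of the G-rich arm.
#' @return An `InvertedRepeat` list (`arm_len`, `left_start`, `left_end`,
#'   `right_start`, `right_end`, `loop_len`, `g_fraction`; absolute 0-based
#'   half-open coordinates) or `NULL` when no qualifying repeat exists.
#' @export
find_enhancer <- function(candidate, sequence, arm_min = 8L,
                          g_rich_min = 0.8) {
  candidate <- as.list(candidate)
  il <- candidate$orb_left_end + candidate$orb_left_gstring_len
  ir <- candidate$orb_right_start - candidate$orb_right_gstring_len
  if (ir - il < 2L * arm_min) return(NULL)
  s <- substr(sequence, il + 1L, ir)
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "X")[ch]

  # complementary matches form runs along anti-diagonals (l + r = d) of the
  # base-pairing matrix; any inverted repeat is a sub-arm of such a run
  runs <- list()
  for (d in 0:(2L * n - 2L)) {
    lmin <- max(0L, d - n + 1L)
    lcap <- as.integer(ceiling(d / 2) - 1L)  # enforce l < d - l
    if (lcap < lmin) next
    lv <- lmin:lcap
    ok <- ch[lv + 1L] == comp[(d - lv) + 1L]
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (q in which(r$values)) {
      if (r$lengths[q] < arm_min) next
      runs[[length(runs) + 1L]] <- list(d = d, l0 = unname(lv[starts[q]]),
                                        len = r$lengths[q])
    }
  }
  if (!length(runs)) return(NULL)

  # longest G-rich arm wins; a G-rich sub-arm of a longer, less G-rich run
  # also counts. Ties: leftmost left arm, then leftmost right arm.
  best <- NULL
  max_len <- max(vapply(runs, `[[`, integer(1), "len"))
  for (a in seq.int(max_len, arm_min)) {
    for (run in runs) {
      if (run$len < a) next
      rc <- ch[run$l0 + seq_len(run$len)]
      gcs <- c(0L, cumsum(rc == "G"))
      ccs <- c(0L, cumsum(rc == "C"))
      for (off in 0:(run$len - a)) {
        gf <- max(gcs[off + a + 1L] - gcs[off + 1L],
                  ccs[off + a + 1L] - ccs[off + 1L]) / a
        if (gf < g_rich_min) next
        l0 <- run$l0 + off
        l1 <- l0 + a - 1L
        cand <- list(arm_len = as.integer(a), l0 = l0, l1 = l1,
                     d = run$d, g_fraction = gf,
                     right_start = run$d - l1)
        if (is.null(best) || cand$l0 < best$l0 ||
            (cand$l0 == best$l0 && cand$right_start < best$right_start)) {
          best <- cand
        }
      }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) return(NULL)
  left_start <- il + best$l0
  left_end <- il + best$l1 + 1L
  right_start <- il + best$d - best$l1
  right_end <- il + best$d - best$l0 + 1L
  res <- list(arm_len = best$arm_len,
              left_start = left_start, left_end = left_end,
              right_start = right_start, right_end = right_end,
              loop_len = right_start - left_end,
              g_fraction = best$g_fraction)
  # arms must be exact reverse complements by construction
  la <- substr(sequence, left_start + 1L, left_end)
  ra <- substr(sequence, right_start + 1L, right_end)
  stopifnot(identical(ra, revcomp(la)))
  class(res) <- "InvertedRepeat"
  res
}

#' Find ORB-rich titration clusters
#'
#' Groups ORB hits (either strand) whose consecutive gaps are at most
#' `max_span / cluster_min` into clusters; clusters of at least
#' `cluster_min` hits that do not overlap any origin candidate are reported
#' as candidate initiator-titration regions, with a flag for whether the
#' region is intergenic. Such ORB clusters lack origin activity themselves
#' but sequester their initiator and thereby damp the adjacent origin.
#'
#' @param hits An `ORBHit` frame.
#' @param candidates An `OriginCandidate` frame (may be empty).
#' @param features Gene features (data frame with `replicon_id`, `start`,
#'   `end`), used for the intergenic flag.
#' @param cluster_min Minimum hits per cluster.
#' @param max_span Scale for the gap heuristic (bp).
#' @return A `TitrationRegion` data frame: `replicon_id`, `start`, `end`,
#'   `orb_count`, `intergenic`.
#' @export
find_titration_regions <- function(hits, candidates, features,
                                   cluster_min = 3L, max_span = 1000L) {
  empty <- data.frame(replicon_id = character(), start = integer(),
                      end = integer(), orb_count = integer(),
                      intergenic = logical(), stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  if (is.null(features)) features <- empty_features()
  max_gap <- max_span / cluster_min
  out <- list()
  for (rid in unique(hits$replicon_id)) {
    h <- hits[hits$replicon_id == rid, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    if (nrow(h) < cluster_min) next
    gaps <- h$start[-1] - h$end[-nrow(h)]
    grp <- cumsum(c(0L, gaps > max_gap))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      if (length(idx) < cluster_min) next
      s <- min(h$start[idx]); e <- max(h$end[idx])
      cand <- candidates[candidates$replicon_id == rid, , drop = FALSE]
      if (nrow(cand) && any(s < cand$end & cand$start < e)) next
      f <- features[features$replicon_id == rid, , drop = FALSE]
      intergenic <- !nrow(f) || !any(s < f$end & f$start < e)
      out[[length(out) + 1L]] <- data.frame(
        replicon_id = rid, start = s, end = e,
        orb_count = length(idx), intergenic = intergenic,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify origin candidates by initiator adjacency
#'
#' Finds each candidate's nearest initiator gene (edge-to-edge circular
#' distance) and classifies the candidate `ori_cdc6` when that distance is
#' at most `max_initiator_dist`, else `orphan`. Characterised archaeal
#' origins sit next to their orc1/cdc6 gene; orphan ORB pairs are reported
#' but flagged.
#'
#' @param candidates An `OriginCandidate` frame.
#' @param assembly The [genome_assembly()] the candidates came from (needed
#'   for replicon lengths and initiator features).
#' @param max_initiator_dist Maximum adjacency distance in bp.
#' @return The candidates with `classification`, `nearest_initiator` and
#'   `initiator_distance` filled in.
#' @export
classify_candidates <- function(candidates, assembly,
                                max_initiator_dist = 2000L) {
  stopifnot(inherits(assembly, "GenomeAssembly"))
  if (!nrow(candidates)) return(candidates)
  feats <- assembly$features
  for (i in seq_len(nrow(candidates))) {
    rid <- candidates$replicon_id[i]
    L <- assembly$replicons[[rid]]$length
    init <- feats[feats$replicon_id == rid & feats$is_initiator, ,
                  drop = FALSE]
    if (!nrow(init)) {
      candidates$classification[i] <- "orphan"
      next
    }
    d <- vapply(seq_len(nrow(init)), function(j) {
      interval_circular_gap(candidates$start[i], candidates$end[i],
                            init$start[j], init$end[j], L)
    }, numeric(1))
    b <- which.min(d)
    candidates$nearest_initiator[i] <- init$name[b]
    candidates$initiator_distance[i] <- d[b]
    candidates$classification[i] <-
      if (d[b] <= max_initiator_dist) "ori_cdc6" else "orphan"
  }
  candidates
}
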