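# Mimic genome builder, synthetic microarray designer, and the
# population-level marker-frequency simulator.

#' Default ORB consensus (G-rich strand)
#'
#' Origin recognition boxes (ORBs) are the conserved repeats bound by
#' Orc1/Cdc6 initiators. The packaged default combines the classic archaeal
#' ORB core with a G-rich 3' end; in halophiles the box is extended by a
#' "G-string" run of consecutive guanines, which this package models as a
#' strand-aware 3' flank rather than part of the consensus (see
#' [scan_orbs()]). The consensus is a configuration value: replace it with a
#' lineage-specific IUPAC string when scanning real genomes.
#'
#' @return A 20-nt consensus string.
#' @export
default_orb_consensus <- function() "TTCCAGTGGAAACGAAAGGG"

#' Declare an origin-locus architecture
#'
#' Describes one plantable origin locus in the haloarchaeal style: an
#' inverted ORB pair (plus-strand box on the left, minus-strand box on the
#' right, each with its G-string extension pointing into the locus), an
#' AT-rich core between them, an optional perfect G-rich inverted-repeat
#' enhancer just inside the ORBs, an adjacent cdc6 gene, and an optional
#' downstream ORB-rich titration cluster in an intergenic region.
#'
#' @param name Locus name; planted element ids are prefixed with it.
#' @param orb_consensus IUPAC consensus for the ORB (G-rich strand).
#' @param n_origin_orbs Number of ORBs at the origin; only the inverted pair
#'   (`2`) is supported.
#' @param orb_spacing Spacer (bp) between an ORB's G-string and the locus
#'   interior.
#' @param at_core_len AT-rich core length in bp.
#' @param at_core_fraction AT fraction of the core, in `(0.5, 1]`.
#' @param gstring_len Length of each planted G-string run.
#' @param enhancer_arm Plus-strand arm of the enhancer inverted repeat, or
#'   `NULL` for none; the reverse-complement arm is planted on the other side
#'   of the core.
#' @param titration_orb_count Number of ORBs in the downstream titration
#'   cluster (0 for none).
#' @param titration_region_len Exact length (bp) of the intergenic titration
#'   region.
#' @param cdc6_gene_len Length of the planted cdc6 gene.
#' @param cdc6_offset Gap (bp) between the origin locus and the cdc6 gene.
#' @return An object of class `OriginArchitectureSpec`.
#' @export
origin_architecture <- function(name,
                                orb_consensus = default_orb_consensus(),
                                n_origin_orbs = 2L,
                                orb_spacing = 5L,
                                at_core_len = 150L,
                                at_core_fraction = 0.85,
                                gstring_len = 8L,
                                enhancer_arm = NULL,
                                titration_orb_count = 0L,
                                titration_region_len = 0L,
                                cdc6_gene_len = 1200L,
                                cdc6_offset = 100L) {
  stopifnot(is.character(name), nzchar(name))
  orb_consensus <- toupper(orb_consensus)
  if (nchar(orb_consensus) < 10L) stop("ORB consensus must be >= 10 nt")
  if (n_origin_orbs != 2L) {
    stop("only the inverted ORB pair (n_origin_orbs = 2) is supported")
  }
  if (!(at_core_fraction > 0.5 && at_core_fraction <= 1)) {
    stop("at_core_fraction must lie in (0.5, 1]")
  }
  if (titration_orb_count < 0L) stop("titration_orb_count must be >= 0")
  if (titration_orb_count > 0L &&
      titration_region_len < titration_orb_count * nchar(orb_consensus)) {
    stop("titration_region_len too small for titration_orb_count ORBs")
  }
  if (!is.null(enhancer_arm)) {
    enhancer_arm <- toupper(enhancer_arm)
    check_sequence(enhancer_arm, "enhancer_arm")
  }
  structure(list(name = name, orb_consensus = orb_consensus,
                 n_origin_orbs = as.integer(n_origin_orbs),
                 orb_spacing = as.integer(orb_spacing),
                 at_core_len = as.integer(at_core_len),
                 at_core_fraction = at_core_fraction,
                 gstring_len = as.integer(gstring_len),
                 enhancer_arm = enhancer_arm,
                 titration_orb_count = as.integer(titration_orb_count),
                 titration_region_len = as.integer(titration_region_len),
                 cdc6_gene_len = as.integer(cdc6_gene_len),
                 cdc6_offset = as.integer(cdc6_offset)),
            class = "OriginArchitectureSpec")
}

# -- internal sequence generators ------------------------------------------

random_bases <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

random_at_core <- function(n, at_fraction) {
  if (n <= 0L) return("")
  is_at <- runif(n) < at_fraction
  b <- character(n)
  b[is_at] <- sample(c("A", "T"), sum(is_at), replace = TRUE)
  b[!is_at] <- sample(c("G", "C"), sum(!is_at), replace = TRUE)
  paste(b, collapse = "")
}

# Draw one concrete instance of an IUPAC consensus.
sample_iupac <- function(consensus) {
  codes <- strsplit(consensus, "")[[1]]
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP[codes], "")
  paste(vapply(sets, function(s) s[sample.int(length(s), 1L)], character(1)),
        collapse = "")
}

mutate_bases <- function(s, n_mut) {
  if (n_mut <= 0L) return(s)
  ch <- strsplit(s, "")[[1]]
  pos <- sample.int(length(ch), n_mut)
  for (i in pos) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

# Partition `total` spacer bp into `k` chunks of >= min_each bp each.
partition_spacers <- function(total, k, min_each = 1L) {
  if (k <= 0L) return(integer())
  stopifnot(total >= k * min_each)
  w <- runif(k)
  extra <- total - k * min_each
  sp <- min_each + floor(w / sum(w) * extra)
  sp[k] <- sp[k] + (total - sum(sp))
  sp
}

# Assemble one origin locus. Returns the locus string plus relative
# ground-truth rows and relative feature rows.
plant_origin_locus <- function(spec, gc) {
  cl <- nchar(spec$orb_consensus)
  parts <- character()
  gt <- list()
  feats <- list()
  pos <- 0L
  add <- function(seq_str, type = NULL, id = NULL, strand = "+") {
    parts[[length(parts) + 1L]] <<- seq_str
    n <- nchar(seq_str)
    if (!is.null(type)) {
      gt[[length(gt) + 1L]] <<- data.frame(
        element_id = id, type = type, start = pos, end = pos + n,
        strand = strand, stringsAsFactors = FALSE)
    }
    pos <<- pos + n
  }
  nm <- function(x) paste0(spec$name, ".", x)

  orb_left <- sample_iupac(spec$orb_consensus)
  orb_right <- sample_iupac(spec$orb_consensus)
  add(orb_left, "orb", nm("orb_I"), "+")
  add(strrep("G", spec$gstring_len), "gstring", nm("gstring_I"), "+")
  add(random_bases(spec$orb_spacing, gc))
  if (!is.null(spec$enhancer_arm)) {
    add(spec$enhancer_arm, "enhancer_arm", nm("enhancer_III"), "+")
  }
  add(random_at_core(spec$at_core_len, spec$at_core_fraction),
      "at_core", nm("at_core"), "+")
  if (!is.null(spec$enhancer_arm)) {
    add(revcomp(spec$enhancer_arm), "enhancer_arm", nm("enhancer_IV"), "-")
  }
  add(random_bases(spec$orb_spacing, gc))
  add(strrep("C", spec$gstring_len), "gstring", nm("gstring_II"), "-")
  add(revcomp(orb_right), "orb", nm("orb_II"), "-")
  origin_end <- pos
  gt[[length(gt) + 1L]] <- data.frame(
    element_id = nm("origin_locus"), type = "origin_locus",
    start = 0L, end = origin_end, strand = "+", stringsAsFactors = FALSE)

  add(random_bases(spec$cdc6_offset, gc))
  gene_start <- pos
  add(random_bases(spec$cdc6_gene_len, gc), "cdc6_gene", nm("cdc6"), "+")
  feats[[length(feats) + 1L]] <- data.frame(
    start = gene_start, end = gene_start + spec$cdc6_gene_len, strand = "+",
    name = paste0("cdc6-", spec$name), is_initiator = TRUE,
    stringsAsFactors = FALSE)

  if (spec$titration_orb_count > 0L) {
    add(random_bases(50L, gc))
    region_start <- pos
    k <- spec$titration_orb_count
    spacers <- partition_spacers(spec$titration_region_len - k * cl, k + 1L)
    for (i in seq_len(k)) {
      add(random_bases(spacers[i], gc))
      inst <- mutate_bases(sample_iupac(spec$orb_consensus),
                           sample(0:2, 1L))
      strand <- sample(c("+", "-"), 1L)
      add(if (strand == "+") inst else revcomp(inst),
          "titration_orb", nm(sprintf("titration_orb_%02d", i)), strand)
    }
    add(random_bases(spacers[k + 1L], gc))
    gt[[length(gt) + 1L]] <- data.frame(
      element_id = nm("titration_region"), type = "titration_region",
      start = region_start, end = region_start + spec$titration_region_len,
      strand = "+", stringsAsFactors = FALSE)
  }

  list(sequence = paste(parts, collapse = ""),
       ground_truth = do.call(rbind, gt),
       features = if (length(feats)) do.call(rbind, feats) else NULL,
       origin_span = c(0L, origin_end))
}

#' Build a synthetic genome with planted origin loci
#'
#' Generates i.i.d. background sequence at a given GC content for each
#' replicon and plants one origin locus per architecture spec. Optionally the
#' background is made strand-asymmetric (leading-strand G excess switching at
#' an origin/terminus pair) so that cumulative GC-skew analysis has a real
#' signal to find.
#'
#' Planted elements never overlap; the builder fails hard if a locus does not
#' fit. Ground-truth coordinates of every planted element are attached to the
#' returned assembly as `$ground_truth` (columns `element_id`, `type`,
#' `replicon_id`, `start`, `end`, `strand`).
#'
#' @param specs One [origin_architecture()] or a list of them.
#' @param replicon_lens Integer vector of replicon lengths; names become
#'   replicon ids (defaults `replicon_1`, ...).
#' @param gc_background Background GC fraction.
#' @param seed Integer seed; the same seed reproduces the genome exactly.
#' @param spec_replicon Index of the target replicon for each spec
#'   (default: spec i on replicon i, requiring equal lengths of `specs` and
#'   `replicon_lens`).
#' @param origin_positions Locus start (bp) per spec; default places the loci
#'   of each replicon evenly around it.
#' @param skew_strength Fraction in `[0, 1)` controlling leading-strand G
#'   enrichment of the background; 0 disables.
#' @param skew_origin Position of the skew switch point (origin); defaults to
#'   the first planted locus midpoint of each skewed replicon.
#' @return A [genome_assembly()] with `$ground_truth` filled in.
#' @export
build_genome <- function(specs, replicon_lens, gc_background = 0.6, seed,
                         spec_replicon = NULL, origin_positions = NULL,
                         skew_strength = 0, skew_origin = NULL) {
  if (inherits(specs, "OriginArchitectureSpec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "OriginArchitectureSpec")),
            length(replicon_lens) >= 1L, !missing(seed))
  ids <- names(replicon_lens)
  if (is.null(ids)) ids <- sprintf("replicon_%d", seq_along(replicon_lens))
  if (is.null(spec_replicon)) {
    if (length(specs) != length(replicon_lens)) {
      stop("provide spec_replicon when specs and replicons differ in number")
    }
    spec_replicon <- seq_along(specs)
  }
  stopifnot(length(spec_replicon) == length(specs),
            all(spec_replicon %in% seq_along(replicon_lens)))

  withr::with_seed(as.integer(seed), {
    # default locus positions: evenly spread per replicon
    if (is.null(origin_positions)) {
      origin_positions <- integer(length(specs))
      for (r in seq_along(replicon_lens)) {
        sel <- which(spec_replicon == r)
        k <- length(sel)
        if (k) {
          origin_positions[sel] <-
            as.integer(floor(replicon_lens[r] * (seq_len(k) - 0.5) / k))
        }
      }
    }

    loci <- lapply(specs, plant_origin_locus, gc = gc_background)
    reps <- vector("list", length(replicon_lens))
    gt_all <- list()
    feat_all <- list()
    for (r in seq_along(replicon_lens)) {
      L <- as.integer(replicon_lens[r])
      sel <- which(spec_replicon == r)
      # background (optionally strand-asymmetric around ori/ter)
      if (skew_strength > 0) {
        ori <- if (!is.null(skew_origin)) skew_origin[min(r, length(skew_origin))]
               else if (length(sel)) {
                 lo <- loci[[sel[1L]]]
                 origin_positions[sel[1L]] + (lo$origin_span[2L] %/% 2L)
               } else 0L
        ter <- (ori + L %/% 2L) %% L
        gpos <- gc_background / 2
        delta <- skew_strength * gpos
        idx <- seq_len(L) - 1L
        lead <- ((idx - ori) %% L) < ((ter - ori) %% L)
        b <- character(L)
        pb_lead <- c((1 - gc_background) / 2, gpos - delta, gpos + delta,
                     (1 - gc_background) / 2)
        pb_lag <- c((1 - gc_background) / 2, gpos + delta, gpos - delta,
                    (1 - gc_background) / 2)
        b[lead] <- sample(c("A", "C", "G", "T"), sum(lead), TRUE, pb_lead)
        b[!lead] <- sample(c("A", "C", "G", "T"), sum(!lead), TRUE, pb_lag)
        bg <- paste(b, collapse = "")
      } else {
        bg <- random_bases(L, gc_background)
      }

      occupied <- matrix(numeric(0), ncol = 2)
      for (s in sel) {
        lo <- loci[[s]]
        p0 <- as.integer(origin_positions[s])
        n <- nchar(lo$sequence)
        if (p0 < 0L || p0 + n > L) {
          stop(sprintf("origin spec '%s' does not fit in replicon '%s'",
                       specs[[s]]$name, ids[r]), call. = FALSE)
        }
        if (nrow(occupied) &&
            any(p0 < occupied[, 2] & occupied[, 1] < p0 + n)) {
          stop(sprintf("planted loci overlap on replicon '%s'", ids[r]),
               call. = FALSE)
        }
        occupied <- rbind(occupied, c(p0, p0 + n))
        substr(bg, p0 + 1L, p0 + n) <- lo$sequence
        g <- lo$ground_truth
        g$start <- g$start + p0
        g$end <- g$end + p0
        g$replicon_id <- ids[r]
        gt_all[[length(gt_all) + 1L]] <- g
        if (!is.null(lo$features)) {
          f <- lo$features
          f$start <- f$start + p0
          f$end <- f$end + p0
          f$replicon_id <- ids[r]
          feat_all[[length(feat_all) + 1L]] <- f
        }
      }
      reps[[r]] <- replicon(ids[r], bg, "circular")
    }
    feats <- if (length(feat_all)) do.call(rbind, feat_all) else NULL
    gt <- if (length(gt_all)) do.call(rbind, gt_all) else NULL
    if (!is.null(gt)) {
      gt <- gt[, c("element_id", "type", "replicon_id", "start", "end",
                   "strand")]
      rownames(gt) <- NULL
    }
    if (!is.null(feats)) {
      feats <- feats[, c("replicon_id", "start", "end", "strand", "name",
                         "is_initiator")]
    }
    genome_assembly(reps, feats, ground_truth = gt)
  })
}

#' Replace the bases of one planted element
#'
#' Site-directed mutagenesis on a synthetic genome: the replacement must have
#' exactly the length of the ground-truth element, and only those bases
#' change. The replacement is given in plus-strand orientation. This is how
#' G-string and enhancer-arm mutant fixtures are built (e.g. turning a
#' planted G-run into an A-run to ablate the G-string).
#'
#' @param assembly A [build_genome()] assembly with ground truth.
#' @param site `element_id` of a ground-truth element.
#' @param replacement Plus-strand nucleotide string, same length as the site.
#' @return The mutated assembly (ground truth unchanged).
#' @export
apply_site_mutation <- function(assembly, site, replacement) {
  stopifnot(inherits(assembly, "GenomeAssembly"))
  gt <- assembly$ground_truth
  if (is.null(gt)) stop("assembly carries no ground truth", call. = FALSE)
  row <- gt[gt$element_id == site, , drop = FALSE]
  if (nrow(row) != 1L) stop(sprintf("unknown site '%s'", site), call. = FALSE)
  replacement <- toupper(replacement)
  check_sequence(replacement, "replacement")
  width <- row$end - row$start
  if (nchar(replacement) != width) {
    stop(sprintf("replacement length %d != site length %d",
                 nchar(replacement), width), call. = FALSE)
  }
  rep_obj <- assembly$replicons[[row$replicon_id]]
  s <- rep_obj$sequence
  substr(s, row$start + 1L, row$end) <- replacement
  assembly$replicons[[row$replicon_id]] <- replicon(rep_obj$id, s,
                                                    rep_obj$topology)
  assembly
}

#' Design a synthetic tiling microarray
#'
#' One probe is centred on each gene midpoint, and uniformly spaced fill-in
#' probes guarantee that every 1-kb window of every replicon contains at
#' least `min_density` probes -- mirroring array designs that add MFA tiling
#' probes on top of per-ORF probes. All probes have the same length.
#'
#' @param assembly A [genome_assembly()].
#' @param probe_len Probe length in bp (60-mers by default).
#' @param min_density Minimum probes per kb.
#' @param seed Integer seed (randomises the phase of the fill-in grid).
#' @return An `ArrayDesign` data frame with columns `replicon_id`,
#'   `position` (0-based probe start) and `length`.
#' @export
design_probes <- function(assembly, probe_len = 60L, min_density = 1.0,
                          seed = 0L) {
  stopifnot(inherits(assembly, "GenomeAssembly"), probe_len >= 1L,
            min_density > 0)
  spacing <- max(1L, as.integer(floor(1000 / min_density)))
  withr::with_seed(as.integer(seed), {
    out <- lapply(assembly$replicons, function(r) {
      if (r$length < probe_len) {
        stop(sprintf("replicon '%s' shorter than probe length", r$id),
             call. = FALSE)
      }
      f <- assembly$features[assembly$features$replicon_id == r$id, ,
                             drop = FALSE]
      gene_pos <- if (nrow(f)) {
        ((f$start + f$end) %/% 2L - probe_len %/% 2L) %% r$length
      } else integer()
      phase <- sample.int(min(spacing, r$length), 1L) - 1L
      grid <- seq.int(phase, r$length - 1L, by = spacing)
      pos <- sort(unique(c(as.integer(gene_pos), as.integer(grid))))
      if (r$topology == "linear") pos <- pos[pos + probe_len <= r$length]
      data.frame(replicon_id = r$id, position = pos,
                 length = as.integer(probe_len), stringsAsFactors = FALSE)
    })
    design <- do.call(rbind, out)
    rownames(design) <- NULL
    attr(design, "min_density") <- min_density
    class(design) <- c("ArrayDesign", "data.frame")
    design
  })
}

#' Define a replication program for one replicon
#'
#' The program drives the population simulator: each origin fires in a given
#' cell with probability `firing_prob`, at time `firing_delay` minutes after
#' birth, and bidirectional forks then advance at `fork_speed`. Viability
#' requires at least one origin certain to fire (`firing_prob = 1`), matching
#' the genetic observation that one active origin per replicon is essential
#' and sufficient; deletion strains are modelled by setting an origin's
#' probability to 0 (or dropping it).
#'
#' @param origins Data frame with columns `position` (bp), `firing_prob`
#'   in `[0, 1]`, and optionally `firing_delay` (minutes, default 0).
#' @param fork_speed Fork speed in bp/minute (`> 0`).
#' @param doubling_time Population doubling time in minutes (`> 0`).
#' @param replicon_id Replicon the program applies to.
#' @param replicon_length Replicon length in bp.
#' @return An object of class `ReplicationProgram`.
#' @export
replication_program <- function(origins, fork_speed, doubling_time,
                                replicon_id, replicon_length) {
  origins <- as.data.frame(origins)
  stopifnot(all(c("position", "firing_prob") %in% names(origins)),
            nrow(origins) >= 1L, fork_speed > 0, doubling_time > 0,
            replicon_length > 0)
  if (is.null(origins$firing_delay)) origins$firing_delay <- 0
  if (any(origins$firing_prob < 0 | origins$firing_prob > 1)) {
    stop("firing_prob must lie in [0, 1]", call. = FALSE)
  }
  if (all(origins$firing_prob == 0)) {
    stop("no origin can fire: all firing probabilities are 0", call. = FALSE)
  }
  if (max(origins$firing_prob) < 1) {
    warning("no origin has firing_prob = 1; some cells will never replicate")
  }
  if (any(origins$position < 0 | origins$position >= replicon_length)) {
    stop("origin positions must lie in [0, replicon_length)", call. = FALSE)
  }
  structure(list(origins = origins, fork_speed = fork_speed,
                 doubling_time = doubling_time, replicon_id = replicon_id,
                 replicon_length = as.integer(replicon_length)),
            class = "ReplicationProgram")
}

# Steady-state age density of an exponential culture, truncated to one
# doubling time: f(a) = (2 ln2 / tau) 2^(-a/tau) on [0, tau]. Sampled by
# inversion: a = tau * (1 - log2(2 - u)).
sample_cell_ages <- function(n, tau) {
  tau * (1 - log2(2 - runif(n)))
}

# Replication time of each probe for a realized firing set: first arrival
# over the fired origins' bidirectional forks (fork collisions resolve at
# the circle midpoints, which first-arrival reproduces exactly).
arrival_times <- function(origins, positions, L, v) {
  t(vapply(seq_len(nrow(origins)), function(i) {
    origins$firing_delay[i] +
      circular_distance(positions, origins$position[i], L) / v
  }, numeric(length(positions))))
}

#' Simulate two-channel marker-frequency signals
#'
#' Population model of an asynchronous exponentially growing culture: each
#' cell has an age drawn from the steady-state age density
#' `f(a) = (2 ln2/tau) 2^(-a/tau)` on `[0, tau]`; each origin fires
#' independently with its programmed probability; bidirectional forks advance
#' at the programmed speed and stop where they meet an opposing fork. A locus
#' has copy number 2 if its replication time is at most the cell's age, else
#' 1; a cell in which no origin fires stays unreplicated. The exponential
#' channel reports the population mean copy number per probe times
#' multiplicative lognormal noise; the stationary channel reports 1 times the
#' same noise model.
#'
#' For a single always-firing origin the expected exponential copy number has
#' the closed form `M(x) = 2^(1 - t(x)/tau)`, and the simulated mean
#' converges to it as `n_cells` grows.
#'
#' @param program A [replication_program()].
#' @param design An [design_probes()] array (probes on other replicons are
#'   ignored).
#' @param n_cells Cells per replicate (`>= 1`).
#' @param noise_cv Coefficient of variation of the lognormal probe noise.
#' @param n_replicates Independent biological replicates.
#' @param seed Integer seed.
#' @return A `SignalTable` data frame (`replicon_id`, `position`,
#'   `exp_signal`, `stat_signal`, `replicate`) with the replicon length and
#'   simulation parameters in attributes.
#' @export
simulate_marker_frequency <- function(program, design, n_cells,
                                      noise_cv = 0.1, n_replicates = 1L,
                                      seed) {
  stopifnot(inherits(program, "ReplicationProgram"), n_cells >= 1L,
            n_replicates >= 1L, noise_cv >= 0, !missing(seed))
  probes <- design[design$replicon_id == program$replicon_id, , drop = FALSE]
  if (!nrow(probes)) stop("no probes on the program's replicon", call. = FALSE)
  if (all(program$origins$firing_prob == 0)) {
    stop("no origin can fire: all firing probabilities are 0", call. = FALSE)
  }
  L <- program$replicon_length
  tau <- program$doubling_time
  ori <- program$origins
  k <- nrow(ori)
  Tmat <- arrival_times(ori, probes$position, L, program$fork_speed)
  np <- nrow(probes)
  sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0

  withr::with_seed(as.integer(seed), {
    out <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      ages <- sample_cell_ages(n_cells, tau)
      fired <- matrix(runif(n_cells * k) < rep(ori$firing_prob,
                                               each = n_cells),
                      nrow = n_cells)
      mask <- as.integer(fired %*% (2^(seq_len(k) - 1)))
      copy_sum <- numeric(np)
      for (m in unique(mask)) {
        cells <- which(mask == m)
        if (m == 0L) {
          copy_sum <- copy_sum + length(cells)  # unreplicated: copy 1
          next
        }
        sel <- which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0)
        tS <- if (length(sel) == 1L) Tmat[sel, ] else
          do.call(pmin, lapply(sel, function(i) Tmat[i, ]))
        a_sorted <- sort(ages[cells])
        n_ge <- length(cells) -
          findInterval(tS, a_sorted, left.open = TRUE)
        copy_sum <- copy_sum + length(cells) + n_ge
      }
      mean_copy <- copy_sum / n_cells
      fe <- if (sdlog > 0) rlnorm(np, -sdlog^2 / 2, sdlog) else rep(1, np)
      fs <- if (sdlog > 0) rlnorm(np, -sdlog^2 / 2, sdlog) else rep(1, np)
      out[[r]] <- data.frame(replicon_id = probes$replicon_id,
                             position = probes$position,
                             exp_signal = mean_copy * fe,
                             stat_signal = fs,
                             replicate = r, stringsAsFactors = FALSE)
    }
    signals <- do.call(rbind, out)
    rownames(signals) <- NULL
    attr(signals, "replicon_length") <- L
    attr(signals, "n_cells") <- as.integer(n_cells)
    attr(signals, "doubling_time") <- tau
    class(signals) <- c("SignalTable", "data.frame")
    signals
  })
}

#' Closed-form expected marker-frequency ratio
#'
#' Expected exponential-phase copy number per position under the population
#' model of [simulate_marker_frequency()], computed exactly as a mixture over
#' all subsets of origins that fire. For an always-firing single origin this
#' reduces to `2^(1 - t(x)/tau)`.
#'
#' @param origins Data frame with `position`, `firing_prob` and optionally
#'   `firing_delay` columns.
#' @param fork_speed,doubling_time As in [replication_program()].
#' @param positions Probe positions (bp).
#' @param replicon_length Replicon length (bp).
#' @return Numeric vector of expected copy numbers (the noiseless
#'   exponential:stationary ratio).
#' @export
expected_marker_ratio <- function(origins, fork_speed, doubling_time,
                                  positions, replicon_length) {
  origins <- as.data.frame(origins)
  if (is.null(origins$firing_delay)) origins$firing_delay <- 0
  k <- nrow(origins)
  if (k > 12L) stop("subset mixture limited to 12 origins", call. = FALSE)
  Tmat <- arrival_times(origins, positions, replicon_length, fork_speed)
  expected_ratio_from_arrivals(Tmat / doubling_time, origins$firing_prob)
}

# Mixture over firing subsets given arrival times already scaled by tau.
# trel: k x npos matrix of t/tau; p: firing probabilities.
expected_ratio_from_arrivals <- function(trel, p) {
  k <- nrow(trel)
  npos <- ncol(trel)
  total <- numeric(npos)
  for (m in 0:(2^k - 1)) {
    bits <- bitwAnd(m, 2^(seq_len(k) - 1)) > 0
    sel <- which(bits)
    w <- prod(ifelse(bits, p, 1 - p))
    if (w == 0) next
    if (length(sel) == 0L) {
      total <- total + w  # copy number 1 everywhere
    } else {
      tS <- if (length(sel) == 1L) trel[sel, ] else
        do.call(pmin, lapply(sel, function(i) trel[i, ]))
      pr2 <- pmin(pmax(2^(1 - tS) - 1, 0), 1)  # P(age >= t)
      total <- total + w * (1 + pr2)
    }
  }
  total
}
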