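# Sequence containers and circular-coordinate primitives.
#
# Internal convention: all coordinates are 0-based, half-open. GFF3 (1-based,
# closed) is converted at the boundary; BED/bedGraph output is 0-based,
# half-open. Sequences are uppercase character strings over A/C/G/T/N.

VALID_BASES <- c("A", "C", "G", "T", "N")

check_sequence <- function(s, context = "sequence") {
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0L) {
    stop(sprintf("invalid character '%s' at position %d in %s",
                 substr(s, bad, bad), as.integer(bad), context), call. = FALSE)
  }
  invisible(s)
}

#' Create a replicon
#'
#' A replicon is a single circular or linear DNA molecule: an id, an
#' uppercase A/C/G/T/N sequence, and a topology. Circular replicons admit
#' coordinate wrap-around in all downstream operations.
#'
#' @param id Replicon identifier (FASTA record id).
#' @param sequence Nucleotide string; lowercase input is uppercased.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return An object of class `Replicon`: a list with `id`, `sequence`,
#'   `length` and `topology`.
#' @export
replicon <- function(id, sequence, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  check_sequence(sequence, sprintf("replicon '%s'", id))
  structure(list(id = id, sequence = sequence,
                 length = nchar(sequence), topology = topology),
            class = "Replicon")
}

#' @export
print.Replicon <- function(x, ...) {
  cat(sprintf("<Replicon> %s: %d bp, %s\n", x$id, x$length, x$topology))
  invisible(x)
}

empty_features <- function() {
  data.frame(replicon_id = character(), start = integer(), end = integer(),
             strand = character(), name = character(),
             is_initiator = logical(), stringsAsFactors = FALSE)
}

#' Create a genome assembly
#'
#' Bundles replicons with gene features. Feature coordinates are 0-based,
#' half-open; features spanning the origin of a circular replicon must be
#' split into two records before construction.
#'
#' @param replicons List of [replicon()] objects (ids must be unique).
#' @param features Data frame with columns `replicon_id`, `start`, `end`,
#'   `strand`, `name`, `is_initiator`, or `NULL` for none.
#' @param ground_truth Optional data frame of planted-element coordinates
#'   (attached by [build_genome()]).
#' @return An object of class `GenomeAssembly`.
#' @export
genome_assembly <- function(replicons, features = NULL, ground_truth = NULL) {
  if (inherits(replicons, "Replicon")) replicons <- list(replicons)
  ids <- vapply(replicons, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("replicon ids must be unique", call. = FALSE)
  names(replicons) <- ids
  if (is.null(features)) features <- empty_features()
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features)) {
    missing_id <- setdiff(unique(features$replicon_id), ids)
    if (length(missing_id)) {
      stop("feature replicon_id does not resolve: ",
           paste(missing_id, collapse = ", "), call. = FALSE)
    }
    lens <- setNames(vapply(replicons, `[[`, integer(1), "length"), ids)
    bad <- features$start < 0L | features$start >= features$end |
      features$end > lens[features$replicon_id]
    if (any(bad)) {
      stop("feature coordinates out of bounds for: ",
           paste(features$name[bad], collapse = ", "), call. = FALSE)
    }
  }
  structure(list(replicons = replicons, features = features,
                 ground_truth = ground_truth),
            class = "GenomeAssembly")
}

#' @export
print.GenomeAssembly <- function(x, ...) {
  cat(sprintf("<GenomeAssembly> %d replicon(s), %d feature(s)\n",
              length(x$replicons), nrow(x$features)))
  for (r in x$replicons) {
    cat(sprintf("  %s: %d bp (%s)\n", r$id, r$length, r$topology))
  }
  invisible(x)
}

#' Load a genome from FASTA and GFF3
#'
#' Every GFF `gene` row (all rows when no row is typed `gene`) becomes a
#' feature; coordinates are converted from GFF 1-based closed to the internal
#' 0-based half-open convention. A feature is flagged as a replication
#' initiator when any of its GFF attribute values contains `initiator_tag`
#' (case-insensitive substring match) -- annotation pipelines differ in where
#' they record orc1/cdc6 homology, so the tag is a required configuration
#' item rather than a built-in guess.
#'
#' @param fasta_path Multi-record FASTA, one record per replicon.
#' @param gff_path GFF3 annotation; seqids must match FASTA record ids.
#' @param initiator_tag Substring marking orc1/cdc6 genes, e.g. `"cdc6"`.
#' @param topology Topology applied to every replicon.
#' @return A [genome_assembly()].
#' @export
load_genome <- function(fasta_path, gff_path, initiator_tag,
                        topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(file.exists(fasta_path), file.exists(gff_path),
            is.character(initiator_tag), nzchar(initiator_tag))
  # read as raw strings first: DNAStringSet would silently drop characters
  # outside its alphabet, and the contract is a hard error with a position
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  reps <- lapply(seq_along(seqs), function(i) {
    replicon(ids[i], as.character(seqs[[i]]), topology)
  })

  gff <- rtracklayer::import(gff_path, format = "gff3")
  if ("type" %in% names(S4Vectors::mcols(gff)) &&
      any(as.character(gff$type) == "gene")) {
    gff <- gff[as.character(gff$type) == "gene"]
  }
  feats <- empty_features()
  if (length(gff)) {
    seqids <- as.character(GenomicRanges::seqnames(gff))
    unknown <- setdiff(unique(seqids), ids)
    if (length(unknown)) {
      stop("GFF seqid not present in FASTA: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    mc <- S4Vectors::mcols(gff)
    attr_text <- vapply(seq_along(gff), function(i) {
      vals <- unlist(lapply(names(mc), function(cn) {
        v <- mc[[cn]][i]
        if (methods::is(v, "List")) v <- unlist(v)
        as.character(v)
      }), use.names = FALSE)
      paste(vals[!is.na(vals)], collapse = ";")
    }, character(1))
    nm <- rep(NA_character_, length(gff))
    for (cand in c("Name", "ID", "gene", "locus_tag")) {
      if (cand %in% names(mc)) {
        v <- as.character(mc[[cand]])
        nm[is.na(nm) & !is.na(v)] <- v[is.na(nm) & !is.na(v)]
      }
    }
    nm[is.na(nm)] <- sprintf("feature_%d", which(is.na(nm)))
    strand <- as.character(GenomicRanges::strand(gff))
    strand[strand == "*"] <- "+"
    feats <- data.frame(
      replicon_id = seqids,
      start = GenomicRanges::start(gff) - 1L,
      end = GenomicRanges::end(gff),
      strand = strand,
      name = nm,
      is_initiator = grepl(tolower(initiator_tag), tolower(attr_text),
                           fixed = TRUE),
      stringsAsFactors = FALSE
    )
  }
  genome_assembly(reps, feats)
}

#' Write a genome assembly to FASTA and GFF3
#'
#' Features are written as `gene` rows with `Name` and `product` attributes
#' set to the feature name, so that [load_genome()] with a matching
#' `initiator_tag` round-trips the assembly.
#'
#' @param assembly A [genome_assembly()].
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, `assembly`.
#' @export
write_genome <- function(assembly, fasta_path, gff_path) {
  stopifnot(inherits(assembly, "GenomeAssembly"))
  seqs <- Biostrings::DNAStringSet(
    vapply(assembly$replicons, `[[`, character(1), "sequence"))
  names(seqs) <- names(assembly$replicons)
  Biostrings::writeXStringSet(seqs, fasta_path)
  f <- assembly$features
  if (nrow(f)) {
    gr <- GenomicRanges::GRanges(
      seqnames = f$replicon_id,
      ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
      strand = f$strand)
    gr$type <- "gene"
    gr$Name <- f$name
    gr$product <- f$name
    rtracklayer::export(gr, gff_path, format = "gff3")
  } else {
    writeLines("##gff-version 3", gff_path)
  }
  invisible(assembly)
}

#' Reverse complement of a nucleotide string
#'
#' Strict A/C/G/T/N alphabet; `N` complements to `N`. The operation is an
#' involution and preserves length and GC content, which is what makes
#' inverted-repeat arithmetic (e.g. the two arms of a G-rich origin enhancer)
#' well defined.
#'
#' @param s A single nucleotide string.
#' @return The reverse complement, same length as `s`.
#' @export
revcomp <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  s <- toupper(s)
  check_sequence(s)
  if (!nzchar(s)) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Reverse complement allowing the full IUPAC alphabet (internal; used for
# degenerate motif consensus strings).
iupac_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Shortest distance between two positions on a circular replicon
#'
#' @param a,b Positions in `[0, L)` (vectors recycle).
#' @param L Replicon length in bp (`> 0`).
#' @return `min((a - b) mod L, (b - a) mod L)`, i.e. the shorter arc; always
#'   `<= L/2`.
#' @export
circular_distance <- function(a, b, L) {
  if (any(L <= 0)) stop("L must be positive", call. = FALSE)
  if (any(a < 0 | a >= L | b < 0 | b >= L)) {
    stop("positions must lie in [0, L)", call. = FALSE)
  }
  d <- (a - b) %% L
  pmin(d, L - d)
}

# Edge-to-edge circular distance between two half-open intervals; 0 if they
# overlap. Intervals are assumed not to wrap (wrapped features are split).
interval_circular_gap <- function(a_start, a_end, b_start, b_end, L) {
  if (a_start < b_end && b_start < a_end) return(0)
  g1 <- (b_start - a_end) %% L
  g2 <- (a_start - b_end) %% L
  min(g1, g2)
}

# Extract a window of `len` bases starting at 0-based `start`, wrapping for
# circular sequences.
seq_window <- function(sequence, start, len, circular = TRUE) {
  L <- nchar(sequence)
  start <- start %% L
  if (start + len <= L) return(substr(sequence, start + 1L, start + len))
  if (!circular) stop("window exceeds linear sequence", call. = FALSE)
  paste0(substr(sequence, start + 1L, L), substr(sequence, 1L, start + len - L))
}
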