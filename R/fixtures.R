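# Packaged mimic-genome configurations and track writers.

#' List or load a packaged mimic-genome configuration
#'
#' Three origin-architecture configurations ship with the package:
#' `hhis_oriC1_mimic` (enhancer repeat, no titration cluster),
#' `hhis_oriC2_mimic` (11 titration ORBs in a 722-bp intergenic region) and
#' `hla_oriC2_mimic` (3 titration ORBs). Each YAML records the architecture,
#' the replicon geometry and a fixed seed, so the fixture genome is fully
#' reproducible.
#'
#' @param name Configuration name (file base name); `NULL` lists the
#'   available names.
#' @return For a name: a list with `name`, `replicon_id`, `replicon_length`,
#'   `origin_position`, `gc_background`, `seed` and `spec` (an
#'   [origin_architecture()]).
#' @export
mimic_config <- function(name = NULL) {
  dir <- system.file("extdata", package = "oriscope", mustWork = TRUE)
  avail <- sub("\\.yaml$", "", list.files(dir, pattern = "_mimic\\.yaml$"))
  if (is.null(name)) return(avail)
  if (!name %in% avail) {
    stop(sprintf("unknown mimic config '%s'; available: %s", name,
                 paste(avail, collapse = ", ")), call. = FALSE)
  }
  cfg <- yaml::read_yaml(file.path(dir, paste0(name, ".yaml")))
  arch <- cfg$architecture
  spec <- origin_architecture(
    name = cfg$name,
    orb_consensus = arch$orb_consensus,
    n_origin_orbs = arch$n_origin_orbs,
    orb_spacing = arch$orb_spacing,
    at_core_len = arch$at_core_len,
    at_core_fraction = arch$at_core_fraction,
    gstring_len = arch$gstring_len,
    enhancer_arm = arch$enhancer_arm,
    titration_orb_count = arch$titration_orb_count,
    titration_region_len = arch$titration_region_len,
    cdc6_gene_len = arch$cdc6_gene_len,
    cdc6_offset = arch$cdc6_offset)
  list(name = cfg$name, replicon_id = cfg$replicon_id,
       replicon_length = cfg$replicon_length,
       origin_position = cfg$origin_position,
       gc_background = cfg$gc_background, seed = cfg$seed, spec = spec)
}

#' Build a packaged mimic genome
#'
#' Convenience wrapper: loads a [mimic_config()] and runs [build_genome()]
#' with the configured geometry and seed.
#'
#' @param name Configuration name, see [mimic_config()].
#' @return A [genome_assembly()] with ground truth.
#' @export
build_mimic_genome <- function(name) {
  cfg <- mimic_config(name)
  lens <- setNames(cfg$replicon_length, cfg$replicon_id)
  build_genome(cfg$spec, lens, gc_background = cfg$gc_background,
               seed = cfg$seed, spec_replicon = 1L,
               origin_positions = cfg$origin_position)
}

#' Write a numeric track as bedGraph
#'
#' 0-based half-open single-position intervals; for cumulative-skew tracks
#' remember that only extrema positions are meaningful on a circular
#' replicon (the running sum is anchored at coordinate 0).
#'
#' @param replicon_id Replicon id.
#' @param positions 0-based positions.
#' @param values Track values.
#' @param path Output path (`.bedGraph`).
#' @param span Interval width per position (default 1 bp).
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(replicon_id, positions, values, path, span = 1L) {
  gr <- GenomicRanges::GRanges(
    seqnames = replicon_id,
    ranges = IRanges::IRanges(start = positions + 1L, width = span),
    score = values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write intervals as BED6
#'
#' @param replicon_id Replicon id (recycled).
#' @param start,end 0-based half-open intervals.
#' @param name Feature names.
#' @param score Scores, clamped to `[0, 1000]`.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @param path Output path (`.bed`).
#' @return Invisibly, `path`.
#' @export
write_bed6 <- function(replicon_id, start, end, name, score, strand, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = replicon_id,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand)
  gr$name <- name
  gr$score <- pmin(pmax(round(score), 0), 1000)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
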