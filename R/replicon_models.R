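# Genetic logic of multi-origin replicons: per-replicon origin/cdc6
# essentiality, cognate-initiator specificity of plasmid (ARS) replication,
# origin-plasmid compatibility, and the equilibrium initiator-titration
# model for ORB-rich negative regulator regions.

#' Define a replication map
#'
#' The map records, per replicon, every origin with its cognate initiator
#' gene, whether the origin is active or dormant under standard growth, and
#' the id of an associated ORB-rich titration region if one exists. It also
#' lists initiator genes that are essential for reasons outside replication
#' initiation, and initiator genes with no adjacent origin (deletable
#' bystanders).
#'
#' @param origins Data frame with columns `origin_id`, `replicon_id`,
#'   `cognate` (initiator gene id), `active` (logical), `titration_region`
#'   (id or `NA`).
#' @param essential_other Initiator gene ids essential outside initiation.
#' @param extra_initiators Initiator gene ids with no adjacent origin.
#' @return An object of class `ReplicationMap`.
#' @export
replication_map <- function(origins, essential_other = character(),
                            extra_initiators = character()) {
  origins <- as.data.frame(origins, stringsAsFactors = FALSE)
  req <- c("origin_id", "replicon_id", "cognate", "active",
           "titration_region")
  stopifnot(all(req %in% names(origins)), nrow(origins) >= 1L,
            !anyDuplicated(origins$origin_id))
  structure(list(origins = origins,
                 essential_other = essential_other,
                 extra_initiators = extra_initiators),
            class = "ReplicationMap")
}

map_element_ids <- function(map) {
  c(map$origins$origin_id, map$origins$cognate, map$extra_initiators,
    map$origins$titration_region[!is.na(map$origins$titration_region)])
}

#' The Haloarcula hispanica replication map
#'
#' Three replicons: the main chromosome with two active origins (oriC1 with
#' cognate cdc6A, oriC2 with cognate cdc6E and the downstream ORB-rich
#' oriC2D titration region), the minichromosome with two dormant (oriC4,
#' oriC5) and two active (oriC6, oriC7) origins, and the megaplasmid pHH400
#' with the single origin oriP. cdc6A is additionally essential outside
#' replication initiation (its knockouts are viable but severely growth
#' impaired); cdc6B/C/D/F have no adjacent origin. Compiled from published
#' deletion analyses of this species.
#'
#' @return A [replication_map()].
#' @export
hhis_replication_map <- function() {
  origins <- data.frame(
    origin_id = c("oriC1", "oriC2", "oriC4", "oriC5", "oriC6", "oriC7",
                  "oriP"),
    replicon_id = c("chromosome", "chromosome", "minichromosome",
                    "minichromosome", "minichromosome", "minichromosome",
                    "pHH400"),
    cognate = c("cdc6A", "cdc6E", "cdc6G", "cdc6H", "cdc6I", "cdc6J",
                "cdc6K"),
    active = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
    titration_region = c(NA, "oriC2D", NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  replication_map(origins,
                  essential_other = "cdc6A",
                  extra_initiators = c("cdc6B", "cdc6C", "cdc6D", "cdc6F"))
}

#' Predict the outcome of a knockout attempt
#'
#' An origin is functional iff it is active and neither the origin locus nor
#' its cognate initiator gene is deleted. The knockout is `not_obtained`
#' when any replicon is left with no functional origin, or when a titration
#' region is deleted while its regulated origin locus is retained (loss of
#' the negative regulator with the origin still present is lethal,
#' consistent with over-initiation at the deregulated origin). A viable
#' knockout that removes an initiator essential outside replication is
#' `obtained_sick`; anything else is `obtained`.
#'
#' @param map A [replication_map()].
#' @param deleted Character vector of deleted element ids (origins,
#'   initiator genes, titration regions).
#' @return `"obtained"`, `"obtained_sick"` or `"not_obtained"`.
#' @export
predict_knockout <- function(map, deleted) {
  stopifnot(inherits(map, "ReplicationMap"), is.character(deleted))
  unknown <- setdiff(deleted, map_element_ids(map))
  if (length(unknown)) {
    stop("unknown element id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  o <- map$origins
  functional <- o$active & !(o$origin_id %in% deleted) &
    !(o$cognate %in% deleted)
  dead_replicon <- tapply(functional, o$replicon_id, function(x) !any(x))
  if (any(dead_replicon)) return("not_obtained")
  titr <- !is.na(o$titration_region) & o$titration_region %in% deleted &
    !(o$origin_id %in% deleted)
  if (any(titr)) return("not_obtained")
  if (any(map$essential_other %in% deleted)) return("obtained_sick")
  "obtained"
}

#' Describe a test plasmid
#'
#' @param origin Origin id carried by the plasmid.
#' @param cdc6 Initiator gene id carried, or `NULL`.
#' @param titration Titration region id carried, or `NULL`.
#' @return An object of class `PlasmidDesign`.
#' @export
plasmid_design <- function(origin, cdc6 = NULL, titration = NULL) {
  stopifnot(is.character(origin), length(origin) == 1L)
  structure(list(origin = origin, cdc6 = cdc6, titration = titration),
            class = "PlasmidDesign")
}

#' Predict autonomous replication (ARS) activity of a plasmid
#'
#' A plasmid-borne origin replicates autonomously iff its cognate initiator
#' is available -- either carried on the plasmid or still encoded in the
#' host genome (initiators act in trans). Initiators of other origins never
#' substitute: each Cdc6 specifically recognises its own origin.
#'
#' @param map A [replication_map()].
#' @param plasmid A [plasmid_design()].
#' @param host_deleted Element ids deleted from the host genome.
#' @return `"ars_positive"` or `"ars_negative"`.
#' @export
predict_ars <- function(map, plasmid, host_deleted = character()) {
  stopifnot(inherits(map, "ReplicationMap"),
            inherits(plasmid, "PlasmidDesign"))
  o <- map$origins
  row <- o[o$origin_id == plasmid$origin, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop(sprintf("unknown origin '%s'", plasmid$origin), call. = FALSE)
  }
  cognate <- row$cognate
  available <- (!is.null(plasmid$cdc6) && plasmid$cdc6 == cognate) ||
    !(cognate %in% host_deleted)
  if (available) "ars_positive" else "ars_negative"
}

#' Predict plasmid maintenance mode (episomal vs integrative)
#'
#' An ARS-positive plasmid is predicted `integrative` when the carried
#' origin is one whose genomic locus is under titration-region control and
#' the host still retains that origin locus -- the chromosomal copy and the
#' plasmid copy of such a strictly regulated origin are incompatible, and
#' transformants survive by integration. Otherwise the plasmid is
#' `episomal`. This rule is hypothesis-derived: maintenance mode is treated
#' as governed by the presence of the titration-controlled origin in both
#' genome and plasmid, not by homology length.
#'
#' @inheritParams predict_ars
#' @return `"episomal"` or `"integrative"`.
#' @export
predict_compatibility <- function(map, plasmid, host_deleted = character()) {
  if (predict_ars(map, plasmid, host_deleted) != "ars_positive") {
    stop("plasmid is not ARS-positive in this host", call. = FALSE)
  }
  o <- map$origins
  row <- o[o$origin_id == plasmid$origin, , drop = FALSE]
  regulated <- !is.na(row$titration_region)
  host_retains <- !(plasmid$origin %in% host_deleted)
  if (regulated && host_retains) "integrative" else "episomal"
}

#' Equilibrium initiation efficiency under initiator titration
#'
#' Minimal mass-balance model of an ORB-rich region competing with its
#' origin for a fixed pool of initiator protein: `T` total initiator
#' molecules distribute over `k` origin sites and `n_c` competitor sites,
#' all independent with identical dissociation scale `Kd` and single
#' occupancy. Free initiator `F` solves
#' `T = F + (k + n_c) * F / (Kd + F)` (bisection on `[0, T]` to relative
#' tolerance 1e-10) and the origin fires when all `k` of its sites are
#' occupied, so efficiency is `(F / (Kd + F))^k`. Efficiency is strictly
#' decreasing in the number of competitor sites -- more ORBs in the
#' titration region means stronger negative control -- and increasing in
#' total initiator.
#'
#' @param total_initiator Total initiator molecules `T` (> 0).
#' @param site_affinity Dissociation scale `Kd` (> 0), same units as `T`.
#' @param origin_sites Number of ORB sites at the origin, `k >= 1`.
#' @param competitor_sites Number of titration-region sites, `n_c >= 0`.
#' @return Initiation efficiency in `[0, 1]`, with the solved free-initiator
#'   concentration attached as attribute `free_initiator`.
#' @export
initiation_efficiency <- function(total_initiator = 20,
                                  site_affinity = 1,
                                  origin_sites = 2L,
                                  competitor_sites = 0L) {
  T_ <- total_initiator; Kd <- site_affinity
  k <- origin_sites; nc <- competitor_sites
  stopifnot(T_ > 0, Kd > 0, k >= 1L, nc >= 0L)
  g <- function(F_) F_ + (k + nc) * F_ / (Kd + F_) - T_
  lo <- 0; hi <- T_
  for (iter in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) <= 1e-10 * T_) break
  }
  F_ <- (lo + hi) / 2
  resid <- abs(T_ - F_ - (k + nc) * F_ / (Kd + F_)) / T_
  stopifnot(resid <= 1e-9)  # cannot fail for valid params
  eff <- (F_ / (Kd + F_))^k
  attr(eff, "free_initiator") <- F_
  eff
}

#' Curated knockout outcomes for H. hispanica
#'
#' The packaged truth table of published single and serial knockout attempts
#' (origins, cdc6 genes, and titration-region deletions) with their observed
#' outcomes; [predict_knockout()] on [hhis_replication_map()] reproduces
#' every row.
#'
#' @return Data frame with columns `set`, `deleted` (comma-separated element
#'   ids) and `outcome`.
#' @export
hhis_knockout_outcomes <- function() {
  path <- system.file("extdata", "hhis_knockout_outcomes.tsv",
                      package = "oriscope", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
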