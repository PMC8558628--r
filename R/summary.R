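# Per-order summary statistics and the screens for non-mitochondrial
# "other DNA": plasmid-like circles and mitovirus-like regions.

#' Summary statistics over a mitogenome metadata table
#'
#' Computes the headline descriptive numbers of a multi-species
#' mitogenome survey: species/genus/family counts, the max/min genome
#' size ratio, per-species repeat and MTPT percentages, circular vs
#' linear topology counts among the newly assembled species, and the
#' fraction of the order's families sampled. Percentages and the size
#' ratio are rounded half-up at one decimal; the family percentage is
#' rounded to an integer. A species counts as circular when its
#' chromosome spec ends in \code{C} (per-species topology is uniform in
#' practice; a mixed spec would count as linear with a warning).
#'
#' @param records Metadata table from \code{\link{read_metadata}}.
#' @param total_families_in_order Number of families in the order (an
#'   input, not hard-coded).
#' @return List of summary statistics; \code{per_species} carries the
#'   per-record percentages.
#' @export
table1_stats <- function(records, total_families_in_order) {
  if (nrow(records) == 0L) stop("no metadata records")
  if (any(records$length_bp <= 0L)) stop("zero-length record")
  n_families <- length(unique(records$family))
  if (total_families_in_order < n_families)
    stop("total_families_in_order below the number of sampled families")
  per_species <- data.frame(
    species = records$species, genus = records$genus,
    family = records$family, newly_assembled = records$newly_assembled,
    length_bp = records$length_bp,
    mtpt_pct = round_half_up(100 * records$mtpt_bp / records$length_bp, 1L),
    repeat_pct = round_half_up(100 * records$repeat_bp / records$length_bp,
                               1L),
    circular = grepl("C$", records$chromosome_spec),
    stringsAsFactors = FALSE)
  newly <- per_species[per_species$newly_assembled, , drop = FALSE]
  list(
    n_species = nrow(records),
    n_genera = length(unique(records$genus)),
    n_families = n_families,
    size_ratio_max_min = round_half_up(
      max(records$length_bp) / min(records$length_bp), 1L),
    largest_bp = max(records$length_bp),
    smallest_bp = min(records$length_bp),
    n_circular_species = sum(newly$circular),
    n_linear_species = sum(!newly$circular),
    families_sampled_pct_of_total = as.integer(round_half_up(
      100 * n_families / total_families_in_order, 0L)),
    per_species = per_species)
}

#' Screen contigs for plasmid-like circles
#'
#' A plasmid-like element is a small autonomous circle co-occurring
#' with the mitogenome at similar depth but largely lacking mitogenome
#' homology. Candidates are circular contigs of 1-20 kb whose depth
#' lies within the mitochondrial coverage band (default 0.5-2x) and
#' whose mitochondrial homology covers under 20 percent of their
#' length. Each candidate is reported with its GC, its plastid homology
#' (small plastid-like regions are tolerated), ORFs of at least 100
#' codons, and — when nuclear references are supplied — whether hits to
#' a single nuclear reference fully encompass it.
#'
#' @param contigs Named contig list (records with \code{seq},
#'   \code{mean_cov}, \code{is_circular}).
#' @param base_cov Single-copy mitochondrial depth.
#' @param mito_set List of mitogenome \code{mito_seq}s for the homology
#'   exclusion.
#' @param plastome Optional plastome for the plastid-homology report.
#' @param nuclear_refs Optional list of nuclear reference sequences.
#' @param thresholds See \code{\link{default_thresholds}}.
#' @param min_orf_aa ORF reporting floor (codons).
#' @return List of candidate records.
#' @export
detect_plasmid_like <- function(contigs, base_cov, mito_set,
                                plastome = NULL, nuclear_refs = NULL,
                                thresholds = default_thresholds(),
                                min_orf_aa = 100L) {
  if (base_cov <= 0) stop("base_cov must be positive")
  band <- thresholds$plasmid_cov_band
  out <- list()
  if (inherits(mito_set, "mito_seq")) mito_set <- list(mito_set)
  for (id in names(contigs)) {
    ctg <- contigs[[id]]
    circ <- isTRUE(ctg$is_circular) ||
      identical(ctg$seq$topology, "circular")
    len <- seq_length(ctg$seq)
    if (!circ || len < 1000L || len > 20000L) next
    ratio <- ctg$mean_cov / base_cov
    if (ratio < band[1] || ratio > band[2]) next
    mito_bp <- 0L
    for (g in mito_set) {
      h <- find_local_matches(ctg$seq, g, min_len = 100L,
                              min_identity = 80,
                              word_size = thresholds$seed_word_size)
      if (nrow(h))
        mito_bp <- max(mito_bp,
                       union_length(hits_query_intervals(h, id)))
    }
    if (mito_bp / len >= thresholds$plasmid_max_mito_frac) next
    plastid_bp <- 0L
    if (!is.null(plastome)) {
      h <- find_local_matches(ctg$seq, plastome, min_len = 100L,
                              min_identity = 80,
                              word_size = thresholds$seed_word_size)
      if (nrow(h))
        plastid_bp <- union_length(hits_query_intervals(h, id))
    }
    encompassed <- NA
    if (!is.null(nuclear_refs)) {
      encompassed <- FALSE
      for (nr in nuclear_refs) {
        h <- find_local_matches(ctg$seq, nr, min_len = 100L,
                                min_identity = 90,
                                word_size = thresholds$seed_word_size)
        if (nrow(h) &&
            union_length(hits_query_intervals(h, id)) >= 0.95 * len) {
          encompassed <- TRUE
          break
        }
      }
    }
    seqc <- ctg$seq
    seqc$topology <- "circular"
    out[[id]] <- list(
      contig = id, seq = seqc, length_bp = len,
      gc_percent = gc_content(seqc),
      coverage_ratio_to_mito = ratio,
      mito_homology_bp = mito_bp, plastid_homology_bp = plastid_bp,
      nuclear_encompassed = encompassed,
      orfs = find_orfs(seqc, min_aa = min_orf_aa))
  }
  out
}

#' Screen a mitogenome for mitovirus-like regions
#'
#' Regions of the genome matching a viral reference (mitovirus
#' RdRP-like sequences) are reported with their best reference; each
#' region is then searched against the other mitogenomes of the set and
#' hits of at least \code{mitovirus_min_hit_bp} (default 700 bp) are
#' collected into an alignment-ready sequence set for cross-taxon
#' comparison.
#'
#' @param genome Target \code{mito_seq}.
#' @param viral_refs Named list of labelled viral reference sequences.
#' @param other_genomes Named list of other mitogenomes.
#' @param thresholds See \code{\link{default_thresholds}}.
#' @param min_region_bp Minimum viral-hit region length to report.
#' @return List: \code{regions} (data.frame with best reference per
#'   region), \code{cross_taxon} (hit table of other-genome hits >=
#'   the floor), \code{sequences} (named list of \code{mito_seq} ready
#'   for alignment: each region plus its qualifying cross-taxon hits).
#' @export
screen_mitovirus_like <- function(genome, viral_refs, other_genomes = list(),
                                  thresholds = default_thresholds(),
                                  min_region_bp = 300L) {
  if (length(viral_refs) == 0L) stop("no viral references supplied")
  hits <- list()
  for (vid in names(viral_refs)) {
    h <- find_local_matches(genome, viral_refs[[vid]],
                            min_len = min_region_bp, min_identity = 70,
                            word_size = thresholds$seed_word_size)
    if (nrow(h)) { h$ref_id <- vid; hits[[length(hits) + 1L]] <- h }
  }
  empty <- list(regions = data.frame(start = integer(), end = integer(),
                                     best_ref = character(),
                                     identity_pct = numeric(),
                                     stringsAsFactors = FALSE),
                cross_taxon = data.frame(region = integer(),
                                         genome = character(),
                                         length = integer(),
                                         identity_pct = numeric(),
                                         stringsAsFactors = FALSE),
                sequences = list())
  if (length(hits) == 0L) return(empty)
  hits <- do.call(rbind, hits)
  iv <- IRanges::reduce(IRanges::IRanges(hits$qstart + 1L, hits$qend))
  regions <- data.frame(start = IRanges::start(iv) - 1L,
                        end = IRanges::end(iv),
                        best_ref = NA_character_,
                        identity_pct = NA_real_, stringsAsFactors = FALSE)
  sequences <- list()
  cross <- list()
  for (r in seq_len(nrow(regions))) {
    inr <- hits$qstart < regions$end[r] & hits$qend > regions$start[r]
    best <- hits[inr, , drop = FALSE]
    best <- best[which.max(best$score), , drop = FALSE]
    regions$best_ref[r] <- best$ref_id
    regions$identity_pct[r] <- best$identity_pct
    rid <- sprintf("%s_mitovirus_region%d", genome$id, r)
    rseq <- substr(genome$residues, regions$start[r] + 1L, regions$end[r])
    region_seq <- dna_seq(rid, rseq, "linear",
                          sprintf("best match %s", best$ref_id))
    sequences[[rid]] <- region_seq
    for (gid in names(other_genomes)) {
      h <- find_local_matches(region_seq, other_genomes[[gid]],
                              min_len = thresholds$seed_word_size * 2L,
                              min_identity = 70,
                              word_size = thresholds$seed_word_size)
      h <- h[h$length >= thresholds$mitovirus_min_hit_bp, , drop = FALSE]
      for (k in seq_len(nrow(h))) {
        cross[[length(cross) + 1L]] <- data.frame(
          region = r, genome = gid, length = h$length[k],
          identity_pct = h$identity_pct[k], stringsAsFactors = FALSE)
        hid <- sprintf("%s_hit%d", gid, k)
        sequences[[hid]] <- dna_seq(
          hid, substr(other_genomes[[gid]]$residues,
                      h$sstart[k] + 1L, h$send[k]), "linear",
          sprintf("cross-taxon hit of %s", rid))
      }
    }
  }
  list(regions = regions,
       cross_taxon = if (length(cross)) do.call(rbind, cross) else
         empty$cross_taxon,
       sequences = sequences)
}
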