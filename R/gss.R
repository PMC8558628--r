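# Genus-specific sequence (GSS) extraction and attribution.
#
# A GSS is a region of a mitogenome, at least gss_min_bp long, with no
# retained homology (cross-genus hits >= gss_hit_mask_bp) to any
# mitogenome of another genus in the comparison set. Cross-genus hits
# shorter than the mask floor are disregarded as homology evidence:
# they cannot break a specific run. GSSs are then attributed against a
# labelled reference collection; the maximal-score hit of each
# non-overlapping GSS sub-region is a best hit, so one GSS can have
# several.

#' Build a genome set for GSS analysis
#'
#' @param genomes Named list of \code{mito_seq} genomes.
#' @param taxon data.frame with at least \code{seq_id} and \code{genus};
#'   every genome needs a row.
#' @param genus_override Optional named character vector reassigning
#'   individual genomes to their own (or another) genus — the mechanism
#'   used to split a non-monophyletic species out of its genus.
#' @return A \code{genome_set} list.
#' @export
genome_set <- function(genomes, taxon, genus_override = NULL) {
  missing_tax <- setdiff(names(genomes), taxon$seq_id)
  if (length(missing_tax))
    stop("no taxon record for genome(s): ",
         paste(missing_tax, collapse = ", "))
  if (!is.null(genus_override)) {
    for (id in names(genus_override))
      taxon$genus[taxon$seq_id == id] <- genus_override[[id]]
  }
  structure(list(genomes = genomes, taxon = taxon), class = "genome_set")
}

.genus_of <- function(set, seq_id) {
  set$taxon$genus[match(seq_id, set$taxon$seq_id)]
}

#' Mask positions of a genome that are homologous across genera
#'
#' Marks every target position covered by a cross-genus hit of at least
#' \code{gss_hit_mask_bp} aligned length; hits from same-genus genomes
#' and hits below the floor carry no evidence.
#'
#' @param target_id Id of the target genome within the set.
#' @param set A \code{\link{genome_set}} (>= 2 genera).
#' @param thresholds See \code{\link{default_thresholds}}.
#' @return Logical vector over the target (TRUE = cross-genus
#'   homologous), with per-partner masked bp in attribute
#'   \code{per_partner}.
#' @export
build_cross_genus_mask <- function(target_id, set,
                                   thresholds = default_thresholds()) {
  if (!target_id %in% names(set$genomes))
    stop("target genome not in the set: ", target_id)
  if (length(unique(set$taxon$genus)) < 2L)
    stop("GSS analysis needs at least two genera in the set")
  target <- set$genomes[[target_id]]
  tg <- .genus_of(set, target_id)
  L <- seq_length(target)
  mask <- logical(L)
  per_partner <- numeric(0)
  for (pid in names(set$genomes)) {
    if (pid == target_id) next
    if (identical(.genus_of(set, pid), tg)) next
    hits <- find_local_matches(target, set$genomes[[pid]],
                               min_len = thresholds$gss_hit_mask_bp,
                               min_identity = thresholds$gss_min_identity_pct,
                               word_size = thresholds$seed_word_size)
    pm <- logical(L)
    for (k in seq_len(nrow(hits)))
      pm[(hits$qstart[k] + 1L):hits$qend[k]] <- TRUE
    per_partner[pid] <- sum(pm)
    mask <- mask | pm
  }
  attr(mask, "per_partner") <- per_partner
  mask
}

#' Extract genus-specific sequences from a homology mask
#'
#' Maximal unmasked runs of at least \code{min_len} bp. On circular
#' genomes a run may join across the origin; such a record keeps
#' \code{start} in \code{[0, L)} with \code{end = start + length}
#' extending virtually past \code{L}.
#'
#' @param target Target \code{mito_seq}.
#' @param mask Logical mask from \code{\link{build_cross_genus_mask}}.
#' @param min_len Minimum GSS length (bp).
#' @return data.frame: \code{gss_id}, \code{seq_id}, \code{start},
#'   \code{end}, \code{length}, \code{sequence}.
#' @export
extract_gss <- function(target, mask, min_len = 300L) {
  L <- seq_length(target)
  if (length(mask) != L)
    stop("mask length (", length(mask), ") != genome length (", L, ")")
  empty <- data.frame(gss_id = character(), seq_id = character(),
                      start = integer(), end = integer(),
                      length = integer(), sequence = character(),
                      stringsAsFactors = FALSE)
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- c(0L, head(ends, -1L))
  runs <- data.frame(start = starts, end = ends, open = !r$values)
  runs <- runs[runs$open, c("start", "end"), drop = FALSE]
  if (nrow(runs) == 0L) return(empty)
  wrap <- identical(target$topology, "circular") && nrow(runs) >= 2L &&
    runs$start[1L] == 0L && runs$end[nrow(runs)] == L
  if (identical(target$topology, "circular") && nrow(runs) == 1L &&
      runs$start[1L] == 0L && runs$end[1L] == L) {
    # fully unmasked circle
  } else if (wrap) {
    runs$end[nrow(runs)] <- L + runs$end[1L]
    runs <- runs[-1L, , drop = FALSE]
  }
  runs <- runs[runs$end - runs$start >= min_len, , drop = FALSE]
  if (nrow(runs) == 0L) return(empty)
  res2 <- paste0(target$residues, target$residues)
  data.frame(
    gss_id = sprintf("%s_gss%02d", target$id, seq_len(nrow(runs))),
    seq_id = target$id, start = runs$start, end = runs$end,
    length = runs$end - runs$start,
    sequence = substring(res2, runs$start + 1L, runs$end),
    stringsAsFactors = FALSE)
}

#' Read a labelled reference collection
#'
#' FASTA whose headers carry \code{[taxon=..] [order=..]
#' [compartment=..]} tokens (compartment one of mitochondrial, plastid,
#' other).
#'
#' @param path FASTA file.
#' @return Named list of labelled \code{mito_seq} entries.
#' @export
read_refdb <- function(path) {
  seqs <- read_fasta(path)
  token <- function(desc, key) {
    m <- regmatches(desc, regexec(paste0("\\[", key, "=([^]]*)\\]"), desc))[[1]]
    if (length(m) == 2L) m[2] else "unknown"
  }
  for (id in names(seqs)) {
    d <- seqs[[id]]$description
    seqs[[id]]$taxon <- token(d, "taxon")
    seqs[[id]]$order <- token(d, "order")
    seqs[[id]]$compartment <- token(d, "compartment")
  }
  seqs
}

#' Attribute GSSs against a labelled reference collection
#'
#' For each GSS, hits against the collection are computed and the
#' maximal-score hit of each non-overlapping sub-region (reciprocal
#' overlap with an already-accepted hit below 50 percent) becomes a
#' best hit — so a GSS matching two different references in two halves
#' yields two best hits. Best hits shorter than
#' \code{attribution_min_best_bp} are dropped. A best hit to a
#' plastid-compartment reference that overlaps the genome's own MTPT
#' annotation by at least half is flagged an MTPT artifact and excluded
#' from linkage totals. Score ties over the same sub-region are all
#' reported with their weight split equally.
#'
#' @param records GSS table from \code{\link{extract_gss}}.
#' @param refdb Labelled collection (\code{\link{read_refdb}} or
#'   \code{\link{make_donor_pools}}).
#' @param mtpt_intervals Optional interval table of the source genome's
#'   MTPT regions.
#' @param thresholds See \code{\link{default_thresholds}}.
#' @return data.frame: one row per best hit (\code{gss_id},
#'   \code{ref_id}, \code{taxon}, \code{order}, \code{compartment},
#'   \code{qstart}, \code{qend}, \code{length}, \code{identity_pct},
#'   \code{score}, \code{weight}, \code{is_mtpt_artifact}).
#' @export
attribute_gss <- function(records, refdb, mtpt_intervals = NULL,
                          thresholds = default_thresholds()) {
  if (length(refdb) == 0L) stop("empty reference collection")
  empty <- data.frame(gss_id = character(), ref_id = character(),
                      taxon = character(), order = character(),
                      compartment = character(), qstart = integer(),
                      qend = integer(), length = integer(),
                      identity_pct = numeric(), score = numeric(),
                      weight = numeric(), is_mtpt_artifact = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(records) == 0L) return(empty)
  min_best <- thresholds$attribution_min_best_bp
  out <- list()
  for (i in seq_len(nrow(records))) {
    gseq <- records$sequence[i]
    hits <- list()
    for (rid in names(refdb)) {
      h <- find_local_matches(gseq, refdb[[rid]],
                              min_len = max(thresholds$seed_word_size * 2L,
                                            50L),
                              min_identity = 70,
                              word_size = thresholds$seed_word_size)
      if (nrow(h)) { h$ref_id <- rid; hits[[length(hits) + 1L]] <- h }
    }
    if (length(hits) == 0L) next
    hits <- do.call(rbind, hits)
    hits <- hits[order(-hits$score, hits$qstart, hits$ref_id), , drop = FALSE]
    accepted <- list()
    for (k in seq_len(nrow(hits))) {
      h <- hits[k, ]
      clash <- FALSE
      tied_with <- NA_integer_
      for (a in seq_along(accepted)) {
        acc <- accepted[[a]]$row
        ov <- max(0L, min(h$qend, acc$qend) - max(h$qstart, acc$qstart))
        rec <- ov / min(h$qend - h$qstart, acc$qend - acc$qstart)
        if (rec >= 0.5) {
          if (h$score == acc$score && h$qstart == acc$qstart &&
              h$qend == acc$qend) tied_with <- a else clash <- TRUE
          break
        }
      }
      if (clash) next
      if (!is.na(tied_with)) {
        accepted[[tied_with]]$ties <- c(accepted[[tied_with]]$ties,
                                        list(h))
      } else {
        accepted[[length(accepted) + 1L]] <- list(row = h, ties = list())
      }
    }
    for (acc in accepted) {
      group <- c(list(acc$row), acc$ties)
      w <- 1 / length(group)
      for (h in group) {
        if (h$length < min_best) next
        ref <- refdb[[h$ref_id]]
        artifact <- FALSE
        if (identical(ref$compartment, "plastid") &&
            !is.null(mtpt_intervals) && nrow(mtpt_intervals)) {
          g0 <- records$start[i] + h$qstart
          g1 <- records$start[i] + h$qend
          ov <- sum(pmax(0L, pmin(mtpt_intervals$end, g1) -
                           pmax(mtpt_intervals$start, g0)))
          artifact <- ov >= 0.5 * (g1 - g0)
        }
        out[[length(out) + 1L]] <- data.frame(
          gss_id = records$gss_id[i], ref_id = h$ref_id,
          taxon = if (is.null(ref$taxon)) "unknown" else ref$taxon,
          order = if (is.null(ref$order)) "unknown" else ref$order,
          compartment = if (is.null(ref$compartment)) "other" else
            ref$compartment,
          qstart = h$qstart, qend = h$qend, length = h$length,
          identity_pct = h$identity_pct, score = h$score, weight = w,
          is_mtpt_artifact = artifact, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty)
  df <- do.call(rbind, out)
  df[order(df$gss_id, df$qstart, df$ref_id), , drop = FALSE]
}

#' Summarize GSS attributions into a linkage table
#'
#' Per (genus, order): summed best-hit lengths (tie weights applied,
#' MTPT artifacts excluded); per genus: compartment proportions and
#' total GSS bp. Row order is deterministic (genus, then order).
#'
#' @param attributions Attribution table(s) from
#'   \code{\link{attribute_gss}}; GSS records from several genomes may
#'   be concatenated.
#' @param records The corresponding GSS records.
#' @param set The \code{\link{genome_set}}.
#' @return List: \code{links} (genus/order/total_linked_bp),
#'   \code{compartments} (genus/compartment/proportion),
#'   \code{gss_totals} (genus/total_gss_bp).
#' @export
linkage_table <- function(attributions, records, set) {
  genus_of_gss <- setNames(.genus_of(set, records$seq_id), records$gss_id)
  gss_tot <- tapply(records$length, .genus_of(set, records$seq_id), sum)
  all_genera <- sort(unique(set$taxon$genus))
  gss_totals <- data.frame(
    genus = all_genera,
    total_gss_bp = as.integer(ifelse(is.na(gss_tot[all_genera]), 0L,
                                     gss_tot[all_genera])),
    stringsAsFactors = FALSE)
  att <- attributions[!attributions$is_mtpt_artifact, , drop = FALSE]
  if (nrow(att) == 0L)
    return(list(links = data.frame(genus = character(), order = character(),
                                   total_linked_bp = numeric(),
                                   stringsAsFactors = FALSE),
                compartments = data.frame(genus = character(),
                                          compartment = character(),
                                          proportion = numeric(),
                                          stringsAsFactors = FALSE),
                gss_totals = gss_totals))
  att$genus <- genus_of_gss[att$gss_id]
  wlen <- att$length * att$weight
  links <- aggregate(wlen, by = list(genus = att$genus, order = att$order),
                     FUN = sum)
  names(links)[3] <- "total_linked_bp"
  links <- links[order(links$genus, links$order), , drop = FALSE]
  rownames(links) <- NULL
  comp <- aggregate(wlen, by = list(genus = att$genus,
                                    compartment = att$compartment),
                    FUN = sum)
  names(comp)[3] <- "bp"
  tot <- tapply(comp$bp, comp$genus, sum)
  comp$proportion <- comp$bp / tot[comp$genus]
  comp <- comp[order(comp$genus, comp$compartment),
               c("genus", "compartment", "proportion")]
  rownames(comp) <- NULL
  list(links = links, compartments = comp, gss_totals = gss_totals)
}

#' Fraction of a genome covered by cross-genus homology
#'
#' Masked positions / genome length — the complement of GSS-eligible
#' space, reported overall and per partner genome.
#'
#' @inheritParams build_cross_genus_mask
#' @return List: \code{overall} (fraction in [0,1]), \code{per_partner}
#'   (named fractions).
#' @export
shared_homology_fraction <- function(target_id, set,
                                     thresholds = default_thresholds()) {
  mask <- build_cross_genus_mask(target_id, set, thresholds)
  L <- length(mask)
  list(overall = sum(mask) / L,
       per_partner = attr(mask, "per_partner") / L)
}
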