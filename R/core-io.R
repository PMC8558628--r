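# Sequence / interval / coverage data model and format IO.
#
# Coordinates are 0-based half-open everywhere in this package. Circular
# topology is carried as sequence metadata; individual features never wrap
# an interval (a wrapped feature on a circular sequence is represented as
# two intervals).

#' DNA sequence with identifier and topology
#'
#' Lightweight container used throughout the package: an id, a residue
#' string over \code{A/C/G/T/N}, a topology flag and a free-text
#' description. Circular topology means coordinate arithmetic on the
#' sequence wraps modulo its length.
#'
#' @param id Sequence identifier (unique within a collection).
#' @param residues DNA string.
#' @param topology \code{"linear"} or \code{"circular"}.
#' @param description Free-text description.
#' @return An object of class \code{mito_seq}.
#' @export
dna_seq <- function(id, residues, topology = c("linear", "circular"),
                    description = "") {
  topology <- match.arg(topology)
  residues <- toupper(as.character(residues))
  if (is.na(residues) || nchar(residues) == 0L)
    stop("sequence '", id, "': residues must be non-empty")
  if (grepl("[^ACGTN]", residues))
    stop("sequence '", id, "': residues outside {A,C,G,T,N}")
  structure(
    list(id = as.character(id), residues = residues,
         topology = topology, description = as.character(description)),
    class = "mito_seq")
}

#' @export
print.mito_seq <- function(x, ...) {
  cat(sprintf("<mito_seq> %s (%s, %d bp)\n", x$id, x$topology,
              seq_length(x)))
  invisible(x)
}

#' Sequence length in bp
#' @param x A \code{mito_seq}.
#' @return Integer length.
#' @export
seq_length <- function(x) nchar(x$residues)

#' Reverse complement of a sequence or residue string
#' @param x A \code{mito_seq} or a character residue string.
#' @return Same type as the input.
#' @export
revcomp <- function(x) {
  if (inherits(x, "mito_seq")) {
    x$residues <- .revcomp_cpp(x$residues)
    return(x)
  }
  .revcomp_cpp(as.character(x))
}

#' Build an interval table
#'
#' Intervals are 0-based half-open rows \code{(seq_id, start, end, strand)}
#' with \code{0 <= start < end}.
#'
#' @param seq_id,start,end,strand Vectors recycled to common length.
#' @return A data.frame with class \code{mito_intervals}.
#' @export
intervals <- function(seq_id, start, end, strand = "+") {
  n <- max(length(seq_id), length(start), length(end))
  df <- data.frame(seq_id = rep_len(as.character(seq_id), n),
                   start = rep_len(as.integer(start), n),
                   end = rep_len(as.integer(end), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  bad <- df$start < 0L | df$end <= df$start
  if (any(bad))
    stop("invalid interval(s): start must satisfy 0 <= start < end (rows ",
         paste(which(bad), collapse = ", "), ")")
  df
}

empty_intervals <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Total bp covered by a set of intervals, counting overlap once
#'
#' Size of the set-union of positions covered by the intervals; the
#' result is independent of interval order and of how often a position
#' is covered.
#'
#' @param ivs Interval data.frame (\code{\link{intervals}}); all rows must
#'   share one \code{seq_id}.
#' @return Integer bp.
#' @export
union_length <- function(ivs) {
  if (is.null(ivs) || nrow(ivs) == 0L) return(0L)
  if (length(unique(ivs$seq_id)) > 1L)
    stop("union_length: intervals span multiple seq_ids: ",
         paste(unique(ivs$seq_id), collapse = ", "))
  r <- IRanges::reduce(IRanges::IRanges(start = ivs$start + 1L,
                                        end = ivs$end))
  sum(IRanges::width(r))
}

.topology_token <- "\\[topology=circular\\]"

#' Read DNA sequences from a FASTA file
#'
#' Headers are split into an id (first whitespace-delimited token) and a
#' description. A \code{[topology=circular]} token in the description
#' marks the sequence circular; the default is linear.
#'
#' @param path FASTA file.
#' @return Named list of \code{mito_seq} objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e)
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    stop("FASTA file contains no sequences: ", path)
  headers <- names(set)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    hdr <- headers[[i]]
    id <- sub("\\s.*$", "", hdr)
    desc <- if (grepl("\\s", hdr)) sub("^\\S+\\s+", "", hdr) else ""
    topo <- if (grepl(.topology_token, desc)) "circular" else "linear"
    desc <- trimws(gsub(.topology_token, "", desc))
    out[[i]] <- dna_seq(id, as.character(set[[i]]), topo, desc)
  }
  ids <- vapply(out, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(out) <- ids
  out
}

#' Write DNA sequences to a FASTA file
#'
#' Circular sequences gain a \code{[topology=circular]} description token
#' so that \code{\link{read_fasta}} round-trips the topology.
#'
#' @param seqs A \code{mito_seq} or list of them.
#' @param path Output file.
#' @param width Line-wrap width.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "mito_seq")) seqs <- list(seqs)
  if (length(seqs) == 0L) stop("write_fasta: empty sequence collection")
  hdrs <- vapply(seqs, function(s) {
    desc <- s$description
    if (identical(s$topology, "circular"))
      desc <- trimws(paste(desc, "[topology=circular]"))
    if (nzchar(desc)) paste(s$id, desc) else s$id
  }, "")
  set <- Biostrings::DNAStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- hdrs
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a mitogenome metadata table
#'
#' Accepts a comma- or tab-separated table whose header names the fields
#' of a taxon record: \code{species}, \code{family}, \code{length_bp},
#' \code{chromosome_spec} (e.g. \code{"3C"}, \code{"16L"}),
#' \code{gc_percent}, \code{repeat_bp}, \code{mtpt_bp}, and optionally
#' \code{genus} (derived from the species binomial when absent). A
#' trailing asterisk on a species name marks a previously published
#' assembly (\code{newly_assembled = FALSE}). Thousands separators in
#' numeric fields are accepted.
#'
#' @param path Table file.
#' @return A data.frame of taxon records.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE, strip.white = TRUE,
                   colClasses = "character")
  required <- c("species", "family", "length_bp", "chromosome_spec",
                "gc_percent", "repeat_bp", "mtpt_bp")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("metadata schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("metadata table has no rows: ", path)
    return(data.frame(species = character(), genus = character(),
                      family = character(), newly_assembled = logical(),
                      chromosome_spec = character(), length_bp = integer(),
                      gc_percent = numeric(), repeat_bp = integer(),
                      mtpt_bp = integer(), stringsAsFactors = FALSE))
  }
  num <- function(col, integer = TRUE) {
    raw <- gsub(",", "", df[[col]], fixed = TRUE)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & nzchar(trimws(df[[col]])))
    if (length(bad) || anyNA(val))
      stop("metadata row error: non-numeric '", col, "' in row(s) ",
           paste(union(bad, which(is.na(val))), collapse = ", "))
    if (integer) as.integer(round(val)) else val
  }
  species_raw <- trimws(df$species)
  newly <- !grepl("\\*\\s*$", species_raw)
  species <- sub("\\*\\s*$", "", species_raw)
  genus <- if ("genus" %in% names(df)) trimws(df$genus) else
    vapply(strsplit(species, "\\s+"), `[[`, "", 1L)
  out <- data.frame(
    species = species, genus = genus, family = trimws(df$family),
    newly_assembled = newly,
    chromosome_spec = trimws(df$chromosome_spec),
    length_bp = num("length_bp"),
    gc_percent = num("gc_percent", integer = FALSE),
    repeat_bp = num("repeat_bp"), mtpt_bp = num("mtpt_bp"),
    stringsAsFactors = FALSE)
  if (any(out$length_bp <= 0L))
    stop("metadata row error: non-positive length_bp in row(s) ",
         paste(which(out$length_bp <= 0L), collapse = ", "))
  bad_spec <- !grepl("^[0-9]+[CL]$", out$chromosome_spec)
  if (any(bad_spec))
    stop("metadata row error: chromosome_spec must match '[0-9]+[CL]' ",
         "in row(s) ", paste(which(bad_spec), collapse = ", "))
  out
}

#' Read a coverage table
#'
#' Either a 2-column TSV \code{(contig_id, mean_depth)} of per-contig
#' mean depths, or a 3-column per-base track
#' \code{(seq_id, pos0, depth)}.
#'
#' @param path TSV file (no header required; a header line is detected
#'   and skipped).
#' @return A data.frame; attribute \code{per_base} says which form.
#' @export
read_coverage <- function(path) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) && is.character(df[[2]]) &&
      is.na(suppressWarnings(as.numeric(df[1, 2]))))
    df <- df[-1, , drop = FALSE]
  if (ncol(df) == 2L) {
    out <- data.frame(contig_id = as.character(df[[1]]),
                      mean_depth = as.numeric(df[[2]]),
                      stringsAsFactors = FALSE)
    if (any(out$mean_depth < 0)) stop("negative depth in ", path)
    attr(out, "per_base") <- FALSE
  } else if (ncol(df) >= 3L) {
    out <- data.frame(seq_id = as.character(df[[1]]),
                      pos = as.integer(df[[2]]),
                      depth = as.numeric(df[[3]]),
                      stringsAsFactors = FALSE)
    if (any(out$depth < 0)) stop("negative depth in ", path)
    attr(out, "per_base") <- TRUE
  } else {
    stop("coverage table must have 2 (per-contig) or 3 (per-base) columns")
  }
  out
}

#' Analysis thresholds
#'
#' One bundle of the bp-length, identity and e-value thresholds applied
#' across the pipeline, with defaults matching the published protocol:
#' 16-bp search words; reference hits under 500 bp ignored when
#' classifying contigs; dispersed repeats require >= 50 bp at >= 95
#' percent identity; plastome hits under 100 bp are masked for MTPT
#' quantification; cross-genus hits under 70 bp carry no homology
#' evidence in the GSS scan and specific runs must reach 300 bp;
#' attribution best hits require 100 bp; mitovirus-region cross-taxon
#' hits require 700 bp; synteny links require 500 bp.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of thresholds.
#' @export
default_thresholds <- function(...) {
  th <- list(
    seed_word_size = 16L,
    evalue_ref_search = 1e-20,
    evalue_gss = 1e-5,
    min_ref_hit_bp = 500L,
    min_repeat_bp = 50L,
    repeat_min_identity_pct = 95,
    mtpt_mask_bp = 100L,
    mtpt_min_identity_pct = 70,
    gss_hit_mask_bp = 70L,
    gss_min_identity_pct = 70,
    gss_min_bp = 300L,
    attribution_min_best_bp = 100L,
    mitovirus_min_hit_bp = 700L,
    synteny_link_min_bp = 500L,
    bait_tolerance_frac = 0.4,
    mtpt_max_fill_bp = 10000L,
    plasmid_cov_band = c(0.5, 2.0),
    plasmid_max_mito_frac = 0.2)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(th))
  if (length(unknown))
    stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
  th[names(ov)] <- ov
  num <- unlist(th[c("seed_word_size", "min_ref_hit_bp", "min_repeat_bp",
                     "repeat_min_identity_pct", "mtpt_mask_bp",
                     "gss_hit_mask_bp", "gss_min_bp",
                     "attribution_min_best_bp", "mitovirus_min_hit_bp",
                     "synteny_link_min_bp")])
  if (any(num <= 0)) stop("thresholds must be positive")
  if (th$repeat_min_identity_pct <= 0 || th$repeat_min_identity_pct > 100)
    stop("repeat_min_identity_pct must be in (0, 100]")
  th
}

# Round half away from zero at `digits` decimal places. R's round() is
# round-half-even; percentage reporting here follows the print convention
# of rounding .x5 upward.
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Canonical form of a circular sequence
#'
#' The deterministic representative used for equality testing: the
#' lexicographically smallest rotation over both strands.
#'
#' @param x A \code{mito_seq} or residue string.
#' @return Residue string in canonical form.
#' @export
canonical_rotation <- function(x) {
  s <- if (inherits(x, "mito_seq")) x$residues else as.character(x)
  fwd <- .smallest_rotation_cpp(s)
  rev <- .smallest_rotation_cpp(.revcomp_cpp(s))
  if (rev < fwd) rev else fwd
}
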