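# Pairwise local homology search.
#
# The built-in matcher is seed-and-extend (exact word seeds, ungapped
# X-drop extension, substitution scoring +1/-2) and filters hits by
# aligned length and percent identity rather than by e-value; e-value
# thresholds apply only through the external-tool adapter. Output order
# is deterministic: descending score, then query start.

.empty_hits <- function(qid = NA_character_, sid = NA_character_) {
  data.frame(qid = character(), sid = character(),
             qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(),
             strand = character(), length = integer(),
             matches = integer(), identity_pct = numeric(),
             score = numeric(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

.as_hit_table <- function(df, qid, sid) {
  if (nrow(df) == 0L) return(.empty_hits())
  data.frame(qid = qid, sid = sid,
             qstart = df$qstart, qend = df$qend,
             sstart = df$sstart, send = df$send,
             strand = df$strand, length = df$length,
             matches = df$matches, identity_pct = df$identity_pct,
             score = as.numeric(df$score), evalue = NA_real_,
             stringsAsFactors = FALSE)
}

#' Find local matches between two sequences
#'
#' Reports every maximal-scoring local match of at least \code{min_len}
#' aligned columns at identity \code{>= min_identity} on both strands.
#' Identity is matching columns / alignment columns x 100. A hit
#' contained in a higher-scoring hit on both axes is merged away.
#'
#' @param query,subject \code{mito_seq} objects (or residue strings).
#' @param min_len Minimum aligned length in bp.
#' @param min_identity Minimum percent identity.
#' @param word_size Seed word size (>= 8).
#' @param both_strands Search the minus strand too.
#' @return Hit table: one row per hit with 0-based half-open query and
#'   subject intervals (subject interval always in forward coordinates),
#'   strand of the subject relative to the query, length, matches,
#'   identity and score.
#' @export
find_local_matches <- function(query, subject, min_len = 50L,
                               min_identity = 70, word_size = 16L,
                               both_strands = TRUE) {
  qres <- if (inherits(query, "mito_seq")) query$residues else as.character(query)
  sres <- if (inherits(subject, "mito_seq")) subject$residues else as.character(subject)
  qid <- if (inherits(query, "mito_seq")) query$id else "query"
  sid <- if (inherits(subject, "mito_seq")) subject$id else "subject"
  if (word_size < 8L) stop("word_size must be >= 8")
  if (min_len < word_size)
    stop("min_len (", min_len, ") must be >= word_size (", word_size, ")")
  if (!nzchar(qres) || !nzchar(sres)) stop("empty sequence")
  df <- .match_seqs_cpp(qres, sres, as.integer(word_size),
                        as.integer(min_len), as.numeric(min_identity),
                        FALSE, isTRUE(both_strands))
  .as_hit_table(df, qid, sid)
}

#' Find dispersed repeats: a sequence matched against itself
#'
#' As \code{\link{find_local_matches}} with query == subject, minus the
#' trivial full-length self-diagonal; each repeat pair is reported once,
#' canonicalized so the query-side copy has the smaller start.
#'
#' @inheritParams find_local_matches
#' @param seq The sequence to scan.
#' @return Hit table of repeat pairs.
#' @export
self_matches <- function(seq, min_len = 50L, min_identity = 95,
                         word_size = 16L) {
  res <- if (inherits(seq, "mito_seq")) seq$residues else as.character(seq)
  id <- if (inherits(seq, "mito_seq")) seq$id else "seq"
  if (word_size < 8L) stop("word_size must be >= 8")
  if (min_len < word_size)
    stop("min_len (", min_len, ") must be >= word_size (", word_size, ")")
  if (!nzchar(res)) stop("empty sequence")
  df <- .match_seqs_cpp(res, res, as.integer(word_size),
                        as.integer(min_len), as.numeric(min_identity),
                        TRUE, TRUE)
  .as_hit_table(df, id, id)
}

#' Parse an external search tool's tabular output into a hit table
#'
#' Reads the 12-column tab-separated dialect (query id, subject id,
#' percent identity, alignment length, mismatches, gap opens, qstart,
#' qend, sstart, send, e-value, bit score) written by common local
#' aligners with \code{-outfmt 6}. One-based closed coordinates are
#' converted to 0-based half-open; descending subject coordinates mean a
#' minus-strand hit. When an e-value ceiling is supplied, hits above it
#' are dropped.
#'
#' @param path Tab-separated hit file.
#' @param max_evalue Optional e-value ceiling.
#' @return Hit table in package coordinates.
#' @export
external_search_adapter <- function(path, max_evalue = NULL) {
  if (!file.exists(path)) stop("hit file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(.empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols != 12L))
    stop("hit-file dialect error: expected 12 tab-separated columns, got ",
         paste(unique(ncols[ncols != 12L]), collapse = "/"),
         " on line(s) ", paste(which(ncols != 12L), collapse = ", "))
  m <- do.call(rbind, parts)
  qstart1 <- as.integer(m[, 7]); qend1 <- as.integer(m[, 8])
  sstart1 <- as.integer(m[, 9]); send1 <- as.integer(m[, 10])
  minus <- send1 < sstart1
  slo <- ifelse(minus, send1, sstart1)
  shi <- ifelse(minus, sstart1, send1)
  evalue <- suppressWarnings(as.numeric(m[, 11]))
  len <- as.integer(m[, 4])
  ident <- as.numeric(m[, 3])
  out <- data.frame(
    qid = m[, 1], sid = m[, 2],
    qstart = qstart1 - 1L, qend = qend1,
    sstart = slo - 1L, send = shi,
    strand = ifelse(minus, "-", "+"),
    length = len,
    matches = as.integer(round(len * ident / 100)),
    identity_pct = ident,
    score = as.numeric(m[, 12]),
    evalue = evalue,
    stringsAsFactors = FALSE)
  if (!is.null(max_evalue))
    out <- out[!is.na(out$evalue) & out$evalue <= max_evalue, , drop = FALSE]
  out <- out[order(-out$score, out$qstart, out$sstart), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a hit table in 12-column tabular dialect
#'
#' Inverse of \code{\link{external_search_adapter}}: package hits are
#' serialized with 1-based closed coordinates, minus-strand hits with
#' descending subject coordinates, and \code{"."} for unknown e-values.
#'
#' @param hits Hit table.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  if (nrow(hits) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  minus <- hits$strand == "-"
  s1 <- ifelse(minus, hits$send, hits$sstart + 1L)
  s2 <- ifelse(minus, hits$sstart + 1L, hits$send)
  mism <- hits$length - hits$matches
  ev <- ifelse(is.na(hits$evalue), ".", format(hits$evalue))
  lines <- paste(hits$qid, hits$sid, sprintf("%.2f", hits$identity_pct),
                 hits$length, mism, 0L, hits$qstart + 1L, hits$qend,
                 s1, s2, ev, hits$score, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# Positions (0-based) on the query covered by hits, as an intervals table.
hits_query_intervals <- function(hits, seq_id = NULL) {
  if (nrow(hits) == 0L) return(empty_intervals())
  intervals(if (is.null(seq_id)) hits$qid else seq_id,
            hits$qstart, hits$qend, hits$strand)
}
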