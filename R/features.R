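# Per-genome feature quantification: dispersed repeats, MTPT content,
# open reading frames and GC.

#' Quantify dispersed repeats in a genome
#'
#' The genome is searched against itself; pairs shorter than
#' \code{min_repeat_bp} or below \code{repeat_min_identity_pct} identity
#' are discarded. Only one side of each repeat pair is counted (the copy
#' with the smaller start coordinate), and overlapping bases are counted
#' once.
#'
#' @param genome A \code{mito_seq}.
#' @param thresholds See \code{\link{default_thresholds}}.
#' @return List: \code{pairs} (hit table), \code{counted_intervals},
#'   \code{total_bp}, \code{fraction_pct}, \code{length_histogram}
#'   (bins <100, 100-199, 200-499, 500-999, >=1000 bp).
#' @export
quantify_repeats <- function(genome, thresholds = default_thresholds()) {
  L <- seq_length(genome)
  if (L < thresholds$min_repeat_bp)
    stop("genome shorter than the minimum repeat length")
  pairs <- self_matches(genome,
                        min_len = thresholds$min_repeat_bp,
                        min_identity = thresholds$repeat_min_identity_pct,
                        word_size = thresholds$seed_word_size)
  counted <- hits_query_intervals(pairs, genome$id)
  total <- union_length(counted)
  bins <- cut(pairs$length, breaks = c(0, 99, 199, 499, 999, Inf),
              labels = c("<100", "100-199", "200-499", "500-999", ">=1000"))
  hist <- table(bins)
  list(genome_id = genome$id, pairs = pairs, counted_intervals = counted,
       total_bp = total, fraction_pct = 100 * total / L,
       length_histogram = hist)
}

#' Quantify mitochondrial plastid insertions (MTPT)
#'
#' The genome is compared against a collection of plastomes; hits
#' shorter than \code{mtpt_mask_bp} are masked and the remaining genome
#' intervals merged by position-set union. The identity floor is
#' permissive (\code{mtpt_min_identity_pct}, default 70) so diverged
#' insertions are admitted.
#'
#' @param genome A \code{mito_seq}.
#' @param plastomes List of plastome \code{mito_seq} objects.
#' @param thresholds See \code{\link{default_thresholds}}.
#' @return List: \code{hits}, \code{merged_intervals}, \code{total_bp},
#'   \code{fraction_pct}.
#' @export
quantify_mtpt <- function(genome, plastomes,
                          thresholds = default_thresholds()) {
  if (inherits(plastomes, "mito_seq")) plastomes <- list(plastomes)
  if (length(plastomes) == 0L)
    stop("quantify_mtpt: empty plastome collection")
  hits <- do.call(rbind, lapply(plastomes, function(p)
    find_local_matches(genome, p,
                       min_len = thresholds$mtpt_mask_bp,
                       min_identity = thresholds$mtpt_min_identity_pct,
                       word_size = thresholds$seed_word_size)))
  hits <- hits[hits$length >= thresholds$mtpt_mask_bp, , drop = FALSE]
  merged <- if (nrow(hits)) {
    iv <- hits_query_intervals(hits, genome$id)
    r <- IRanges::reduce(IRanges::IRanges(iv$start + 1L, iv$end))
    intervals(genome$id, IRanges::start(r) - 1L, IRanges::end(r))
  } else empty_intervals()
  total <- union_length(merged)
  list(genome_id = genome$id, hits = hits, merged_intervals = merged,
       total_bp = total, fraction_pct = 100 * total / seq_length(genome))
}

.codon_stops <- c("TAA", "TAG", "TGA")

# ORFs on the forward strand of a linear residue string. Returns rows
# with 0-based start of the ATG and end excluding the stop codon.
.orfs_forward <- function(res, min_aa) {
  n <- nchar(res)
  out <- list()
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 2L) next
    starts0 <- frame + 3L * (seq_len(ncod) - 1L)
    codons <- substring(res, starts0 + 1L, starts0 + 3L)
    is_stop <- codons %in% .codon_stops
    is_atg <- codons == "ATG"
    # segment the frame at stops; within each segment the ORF runs from
    # the first ATG to the stop
    seg <- cumsum(c(TRUE, is_stop[-length(is_stop)]))
    stop_idx <- which(is_stop)
    if (length(stop_idx) == 0L) next
    for (si in stop_idx) {
      seg_id <- seg[si]
      members <- which(seg == seg_id)
      members <- members[members < si]
      atgs <- members[is_atg[members]]
      if (length(atgs) == 0L) next
      first_atg <- atgs[1L]
      aa <- si - first_atg
      if (aa < min_aa) next
      out[[length(out) + 1L]] <- data.frame(
        start = starts0[first_atg], end = starts0[si],
        aa_length = aa, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      aa_length = integer()))
  do.call(rbind, out)
}

#' Find open reading frames
#'
#' Maximal ATG-to-stop frames with at least \code{min_aa} sense codons.
#' The reported interval and the codon count exclude the stop codon, and
#' records are named \code{ORF<aa_length>} (so a 244-codon frame is
#' ORF244 with a 732-bp interval). Circular sequences are scanned across
#' the origin by doubling; an origin-spanning frame is reported once,
#' with its start coordinate in \code{[0, length)} and an interval that
#' wraps virtually (start + 3*aa may exceed the sequence length).
#'
#' @param seq A \code{mito_seq}.
#' @param min_aa Minimum number of sense codons.
#' @param both_strands Scan the reverse strand too.
#' @return data.frame: \code{name}, \code{start}, \code{end} (0-based
#'   half-open on the forward strand of the given sequence), \code{strand},
#'   \code{aa_length}, \code{protein}.
#' @export
find_orfs <- function(seq, min_aa = 100L, both_strands = TRUE) {
  if (min_aa < 1L) stop("min_aa must be >= 1")
  L <- seq_length(seq)
  circular <- identical(seq$topology, "circular")
  scan_one <- function(res, strand) {
    scanned <- if (circular) paste0(res, res) else res
    df <- .orfs_forward(scanned, min_aa)
    if (circular && nrow(df)) {
      df <- df[df$start < L & df$aa_length * 3L <= L, , drop = FALSE]
      # an ORF found at start and again at start+L is the same ORF
      df <- df[!duplicated(df$start %% L), , drop = FALSE]
    }
    if (nrow(df) == 0L) return(NULL)
    prot <- vapply(seq_len(nrow(df)), function(i) {
      s <- substring(if (circular) paste0(res, res) else res,
                     df$start[i] + 1L, df$start[i] + 3L * df$aa_length[i])
      as.character(Biostrings::translate(Biostrings::DNAString(s)))
    }, "")
    if (strand == "+") {
      data.frame(start = df$start %% L,
                 end = df$end, aa_length = df$aa_length,
                 strand = "+", protein = prot, stringsAsFactors = FALSE)
    } else {
      # map coordinates on the reverse strand back to forward
      st <- (L - df$end) %% L
      data.frame(start = st, end = L - df$start,
                 aa_length = df$aa_length,
                 strand = "-", protein = prot, stringsAsFactors = FALSE)
    }
  }
  res <- list(scan_one(seq$residues, "+"))
  if (both_strands)
    res <- c(res, list(scan_one(.revcomp_cpp(seq$residues), "-")))
  df <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(df))
    return(data.frame(name = character(), start = integer(),
                      end = integer(), strand = character(),
                      aa_length = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  df$name <- paste0("ORF", df$aa_length)
  df <- df[order(-df$aa_length, df$start), c("name", "start", "end",
                                             "strand", "aa_length",
                                             "protein")]
  rownames(df) <- NULL
  df
}

#' GC content in percent
#'
#' (G+C) / (A+C+G+T) x 100; \code{N} bases are excluded from the
#' denominator.
#'
#' @param seq A \code{mito_seq} or residue string.
#' @return Percent GC.
#' @export
gc_content <- function(seq) {
  res <- if (inherits(seq, "mito_seq")) seq$residues else as.character(seq)
  if (!nzchar(res)) stop("gc_content: empty sequence")
  counts <- table(strsplit(res, "", fixed = TRUE)[[1]])
  acgt <- sum(counts[intersect(names(counts), c("A", "C", "G", "T"))])
  if (acgt == 0L) stop("gc_content: no determined (A/C/G/T) bases")
  gc <- sum(counts[intersect(names(counts), c("G", "C"))])
  100 * gc / acgt
}
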