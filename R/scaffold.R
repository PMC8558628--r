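# Assembly finishing: contig classification, coverage-based copy
# numbers, MTPT end pairing via plastome coordinates, junction-graph
# traversal into chromosomes, and verification.

.flip <- function(o) ifelse(o == "+", "-", "+")
.orient_seq <- function(res, o) if (identical(o, "-")) .revcomp_cpp(res) else res

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

#' Classify contigs against organellar references
#'
#' Contigs with a reference-mitogenome hit of at least
#' \code{min_ref_hit_bp} are labelled \code{mito}; contigs dominated by
#' plastome homology (>= 80 percent of their length) at clearly
#' super-mitochondrial depth are labelled \code{plastid}; the rest stay
#' \code{unassigned}. The single-copy mitochondrial depth
#' (\code{base_cov}) is estimated as the length-weighted median of mito
#' contig depths, refined over contigs in the single-copy band.
#'
#' @param contigs Named list of contig records, each with \code{seq}
#'   (a \code{mito_seq}) and \code{mean_cov}.
#' @param ref_mito Reference mitogenome \code{mito_seq}.
#' @param ref_plastome Reference plastome \code{mito_seq}.
#' @param thresholds See \code{\link{default_thresholds}}.
#' @param min_identity Identity floor for reference hits.
#' @param plastid_cov_ratio Depth ratio above which dominant plastome
#'   homology is called plastid.
#' @return List: \code{contigs} (with \code{class_label} and
#'   \code{mito_bp}/\code{plastid_bp} filled in), \code{base_cov}.
#' @export
classify_contigs <- function(contigs, ref_mito, ref_plastome,
                             thresholds = default_thresholds(),
                             min_identity = 80, plastid_cov_ratio = 3) {
  stopifnot(length(contigs) > 0L)
  min_hit <- thresholds$min_ref_hit_bp
  for (id in names(contigs)) {
    ctg <- contigs[[id]]
    len <- seq_length(ctg$seq)
    mito_bp <- plast_bp <- 0L
    if (len >= min_hit) {
      hm <- find_local_matches(ctg$seq, ref_mito, min_len = min_hit,
                               min_identity = min_identity,
                               word_size = thresholds$seed_word_size)
      if (nrow(hm)) mito_bp <- union_length(hits_query_intervals(hm, id))
      hp <- find_local_matches(ctg$seq, ref_plastome, min_len = min_hit,
                               min_identity = min_identity,
                               word_size = thresholds$seed_word_size)
      if (nrow(hp)) plast_bp <- union_length(hits_query_intervals(hp, id))
    }
    contigs[[id]]$mito_bp <- mito_bp
    contigs[[id]]$plastid_bp <- plast_bp
    contigs[[id]]$class_label <- "unassigned"
  }
  lens <- vapply(contigs, function(c) seq_length(c$seq), 0)
  covs <- vapply(contigs, `[[`, 0, "mean_cov")
  mito_bp <- vapply(contigs, `[[`, 0L, "mito_bp")
  plast_frac <- vapply(contigs, `[[`, 0L, "plastid_bp") / lens
  mito_cand <- mito_bp >= min_hit & plast_frac < 0.8
  if (!any(mito_bp >= min_hit))
    stop("empty classification: no contig has a >= ", min_hit,
         " bp hit to the reference mitogenome; check the reference ",
         "and contig inputs")
  prelim <- weighted_median(covs[mito_cand], lens[mito_cand])
  for (id in names(contigs)) {
    if (plast_frac[[id]] >= 0.8 && covs[[id]] >= plastid_cov_ratio * prelim) {
      contigs[[id]]$class_label <- "plastid"
    } else if (mito_bp[[id]] >= min_hit) {
      contigs[[id]]$class_label <- "mito"
    }
  }
  is_mito <- vapply(contigs, function(c) c$class_label == "mito", TRUE)
  base0 <- weighted_median(covs[is_mito], lens[is_mito])
  sc <- is_mito & covs / base0 >= 0.7 & covs / base0 <= 1.35
  base_cov <- if (any(sc)) weighted_median(covs[sc], lens[sc]) else base0
  list(contigs = contigs, base_cov = base_cov)
}

#' Promote unassigned contigs whose depth sits in the mitochondrial band
#'
#' Contigs with no reference homology but depth within
#' \code{[base_cov*(1-t), base_cov*(1+t)]} are promoted to \code{mito}
#' (they are "baited" by coverage). Promotions are recorded with their
#' coverage ratio.
#'
#' @param contigs Classified contig list.
#' @param base_cov Single-copy mitochondrial depth.
#' @param tolerance_frac Band half-width \code{t} (default 0.4).
#' @return List: \code{contigs}, \code{promotions} (data.frame).
#' @export
bait_by_coverage <- function(contigs, base_cov, tolerance_frac = 0.4) {
  if (base_cov <= 0) stop("base_cov must be positive")
  lo <- base_cov * (1 - tolerance_frac)
  hi <- base_cov * (1 + tolerance_frac)
  promoted <- list()
  for (id in names(contigs)) {
    ctg <- contigs[[id]]
    if (ctg$class_label == "unassigned" &&
        ctg$mean_cov >= lo && ctg$mean_cov <= hi) {
      contigs[[id]]$class_label <- "mito"
      contigs[[id]]$promoted_by_coverage <- TRUE
      promoted[[length(promoted) + 1L]] <- data.frame(
        contig = id, mean_cov = ctg$mean_cov,
        ratio = ctg$mean_cov / base_cov, stringsAsFactors = FALSE)
    }
  }
  list(contigs = contigs,
       promotions = if (length(promoted)) do.call(rbind, promoted) else
         data.frame(contig = character(), mean_cov = numeric(),
                    ratio = numeric(), stringsAsFactors = FALSE))
}

#' Estimate contig copy number from coverage
#'
#' \code{round(mean_cov / base_cov)} with a floor of 1 (half values
#' round away from zero). Ratios whose fractional part lies in
#' \code{[0.35, 0.65]} are ambiguous between neighbouring integers and
#' trigger a warning; the hard assignment still comes from rounding.
#'
#' @param mean_cov Vector of contig depths.
#' @param base_cov Single-copy depth.
#' @return Integer vector of copy numbers (attribute \code{ambiguous}).
#' @export
estimate_copy_number <- function(mean_cov, base_cov) {
  if (base_cov <= 0) stop("base_cov must be positive")
  r <- mean_cov / base_cov
  cn <- pmax(1L, as.integer(floor(r + 0.5)))
  frac <- r - floor(r)
  amb <- r >= 1.35 & frac >= 0.35 & frac <= 0.65
  if (any(amb))
    warning("ambiguous copy-number ratio(s): ",
            paste(sprintf("%.2f", r[amb]), collapse = ", "),
            " (within 0.15 of a half-integer)")
  structure(cn, ambiguous = amb)
}

#' Annotate contig ends that terminate in plastome-derived sequence
#'
#' Each end's terminal window is matched against the plastome; a hit
#' that reaches the contig tip marks the end as MTPT-interrupted and
#' records its plastome interval and orientation.
#'
#' @param contigs Named list of contig records (mito, single-copy).
#' @param plastome Plastome \code{mito_seq}.
#' @param thresholds See \code{\link{default_thresholds}}.
#' @param window Terminal window size (bp).
#' @param min_len Minimum stub match length (bp).
#' @param tip_tol Maximum distance of the hit from the contig tip (bp).
#' @return data.frame: \code{contig}, \code{side} (L/R), \code{sstart},
#'   \code{send}, \code{strand}.
#' @export
annotate_mtpt_ends <- function(contigs, plastome,
                               thresholds = default_thresholds(),
                               window = 250L, min_len = 50L,
                               tip_tol = 5L) {
  rows <- list()
  for (id in names(contigs)) {
    res <- contigs[[id]]$seq$residues
    len <- nchar(res)
    w <- min(window, len)
    for (side in c("L", "R")) {
      wseq <- if (side == "L") substr(res, 1L, w) else
        substr(res, len - w + 1L, len)
      hits <- find_local_matches(wseq, plastome, min_len = min_len,
                                 min_identity = 85, word_size = 12L)
      if (nrow(hits) == 0L) next
      ok <- if (side == "L") hits$qstart <= tip_tol else
        hits$qend >= w - tip_tol
      hits <- hits[ok, , drop = FALSE]
      if (nrow(hits) == 0L) next
      best <- hits[1L, ]  # already score-desc
      # project the interval to the exact contig tip, so a mismatch at
      # the very stub edge cannot shift the filler boundary
      ss <- best$sstart; se <- best$send
      P <- seq_length(plastome)
      if (side == "R") {
        d <- w - best$qend
        if (best$strand == "+") se <- min(se + d, P) else ss <- max(ss - d, 0L)
      } else {
        d <- best$qstart
        if (best$strand == "+") ss <- max(ss - d, 0L) else se <- min(se + d, P)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        contig = id, side = side, sstart = ss, send = se,
        strand = best$strand, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), side = character(),
               sstart = integer(), send = integer(), strand = character(),
               stringsAsFactors = FALSE)
}

# circular distance from a to b walking forward on a plastome of size P
.circ_gap <- function(from, to, P) (to - from) %% P

#' Pair MTPT-interrupted contig ends via plastome coordinates
#'
#' Outgoing ends (side R, contig sequence runs into the insertion) are
#' paired with incoming ends (side L) of the same orientation by the
#' smallest forward plastome-coordinate gap, greedily, with a
#' deterministic tie-break (gap, then contig ids). A paired junction's
#' filler is the spanned plastome segment. Pairings whose gap exceeds
#' \code{mtpt_max_fill_bp} are not made without read-pair evidence;
#' opposite-orientation ends are paired only when the supplied link
#' evidence names them.
#'
#' @param ends End annotation table from
#'   \code{\link{annotate_mtpt_ends}}.
#' @param plastome Plastome \code{mito_seq}.
#' @param links Optional read-pair evidence table with \code{kind ==
#'   "mtpt"} rows naming end pairs.
#' @param thresholds See \code{\link{default_thresholds}}.
#' @return List: \code{junctions} (data.frame with filler sequences),
#'   \code{unresolved} (ends left unpaired).
#' @export
pair_mtpt_ends <- function(ends, plastome, links = NULL,
                           thresholds = default_thresholds()) {
  P <- seq_length(plastome)
  res <- plastome$residues
  max_gap <- thresholds$mtpt_max_fill_bp
  take_seg <- function(a, b) {   # forward plastome segment [a, b), may wrap
    if (b >= a) substr(res, a + 1L, b) else
      paste0(substr(res, a + 1L, P), substr(res, 1L, b))
  }
  junctions <- list(); used <- rep(FALSE, nrow(ends))
  add_junction <- function(ia, ib, gap) {
    ea <- ends[ia, ]; eb <- ends[ib, ]
    if (ea$strand == "+") {
      from <- ea$send; to <- eb$sstart
      filler <- take_seg(from %% P, to %% P)
    } else {
      from <- eb$send; to <- ea$sstart
      filler <- .revcomp_cpp(take_seg(from %% P, to %% P))
    }
    junctions[[length(junctions) + 1L]] <<- data.frame(
      end_a_contig = ea$contig, end_a_side = ea$side,
      end_b_contig = eb$contig, end_b_side = eb$side,
      kind = "mtpt_fill", strand = ea$strand,
      plastome_from = from %% P, plastome_to = to %% P,
      gap = gap, filler = filler, stringsAsFactors = FALSE)
  }

  # link-evidence pairings take precedence (resolve rearranged MTPTs)
  if (!is.null(links) && nrow(links)) {
    ml <- links[links$kind == "mtpt", , drop = FALSE]
    for (k in seq_len(nrow(ml))) {
      ia <- which(ends$contig == ml$end_a_contig[k] &
                    ends$side == ml$end_a_side[k] & !used)
      ib <- which(ends$contig == ml$end_b_contig[k] &
                    ends$side == ml$end_b_side[k] & !used)
      if (length(ia) == 1L && length(ib) == 1L) {
        gap <- .circ_gap(ends$send[ia], ends$sstart[ib], P)
        add_junction(ia, ib, gap)
        used[c(ia, ib)] <- TRUE
      }
    }
  }

  out_idx <- which(ends$side == "R" & !used)
  in_idx <- which(ends$side == "L" & !used)
  cand <- list()
  for (ia in out_idx) for (ib in in_idx) {
    if (ends$strand[ia] != ends$strand[ib]) next
    gap <- if (ends$strand[ia] == "+")
      .circ_gap(ends$send[ia], ends$sstart[ib], P)
    else
      .circ_gap(ends$send[ib], ends$sstart[ia], P)
    if (gap > max_gap) next
    cand[[length(cand) + 1L]] <- data.frame(
      ia = ia, ib = ib, gap = gap, stringsAsFactors = FALSE)
  }
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$gap, ends$contig[cand$ia],
                       ends$contig[cand$ib]), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      ia <- cand$ia[k]; ib <- cand$ib[k]
      if (used[ia] || used[ib]) next
      add_junction(ia, ib, cand$gap[k])
      used[c(ia, ib)] <- TRUE
    }
  }
  list(junctions = if (length(junctions)) do.call(rbind, junctions) else
    .empty_junctions(),
    unresolved = ends[!used, , drop = FALSE])
}

.empty_junctions <- function() {
  data.frame(end_a_contig = character(), end_a_side = character(),
             end_b_contig = character(), end_b_side = character(),
             kind = character(), strand = character(),
             plastome_from = integer(), plastome_to = integer(),
             gap = integer(), filler = character(),
             through_contig = character(), through_orient = character(),
             stringsAsFactors = FALSE)
}

#' Correct a plastome-derived junction filler with re-mapping evidence
#'
#' MTPTs and their plastid counterparts need not be identical; filler
#' bases at which non-plastome evidence forms a majority are replaced.
#' Evidence rows give a plastome position (0-based, forward strand), the
#' alternative base and its support counts.
#'
#' @param filler Filler residue string (oriented as inserted).
#' @param plastome_from Forward-strand plastome start of the filler.
#' @param strand Orientation of the filler relative to the plastome.
#' @param evidence data.frame: \code{plastome_pos}, \code{base},
#'   \code{support_alt}, \code{support_ref}.
#' @param plastome_length Plastome length (for wrapped fillers).
#' @return List: \code{filler}, \code{n_changed}, \code{n_ambiguous},
#'   \code{corrected} (FALSE when no evidence was supplied).
#' @export
correct_mtpt_bases <- function(filler, plastome_from, strand = "+",
                               evidence = NULL, plastome_length = NULL) {
  n <- nchar(filler)
  if (is.null(evidence) || nrow(evidence) == 0L)
    return(list(filler = filler, n_changed = 0L, n_ambiguous = 0L,
                corrected = FALSE))
  P <- if (is.null(plastome_length)) plastome_from + n else plastome_length
  chars <- strsplit(filler, "", fixed = TRUE)[[1]]
  n_changed <- 0L; n_amb <- 0L
  for (k in seq_len(nrow(evidence))) {
    off <- .circ_gap(plastome_from, evidence$plastome_pos[k], P)
    if (off >= n) next
    idx <- if (strand == "+") off + 1L else n - off
    base <- if (strand == "+") evidence$base[k] else
      chartr("ACGT", "TGCA", evidence$base[k])
    if (evidence$support_alt[k] > evidence$support_ref[k]) {
      if (chars[idx] != base) { chars[idx] <- base; n_changed <- n_changed + 1L }
    } else if (evidence$support_alt[k] == evidence$support_ref[k]) {
      n_amb <- n_amb + 1L   # tie: plastome base kept
    }
  }
  list(filler = paste(chars, collapse = ""), n_changed = n_changed,
       n_ambiguous = n_amb, corrected = TRUE)
}

# repeat pass-through junctions from read-pair link evidence
.junctions_from_links <- function(links, contigs) {
  if (is.null(links) || nrow(links) == 0L) return(.empty_junctions())
  rl <- links[links$kind == "repeat", , drop = FALSE]
  rl <- rl[rl$through_contig %in% names(contigs), , drop = FALSE]
  if (nrow(rl) == 0L) return(.empty_junctions())
  data.frame(end_a_contig = rl$end_a_contig, end_a_side = rl$end_a_side,
             end_b_contig = rl$end_b_contig, end_b_side = rl$end_b_side,
             kind = "repeat_fill", strand = "+",
             plastome_from = NA_integer_, plastome_to = NA_integer_,
             gap = NA_integer_, filler = "",
             through_contig = rl$through_contig,
             through_orient = rl$through_orient,
             stringsAsFactors = FALSE)
}

#' Traverse the junction graph into chromosomes
#'
#' Walks the contig graph consuming each single-copy contig once and
#' each repeat contig once per pass-through junction. Closed walks emit
#' circular chromosomes; open walks emit linear chromosomes with their
#' dangling ends reported. Unresolvable structures are never
#' force-joined. Walk starts are deterministic (lexicographically
#' smallest unvisited contig).
#'
#' @param contigs Named list of single-copy and repeat contig records
#'   (mitochondrial only), each with \code{seq} and
#'   \code{copy_number}.
#' @param junctions Junction table (rows from
#'   \code{\link{pair_mtpt_ends}} and repeat links).
#' @return Assembly report: \code{chromosomes} (list of \code{mito_seq}
#'   with topology), \code{junction_positions},
#'   \code{unresolved_ends}, \code{walks}, \code{total_contig_bp},
#'   \code{total_filler_bp}, \code{leftover_repeat_copies}.
#' @export
traverse <- function(contigs, junctions) {
  cn <- vapply(contigs, function(c)
    if (is.null(c$copy_number)) 1L else as.integer(c$copy_number), 0L)
  names(cn) <- names(contigs)
  is_through <- names(contigs) %in% junctions$through_contig
  sc_ids <- sort(names(contigs)[!is_through])
  remaining <- cn
  jused <- rep(FALSE, nrow(junctions))
  find_junction <- function(ctg, side) {
    hit <- which(!jused &
                   ((junctions$end_a_contig == ctg &
                       junctions$end_a_side == side) |
                      (junctions$end_b_contig == ctg &
                         junctions$end_b_side == side)))
    if (length(hit)) hit[1L] else NA_integer_
  }

  visited <- setNames(rep(FALSE, length(sc_ids)), sc_ids)
  chromosomes <- list()
  junction_positions <- list()
  walks <- list()
  unresolved <- list()
  total_contig_bp <- 0; total_filler_bp <- 0
  structure_errors <- character()

  # walk in one direction from (ctg, orient); returns oriented elements
  walk_dir <- function(ctg, orient) {
    elems <- list()
    cur <- ctg; cur_o <- orient
    circular <- FALSE
    repeat {
      exit_side <- if (cur_o == "+") "R" else "L"
      ji <- find_junction(cur, exit_side)
      if (is.na(ji)) {
        unresolved[[length(unresolved) + 1L]] <<- data.frame(
          contig = cur, side = exit_side, stringsAsFactors = FALSE)
        break
      }
      jused[ji] <<- TRUE
      j <- junctions[ji, ]
      forward <- j$end_a_contig == cur & j$end_a_side == exit_side
      filler <- j$filler
      through <- if ("through_contig" %in% names(j)) j$through_contig else NA
      torient <- if ("through_orient" %in% names(j)) j$through_orient else NA
      if (!forward) {
        filler <- if (nzchar(filler)) .revcomp_cpp(filler) else filler
        torient <- .flip(torient)
      }
      if (!is.na(through) && nzchar(through) && through %in% names(contigs)) {
        remaining[through] <<- remaining[through] - 1L
        if (remaining[through] < 0L)
          structure_errors <<- c(structure_errors, paste0(
            "repeat contig ", through,
            " consumed more times than its copy number"))
        elems[[length(elems) + 1L]] <- list(type = "contig", id = through,
                                            orient = torient)
      } else if (nzchar(filler)) {
        elems[[length(elems) + 1L]] <- list(type = "filler", seq = filler,
                                            junction = ji)
      } else {
        elems[[length(elems) + 1L]] <- list(type = "filler", seq = "",
                                            junction = ji)
      }
      nxt <- if (forward) j$end_b_contig else j$end_a_contig
      nxt_side <- if (forward) j$end_b_side else j$end_a_side
      nxt_o <- if (nxt_side == "L") "+" else "-"
      if (nxt == ctg) { circular <- TRUE; break }
      elems[[length(elems) + 1L]] <- list(type = "contig", id = nxt,
                                          orient = nxt_o)
      visited[nxt] <<- TRUE
      cur <- nxt; cur_o <- nxt_o
    }
    list(elems = elems, circular = circular)
  }

  chr_i <- 0L
  for (start in sc_ids) {
    if (visited[[start]]) next
    visited[[start]] <- TRUE
    fwd <- walk_dir(start, "+")
    elems <- c(list(list(type = "contig", id = start, orient = "+")),
               fwd$elems)
    circular <- fwd$circular
    if (!circular) {
      bwd <- walk_dir(start, "-")
      if (length(bwd$elems)) {
        rev_elems <- rev(lapply(bwd$elems, function(e) {
          if (e$type == "contig") e$orient <- .flip(e$orient)
          else if (nzchar(e$seq)) e$seq <- .revcomp_cpp(e$seq)
          e
        }))
        elems <- c(rev_elems, elems)
      }
    }
    # assemble the sequence and record junction positions
    pieces <- character(length(elems))
    jpos <- list(); pos <- 0L
    for (k in seq_along(elems)) {
      e <- elems[[k]]
      if (e$type == "contig") {
        s <- .orient_seq(contigs[[e$id]]$seq$residues, e$orient)
        total_contig_bp <- total_contig_bp + nchar(s)
      } else {
        s <- e$seq
        total_filler_bp <- total_filler_bp + nchar(s)
        jpos[[length(jpos) + 1L]] <- data.frame(
          pos = pos, junction = e$junction, stringsAsFactors = FALSE)
      }
      pieces[k] <- s
      pos <- pos + nchar(s)
    }
    chr_i <- chr_i + 1L
    chr_id <- sprintf("chr%d", chr_i)
    chromosomes[[chr_id]] <- dna_seq(
      chr_id, paste(pieces, collapse = ""),
      if (circular) "circular" else "linear",
      "assembled chromosome")
    if (length(jpos)) {
      jp <- do.call(rbind, jpos)
      jp$chromosome <- chr_id
      if (circular) jp$pos[jp$pos == 0L] <- pos
      junction_positions[[chr_id]] <- jp
    }
    walks[[chr_id]] <- list(
      elements = elems, circular = circular,
      contigs = vapply(Filter(function(e) e$type == "contig", elems),
                       `[[`, "", "id"))
  }
  if (length(structure_errors))
    stop("structural inconsistency:\n  ",
         paste(unique(structure_errors), collapse = "\n  "))
  leftover <- remaining[is_through & remaining > 0L &
                          names(remaining) %in% names(contigs)]
  list(chromosomes = chromosomes,
       junction_positions = if (length(junction_positions))
         do.call(rbind, junction_positions) else
           data.frame(pos = integer(), junction = integer(),
                      chromosome = character(), stringsAsFactors = FALSE),
       unresolved_ends = if (length(unresolved)) do.call(rbind, unresolved)
       else data.frame(contig = character(), side = character(),
                       stringsAsFactors = FALSE),
       walks = walks,
       total_contig_bp = total_contig_bp,
       total_filler_bp = total_filler_bp,
       leftover_repeat_copies = leftover)
}

#' Verify assembled chromosomes against coverage and reference evidence
#'
#' Flags zero-coverage positions (from per-base coverage tracks) and
#' junction-spanning windows that no single reference alignment
#' supports. A chromosome passes when it collects no flags.
#'
#' @param report Result of \code{\link{traverse}}.
#' @param coverage Optional named list of per-base depth vectors, one
#'   per chromosome.
#' @param reference Optional \code{mito_seq} to check junction windows
#'   against (e.g. a trusted assembly or, in simulation, the truth).
#' @param window Half-width of the junction window (bp).
#' @return List: \code{flags} (data.frame chromosome/pos/type),
#'   \code{pass} (named logical per chromosome).
#' @export
verify_assembly <- function(report, coverage = NULL, reference = NULL,
                            window = 50L) {
  flags <- list()
  chroms <- report$chromosomes
  if (!is.null(coverage)) {
    for (id in names(chroms)) {
      cov <- coverage[[id]]
      if (is.null(cov)) next
      if (length(cov) != seq_length(chroms[[id]]))
        stop("coverage track length mismatch for ", id)
      zero <- which(cov == 0) - 1L
      for (p in zero)
        flags[[length(flags) + 1L]] <- data.frame(
          chromosome = id, pos = p, type = "zero_coverage",
          stringsAsFactors = FALSE)
    }
  }
  if (!is.null(reference) && nrow(report$junction_positions)) {
    ref_res <- if (identical(reference$topology, "circular"))
      paste0(reference$residues, reference$residues) else reference$residues
    for (id in unique(report$junction_positions$chromosome)) {
      chrom <- chroms[[id]]
      L <- seq_length(chrom)
      qres <- if (identical(chrom$topology, "circular"))
        paste0(chrom$residues, chrom$residues) else chrom$residues
      hits <- find_local_matches(qres, ref_res, min_len = 2L * window,
                                 min_identity = 95)
      jp <- report$junction_positions
      jp <- jp[jp$chromosome == id, , drop = FALSE]
      for (k in seq_len(nrow(jp))) {
        p <- jp$pos[k]
        spanned <- any(hits$qstart <= p - window & hits$qend >= p + window)
        if (!spanned && identical(chrom$topology, "circular") && p <= window)
          spanned <- any(hits$qstart <= p + L - window &
                           hits$qend >= p + L + window)
        if (!spanned)
          flags[[length(flags) + 1L]] <- data.frame(
            chromosome = id, pos = p, type = "junction_unsupported",
            stringsAsFactors = FALSE)
      }
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(chromosome = character(), pos = integer(),
               type = character(), stringsAsFactors = FALSE)
  pass <- setNames(!(names(chroms) %in% flags$chromosome), names(chroms))
  list(flags = flags, pass = pass)
}

#' Check gene completeness on an assembled contig set
#'
#' Locates each gene by homology on the mitochondrial contigs. A gene
#' covered >= 90 percent whose located copy has an intact reading frame
#' (starts ATG, a multiple of 3 long, no internal stop) is
#' \code{intact}; a located copy with a disrupted frame is
#' \code{pseudo}; genes absent from the mito set but present on other
#' contigs yield a rescue list.
#'
#' @param mito_contigs Named list of mitochondrial contig records.
#' @param gene_db Named list of gene \code{mito_seq}s.
#' @param other_contigs Optional list of remaining contigs to search for
#'   missing genes.
#' @param thresholds See \code{\link{default_thresholds}}.
#' @return List: \code{status} (named character:
#'   intact/pseudo/missing), \code{rescue} (data.frame gene/contig).
#' @export
check_gene_completeness <- function(mito_contigs, gene_db,
                                    other_contigs = NULL,
                                    thresholds = default_thresholds()) {
  if (length(gene_db) == 0L) stop("gene_db is empty")
  locate <- function(gene, contigs) {
    glen <- seq_length(gene)
    best <- NULL
    for (id in names(contigs)) {
      hits <- find_local_matches(gene, contigs[[id]]$seq,
                                 min_len = min(60L, glen),
                                 min_identity = 85, word_size = 12L)
      if (nrow(hits) == 0L) next
      cov <- union_length(hits_query_intervals(hits, gene$id)) / glen
      if (is.null(best) || cov > best$cov)
        best <- list(contig = id, cov = cov, hits = hits)
    }
    best
  }
  frame_intact <- function(hits, contig) {
    strand <- hits$strand[1L]
    a <- min(hits$sstart); b <- max(hits$send)
    region <- substr(contig$seq$residues, a + 1L, b)
    if (strand == "-") region <- .revcomp_cpp(region)
    n <- nchar(region)
    if (n %% 3L != 0L) return(FALSE)
    if (substr(region, 1L, 3L) != "ATG") return(FALSE)
    codons <- substring(region, seq(1L, n - 3L, by = 3L),
                        seq(3L, n - 3L, by = 3L))  # internal codons
    !any(codons[-1L] %in% .codon_stops)
  }
  status <- setNames(rep("missing", length(gene_db)), names(gene_db))
  rescue <- list()
  for (g in names(gene_db)) {
    best <- locate(gene_db[[g]], mito_contigs)
    if (!is.null(best) && best$cov >= 0.9) {
      status[g] <- if (frame_intact(best$hits, mito_contigs[[best$contig]]))
        "intact" else "pseudo"
    } else if (!is.null(best) && best$cov >= 0.5) {
      status[g] <- "pseudo"
    } else if (!is.null(other_contigs) && length(other_contigs)) {
      found <- locate(gene_db[[g]], other_contigs)
      if (!is.null(found) && found$cov >= 0.9)
        rescue[[length(rescue) + 1L]] <- data.frame(
          gene = g, contig = found$contig, stringsAsFactors = FALSE)
    }
  }
  list(status = status,
       rescue = if (length(rescue)) do.call(rbind, rescue) else
         data.frame(gene = character(), contig = character(),
                    stringsAsFactors = FALSE))
}

#' Finish an assembly from classified contigs
#'
#' End-to-end finishing: classify contigs against the references, bait
#' further mitochondrial contigs by coverage, estimate copy numbers,
#' annotate and pair MTPT-interrupted ends (correcting fillers with
#' re-mapping evidence), add repeat pass-throughs from read-pair links,
#' and traverse the junction graph into chromosomes. Promoted contigs
#' that join no junction and carry no reference homology are routed to
#' \code{orphans} (plasmid-like candidates), never into chromosomes.
#'
#' @param contigs Named contig list (see
#'   \code{\link{fragment_to_contigs}} for the record shape).
#' @param ref_mito,ref_plastome Reference sequences.
#' @param gene_db Optional gene set for the completeness check.
#' @param links Optional read-pair evidence table.
#' @param mtpt_evidence Optional per-base divergence evidence for filler
#'   correction.
#' @param thresholds See \code{\link{default_thresholds}}.
#' @param isomer_min_span Minimum inverted-repeat length counted as an
#'   isomer-generating pair (bp).
#' @return Assembly report (see \code{\link{traverse}}) extended with
#'   \code{base_cov}, \code{classification}, \code{promotions},
#'   \code{copy_numbers}, \code{gene_completeness}, \code{orphans},
#'   \code{isomers}, \code{junctions}.
#' @export
assemble <- function(contigs, ref_mito, ref_plastome, gene_db = NULL,
                     links = NULL, mtpt_evidence = NULL,
                     thresholds = default_thresholds(),
                     isomer_min_span = 300L) {
  cls <- classify_contigs(contigs, ref_mito, ref_plastome, thresholds)
  baited <- bait_by_coverage(cls$contigs, cls$base_cov,
                             thresholds$bait_tolerance_frac)
  contigs <- baited$contigs
  base_cov <- cls$base_cov

  mito <- Filter(function(c) c$class_label == "mito", contigs)
  covs <- vapply(mito, `[[`, 0, "mean_cov")
  cn <- suppressWarnings(estimate_copy_number(covs, base_cov))
  for (i in seq_along(mito)) mito[[i]]$copy_number <- cn[[i]]

  genes <- NULL
  if (!is.null(gene_db)) {
    other <- Filter(function(c) c$class_label != "mito", contigs)
    genes <- check_gene_completeness(mito, gene_db, other, thresholds)
    for (k in seq_len(nrow(genes$rescue))) {
      id <- genes$rescue$contig[k]
      if (!id %in% names(mito)) {
        contigs[[id]]$class_label <- "mito"
        mito[[id]] <- contigs[[id]]
        mito[[id]]$copy_number <- 1L
      }
    }
  }

  single_copy <- Filter(function(c) c$copy_number == 1L, mito)
  ends <- annotate_mtpt_ends(single_copy, ref_plastome, thresholds)
  paired <- pair_mtpt_ends(ends, ref_plastome, links, thresholds)
  mj <- paired$junctions
  if (nrow(mj) && !is.null(mtpt_evidence) && nrow(mtpt_evidence)) {
    for (k in seq_len(nrow(mj))) {
      corr <- correct_mtpt_bases(mj$filler[k], mj$plastome_from[k],
                                 mj$strand[k], mtpt_evidence,
                                 seq_length(ref_plastome))
      mj$filler[k] <- corr$filler
    }
  }
  if (nrow(mj)) { mj$through_contig <- ""; mj$through_orient <- "" }
  rj <- .junctions_from_links(links, mito)
  junctions <- rbind(mj, rj)

  # promoted orphans: no reference homology, participate in no junction
  jnames <- unique(c(junctions$end_a_contig, junctions$end_b_contig,
                     junctions$through_contig))
  orphans <- character()
  for (id in names(mito)) {
    if (isTRUE(mito[[id]]$promoted_by_coverage) &&
        mito[[id]]$mito_bp == 0L && !(id %in% jnames)) {
      orphans <- c(orphans, id)
      mito[[id]] <- NULL
    }
  }

  report <- traverse(mito, junctions)

  isomers <- 1L
  for (chrom in report$chromosomes) {
    inv <- self_matches(chrom, min_len = isomer_min_span,
                        min_identity = thresholds$repeat_min_identity_pct,
                        word_size = thresholds$seed_word_size)
    isomers <- isomers + sum(inv$strand == "-")
  }

  report$base_cov <- base_cov
  report$classification <- vapply(contigs, `[[`, "", "class_label")
  report$promotions <- baited$promotions
  report$copy_numbers <- cn
  report$gene_completeness <- genes
  report$orphans <- orphans
  report$isomers <- isomers
  report$junctions <- junctions
  report
}
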