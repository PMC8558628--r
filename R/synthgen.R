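# Truth-carrying simulator.
#
# Generates circular mitogenomes as a single-copy backbone with planted
# dispersed repeats, plastome-derived insertions (MTPTs), donor-derived
# HGT-like segments, toy gene cassettes and an optional nuclear-origin
# plasmid-like circle; fragments genomes into contigs with
# copy-number-proportional coverage the way short-read assemblies break
# at repeat and MTPT boundaries; and builds multi-genus genome sets with
# a shared mutated core plus genus-private segments. Every planted
# feature is recorded in a truth table so recovery can be scored
# exactly. All randomness flows from the spec seed.

.BASES <- c("A", "C", "G", "T")

# sample n integers uniformly from [a, b]; safe when a == b
.rint <- function(a, b, n = 1L) {
  if (a > b) stop("empty integer range")
  a + sample.int(b - a + 1L, n, replace = TRUE) - 1L
}

random_dna <- function(n, gc = 0.45) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Point-substitute `n_subs` random positions (always to a different base).
mutate_seq <- function(res, n_subs) {
  if (n_subs <= 0L) return(list(res = res, pos = integer(), base = character()))
  n <- nchar(res)
  n_subs <- min(n_subs, n)
  pos <- sort(sample.int(n, n_subs))
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  new <- vapply(pos, function(i) sample(setdiff(.BASES, chars[i]), 1L), "")
  chars[pos] <- new
  list(res = paste(chars, collapse = ""), pos = pos - 1L, base = new)
}

# Toy protein-coding cassette: ATG + (aa-1) random non-stop sense codons
# + stop. Total length 3*aa + 3.
make_toy_gene <- function(aa) {
  sense <- setdiff(apply(expand.grid(.BASES, .BASES, .BASES), 1L, paste,
                         collapse = ""), .codon_stops)
  body <- sample(sense, aa - 1L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(.codon_stops, 1L))
}

.CORE_GENES <- c("atp1", "atp4", "atp6", "atp8", "atp9",
                 "ccmB", "ccmC", "ccmFc", "ccmFn", "cob",
                 "cox1", "cox2", "cox3",
                 "nad1", "nad2", "nad3", "nad4", "nad5", "nad6", "nad7",
                 "nad9", "nad4L", "matR", "mttB")

#' Toy core mitochondrial gene set
#'
#' 24 placeholder protein-coding cassettes (150-600 bp, ATG-to-stop)
#' named after the core mitochondrial genes, used for gene-completeness
#' checks against simulated assemblies.
#'
#' @param seed Integer seed.
#' @return Named list of \code{mito_seq} genes.
#' @export
make_core_gene_db <- function(seed = 101L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lens_aa <- sample(50:199, length(.CORE_GENES), replace = TRUE)
  db <- lapply(seq_along(.CORE_GENES), function(i)
    dna_seq(.CORE_GENES[i], make_toy_gene(lens_aa[i]), "linear",
            "toy core gene"))
  names(db) <- .CORE_GENES
  db
}

#' Labelled donor reference pools
#'
#' A synthetic stand-in for a labelled nucleotide collection: random
#' entries labelled with a taxon, one of \code{n_orders} pseudo-orders
#' and a compartment (mitochondrial or plastid), used both as HGT donor
#' pools for the simulator and as the attribution reference collection.
#'
#' @param n_orders Number of pseudo-orders.
#' @param entries_per_order Entries per order and compartment.
#' @param entry_len Entry length in bp.
#' @param seed Integer seed.
#' @return Named list of \code{mito_seq}; each carries \code{taxon},
#'   \code{order}, \code{compartment} fields.
#' @export
make_donor_pools <- function(n_orders = 5L, entries_per_order = 2L,
                             entry_len = 4000L, seed = 202L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  orders <- paste0("Order", LETTERS[seq_len(n_orders)])
  pools <- list()
  for (o in orders) {
    for (comp in c("mitochondrial", "plastid")) {
      for (k in seq_len(entries_per_order)) {
        id <- sprintf("%s_%s_%02d", o, substr(comp, 1, 2), k)
        s <- dna_seq(id, random_dna(entry_len, 0.44), "linear",
                     sprintf("[taxon=%s_taxon%d] [order=%s] [compartment=%s]",
                             o, k, o, comp))
        s$taxon <- sprintf("%s_taxon%d", o, k)
        s$order <- o
        s$compartment <- comp
        pools[[id]] <- s
      }
    }
  }
  pools
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Specification of a simulated mitogenome
#'
#' Defaults describe the study conditions the simulator emulates: a
#' circular genome in the plant-mitogenome size range at GC 45 percent,
#' a handful of dispersed repeats of 0.5-3 kb, one to three
#' plastome-derived insertions of 0.3-5 kb with slight divergence from
#' their plastome source, toy core genes on the backbone, and at least
#' 200 bp of single-copy backbone between planted features so contig
#' fragmentation is well defined.
#'
#' @param length Genome length in bp.
#' @param gc GC fraction of backbone sequence.
#' @param n_repeats Number of dispersed repeat pairs.
#' @param repeat_len_range Repeat unit length range (bp).
#' @param repeat_identity_pct Identity between the two copies of a
#'   repeat (100 = identical; assembly fixtures use 100, mirroring the
#'   collapse of near-identical repeats by short-read assembly).
#' @param repeat_inverted Logical; plant the second copy of each repeat
#'   reverse-complemented.
#' @param n_mtpt Number of MTPT insertions.
#' @param mtpt_len_range MTPT length range (bp).
#' @param mtpt_divergence Substitution rate of the insertion relative to
#'   its plastome source.
#' @param plastome_length,plastome_gc Synthetic plastome size and GC.
#' @param hgt_specs List of HGT plantings; each element is a list with
#'   \code{order}, \code{compartment}, \code{len} (see
#'   \code{\link{make_donor_pools}}).
#' @param genes Plant the toy core gene set on the backbone.
#' @param plasmid \code{NULL}, or a list with \code{length}, \code{gc}
#'   and \code{orf_aa} (vector of ORF codon counts) describing a
#'   nuclear-origin plasmid-like circle.
#' @param min_gap Minimum backbone gap between planted features (bp).
#' @param seed Integer seed fixing all randomness.
#' @return A spec list for \code{\link{generate_mitogenome}}.
#' @export
genome_spec <- function(length = 100000L, gc = 0.45,
                        n_repeats = 3L, repeat_len_range = c(500L, 3000L),
                        repeat_identity_pct = 100,
                        repeat_inverted = FALSE,
                        n_mtpt = 2L, mtpt_len_range = c(300L, 5000L),
                        mtpt_divergence = 0.005,
                        plastome_length = 30000L, plastome_gc = 0.37,
                        hgt_specs = list(), genes = TRUE, plasmid = NULL,
                        min_gap = 200L, seed = 1L) {
  spec <- list(length = as.integer(length), gc = gc,
               n_repeats = as.integer(n_repeats),
               repeat_len_range = as.integer(repeat_len_range),
               repeat_identity_pct = repeat_identity_pct,
               repeat_inverted = isTRUE(repeat_inverted),
               n_mtpt = as.integer(n_mtpt),
               mtpt_len_range = as.integer(mtpt_len_range),
               mtpt_divergence = mtpt_divergence,
               plastome_length = as.integer(plastome_length),
               plastome_gc = plastome_gc,
               hgt_specs = hgt_specs, genes = isTRUE(genes),
               plasmid = plasmid, min_gap = as.integer(min_gap),
               seed = as.integer(seed))
  spec
}

.truth_row <- function(start, end, kind, id, strand = "+",
                       repeat_unit = NA, copy_index = NA,
                       plastome_start = NA, plastome_end = NA,
                       donor_id = NA, order = NA, compartment = NA,
                       gene = NA) {
  data.frame(start = start, end = end, kind = kind, id = id,
             strand = strand, repeat_unit = repeat_unit,
             copy_index = copy_index, plastome_start = plastome_start,
             plastome_end = plastome_end, donor_id = donor_id,
             order = order, compartment = compartment, gene = gene,
             stringsAsFactors = FALSE)
}

#' Generate a simulated circular mitogenome with ground truth
#'
#' Assembles a genome as backbone + planted features according to the
#' spec: repeats as dispersed copies at controlled identity, MTPTs
#' copied from a synthetic plastome with recorded divergences, HGT
#' segments copied verbatim from labelled donor pools, and toy genes.
#' Deterministic under the spec seed.
#'
#' @param spec A \code{\link{genome_spec}}.
#' @param donor_pools Labelled donor collection (required when
#'   \code{spec$hgt_specs} is non-empty); see
#'   \code{\link{make_donor_pools}}.
#' @param gene_db Toy gene set; defaults to
#'   \code{\link{make_core_gene_db}} when \code{spec$genes}.
#' @param id Genome id.
#' @return List: \code{genome} (circular \code{mito_seq}), \code{truth}
#'   (feature table + divergence table + expected totals),
#'   \code{plastome}, \code{gene_db}, \code{plasmid} (or NULL),
#'   \code{spec}.
#' @export
generate_mitogenome <- function(spec, donor_pools = NULL, gene_db = NULL,
                                id = "mito1") {
  set.seed(spec$seed)
  L <- spec$length

  plastome <- dna_seq("plastome", random_dna(spec$plastome_length,
                                             spec$plastome_gc),
                      "circular", "synthetic plastome")

  if (spec$genes && is.null(gene_db)) gene_db <- make_core_gene_db()

  # ---- build the feature blocks -------------------------------------
  feats <- list()   # each: list(kind, id, seq, strand, extra truth cols)
  # dispersed repeats: two copies per unit
  if (spec$n_repeats > 0L) {
    for (i in seq_len(spec$n_repeats)) {
      rl <- .rint(spec$repeat_len_range[1], spec$repeat_len_range[2])
      unit <- random_dna(rl, spec$gc)
      n_subs <- round(rl * (100 - spec$repeat_identity_pct) / 100)
      copy2 <- mutate_seq(unit, n_subs)$res
      strand2 <- "+"
      if (spec$repeat_inverted) { copy2 <- .revcomp_cpp(copy2); strand2 <- "-" }
      rid <- sprintf("rep%02d", i)
      feats[[length(feats) + 1L]] <-
        list(kind = "repeat_copy", id = paste0(rid, "_c1"), seq = unit,
             strand = "+", repeat_unit = rid, copy_index = 1L)
      feats[[length(feats) + 1L]] <-
        list(kind = "repeat_copy", id = paste0(rid, "_c2"), seq = copy2,
             strand = strand2, repeat_unit = rid, copy_index = 2L)
    }
  }
  # MTPTs from disjoint plastome source intervals
  mtpt_divs <- list()
  if (spec$n_mtpt > 0L) {
    P <- spec$plastome_length
    lens <- .rint(spec$mtpt_len_range[1], spec$mtpt_len_range[2],
                   spec$n_mtpt)
    if (sum(lens) + 500L * spec$n_mtpt > P)
      stop("over-packed spec: MTPT lengths exceed the plastome")
    # lay sources left to right with >= 500 bp separation
    slack <- P - sum(lens) - 500L * spec$n_mtpt
    offs <- sort(sample.int(max(slack, 1L), spec$n_mtpt))
    pos <- 0L
    for (i in seq_len(spec$n_mtpt)) {
      ps <- pos + 500L + offs[i] - if (i > 1L) offs[i - 1L] else 0L
      ps <- min(ps, P - lens[i])
      pe <- ps + lens[i]
      src <- substr(plastome$residues, ps + 1L, pe)
      n_subs <- round(lens[i] * spec$mtpt_divergence)
      mut <- mutate_seq(src, n_subs)
      mid <- sprintf("mtpt%02d", i)
      feats[[length(feats) + 1L]] <-
        list(kind = "mtpt", id = mid, seq = mut$res, strand = "+",
             plastome_start = ps, plastome_end = pe)
      if (length(mut$pos))
        mtpt_divs[[mid]] <- data.frame(
          mtpt_id = mid, plastome_pos = ps + mut$pos, base = mut$base,
          stringsAsFactors = FALSE)
      pos <- pe
    }
  }
  # HGT segments copied verbatim from donors
  if (length(spec$hgt_specs)) {
    if (is.null(donor_pools))
      stop("hgt_specs given but no donor_pools supplied")
    for (i in seq_along(spec$hgt_specs)) {
      hs <- spec$hgt_specs[[i]]
      cand <- Filter(function(d)
        (is.null(hs$order) || d$order == hs$order) &&
        (is.null(hs$compartment) || d$compartment == hs$compartment),
        donor_pools)
      if (length(cand) == 0L) stop("no donor matches hgt spec ", i)
      donor <- cand[[sample.int(length(cand), 1L)]]
      len <- min(hs$len, seq_length(donor))
      off <- sample.int(seq_length(donor) - len + 1L, 1L) - 1L
      feats[[length(feats) + 1L]] <-
        list(kind = "hgt", id = sprintf("hgt%02d", i),
             seq = substr(donor$residues, off + 1L, off + len),
             strand = "+", donor_id = donor$id, order = donor$order,
             compartment = donor$compartment)
    }
  }
  # toy genes
  if (spec$genes) {
    for (g in gene_db) {
      feats[[length(feats) + 1L]] <-
        list(kind = "gene", id = paste0("gene_", g$id), seq = g$residues,
             strand = "+", gene = g$id)
    }
  }

  feat_len <- sum(vapply(feats, function(f) nchar(f$seq), 0))
  n_gaps <- length(feats) + 1L
  backbone_total <- L - feat_len
  if (backbone_total < n_gaps * spec$min_gap)
    stop("over-packed spec: planted features leave under ",
         n_gaps * spec$min_gap, " bp of backbone")
  feats <- feats[sample.int(length(feats))]
  w <- runif(n_gaps)
  extra <- floor(w / sum(w) * (backbone_total - n_gaps * spec$min_gap))
  gaps <- spec$min_gap + extra
  gaps[n_gaps] <- backbone_total - sum(gaps[-n_gaps])

  pieces <- character(2L * length(feats) + 1L)
  truth <- list()
  pos <- 0L
  for (i in seq_along(feats)) {
    bb <- random_dna(gaps[i], spec$gc)
    pieces[2L * i - 1L] <- bb
    pos <- pos + gaps[i]
    f <- feats[[i]]
    flen <- nchar(f$seq)
    pieces[2L * i] <- f$seq
    truth[[length(truth) + 1L]] <- .truth_row(
      start = pos, end = pos + flen, kind = f$kind, id = f$id,
      strand = f$strand,
      repeat_unit = if (is.null(f$repeat_unit)) NA else f$repeat_unit,
      copy_index = if (is.null(f$copy_index)) NA else f$copy_index,
      plastome_start = if (is.null(f$plastome_start)) NA else f$plastome_start,
      plastome_end = if (is.null(f$plastome_end)) NA else f$plastome_end,
      donor_id = if (is.null(f$donor_id)) NA else f$donor_id,
      order = if (is.null(f$order)) NA else f$order,
      compartment = if (is.null(f$compartment)) NA else f$compartment,
      gene = if (is.null(f$gene)) NA else f$gene)
    pos <- pos + flen
  }
  pieces[2L * length(feats) + 1L] <- random_dna(gaps[n_gaps], spec$gc)
  genome <- dna_seq(id, paste(pieces, collapse = ""), "circular",
                    "simulated mitogenome")
  stopifnot(seq_length(genome) == L)

  features <- if (length(truth)) do.call(rbind, truth) else
    .truth_row(0L, 1L, "backbone", "none")[0, ]

  # hard flanks: force a short run of backbone bases just outside each
  # planted repeat copy / MTPT to mismatch its homolog's flank, so the
  # X-drop extension stops exactly at the planted boundary (a single
  # mismatch can occasionally be climbed over by chance matches) and
  # truth totals are exact
  flank_w <- 8L
  gchars <- strsplit(genome$residues, "", fixed = TRUE)[[1]]
  pchars <- strsplit(plastome$residues, "", fixed = TRUE)[[1]]
  force_diff <- function(idx, avoid) {
    if (idx >= 1L && idx <= length(gchars) && gchars[idx] %in% avoid)
      gchars[idx] <<- sample(setdiff(.BASES, avoid), 1L)
  }
  rep_rows <- features[features$kind == "repeat_copy", , drop = FALSE]
  for (u in unique(rep_rows$repeat_unit)) {
    cp <- rep_rows[rep_rows$repeat_unit == u, ]
    c1 <- cp[cp$copy_index == 1L, ]; c2 <- cp[cp$copy_index == 2L, ]
    if (c2$strand == "+") {
      for (j in seq_len(flank_w) - 1L) {
        force_diff(c2$start - j, gchars[c1$start - j])  # before copy2
        force_diff(c2$end + 1L + j, gchars[c1$end + 1L + j])  # after
      }
    }
  }
  mt_rows <- features[features$kind == "mtpt", , drop = FALSE]
  for (k in seq_len(nrow(mt_rows))) {
    m <- mt_rows[k, ]
    for (j in seq_len(flank_w) - 1L) {
      if (m$plastome_start - j >= 1L)
        force_diff(m$start - j, pchars[m$plastome_start - j])
      if (m$plastome_end + 1L + j <= spec$plastome_length)
        force_diff(m$end + 1L + j, pchars[m$plastome_end + 1L + j])
    }
  }
  genome$residues <- paste(gchars, collapse = "")
  divs <- if (length(mtpt_divs)) do.call(rbind, mtpt_divs) else
    data.frame(mtpt_id = character(), plastome_pos = integer(),
               base = character(), stringsAsFactors = FALSE)

  rep1 <- features[features$kind == "repeat_copy" & features$copy_index == 1L, ]
  expected_repeat_bp <- if (nrow(rep1))
    union_length(intervals(id, rep1$start, rep1$end)) else 0L
  mt <- features[features$kind == "mtpt", ]
  expected_mtpt_bp <- if (nrow(mt))
    union_length(intervals(id, mt$start, mt$end)) else 0L

  plasmid <- NULL
  if (!is.null(spec$plasmid)) {
    pl <- spec$plasmid
    pl_gc <- if (is.null(pl$gc)) 0.375 else pl$gc
    # a leading in-frame stop pins each ORF to its planted ATG
    orf_seqs <- vapply(pl$orf_aa, function(a)
      paste0(sample(.codon_stops, 1L), make_toy_gene(a)), "")
    orf_len <- nchar(orf_seqs)
    rest <- pl$length - sum(orf_len)
    if (rest < 100L) stop("plasmid spec too small for its ORFs")
    k <- length(orf_seqs) + 1L
    gp <- rep(rest %/% k, k); gp[k] <- rest - sum(gp[-k])
    parts <- character(0)
    for (i in seq_along(orf_seqs))
      parts <- c(parts, random_dna(gp[i], pl_gc), orf_seqs[i])
    parts <- c(parts, random_dna(gp[k], pl_gc))
    plasmid <- dna_seq(paste0(id, "_plasmid"),
                       paste(parts, collapse = ""), "circular",
                       "simulated nuclear-origin plasmid-like circle")
  }

  list(genome = genome,
       truth = list(features = features, mtpt_divergences = divs,
                    expected_repeat_bp = expected_repeat_bp,
                    expected_mtpt_bp = expected_mtpt_bp),
       plastome = plastome, gene_db = gene_db, plasmid = plasmid,
       spec = spec)
}

#' Fragment a simulated genome into contigs with coverage
#'
#' Reproduces the breakage model of short-read mitogenome assembly: the
#' genome is cut at every repeat-copy boundary and at MTPT boundaries.
#' Each distinct repeat unit is emitted once, with coverage proportional
#' to its copy number; MTPT interiors are not emitted as mitochondrial
#' contigs (their sequence lives in the plastome), leaving flanking
#' contigs that terminate in short MTPT stubs whose ends map to plastome
#' coordinates. Single-copy contigs get multiplicative lognormal
#' coverage noise. Synthetic read-pair links spanning each true repeat
#' pass are emitted as evidence, as is the per-base divergence evidence
#' needed to correct MTPT fillers.
#'
#' @param sim Result of \code{\link{generate_mitogenome}}.
#' @param base_cov Single-copy mitochondrial depth.
#' @param cov_noise_cv Coefficient of variation of coverage noise.
#' @param stub MTPT stub length retained on flanking contigs (bp).
#' @param plastid_cov_factor Plastid depth relative to \code{base_cov}.
#' @param n_nuclear Number of low-depth nuclear background contigs.
#' @param seed Seed for the noise (defaults to the spec seed + 1).
#' @return List: \code{contigs} (list of contig records: \code{seq},
#'   \code{mean_cov}, \code{is_circular}, \code{truth_label},
#'   \code{truth_copy_number}), \code{links} (read-pair evidence table),
#'   \code{mtpt_evidence} (per-base divergence evidence),
#'   \code{base_cov}, \code{truth_junctions}.
#' @export
fragment_to_contigs <- function(sim, base_cov = 50, cov_noise_cv = 0.05,
                                stub = 150L, plastid_cov_factor = 10,
                                n_nuclear = 2L, seed = NULL) {
  if (base_cov <= 0) stop("base_cov must be positive")
  set.seed(if (is.null(seed)) sim$spec$seed + 1L else seed)
  genome <- sim$genome
  L <- seq_length(genome)
  feats <- sim$truth$features
  cutf <- feats[feats$kind %in% c("repeat_copy", "mtpt"), , drop = FALSE]
  cutf <- cutf[order(cutf$start), , drop = FALSE]
  if (nrow(cutf) >= 2L) {
    gap <- c(cutf$start[-1L], cutf$start[1L] + L) -
      c(cutf$end[-nrow(cutf)], cutf$end[nrow(cutf)])
    if (any(gap < 2L * 16L))
      stop("spec error: planted features closer than twice the seed word ",
           "size cannot be resolved by construction")
  }

  sdlog <- sqrt(log(1 + cov_noise_cv^2))
  noise <- function() rlnorm(1L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  sub_seq <- function(s, a, b) substr(s, a + 1L, b)  # 0-based half-open

  contigs <- list()
  elements <- list()  # ordered walk around the circle
  add_contig <- function(id, res, cov, label, cn = 1L, circ = FALSE) {
    contigs[[id]] <<- list(
      seq = dna_seq(id, res, if (circ) "circular" else "linear"),
      mean_cov = cov, is_circular = circ, truth_label = label,
      truth_copy_number = cn)
  }

  if (nrow(cutf) == 0L) {
    add_contig("ctg001", genome$residues, base_cov * noise(), "mito")
    return(list(contigs = contigs,
                links = .empty_links(), mtpt_evidence = .empty_evidence(),
                base_cov = base_cov, truth_junctions = 0L))
  }

  # single-copy segments between cut features, walking the circle;
  # segment i runs from boundary after feature i to start of feature i+1
  nseg <- nrow(cutf)
  seg_from <- integer(nseg); seg_to <- integer(nseg)
  for (i in seq_len(nseg)) {
    f <- cutf[i, ]
    nf <- cutf[(i %% nseg) + 1L, ]
    from <- if (f$kind == "mtpt") {
      m <- f$end - f$start
      f$end - min(stub, m %/% 2L)          # right flank keeps a stub
    } else f$end
    to <- if (nf$kind == "mtpt") {
      m <- nf$end - nf$start
      nf$start + min(stub, m %/% 2L)       # left flank keeps a stub
    } else nf$start
    seg_from[i] <- from; seg_to[i] <- to
  }
  sc_id <- sprintf("ctg%03d", seq_len(nseg))
  for (i in seq_len(nseg)) {
    a <- seg_from[i]; b <- seg_to[i]
    res <- if (b > a) sub_seq(genome$residues, a, b) else
      paste0(sub_seq(genome$residues, a, L), sub_seq(genome$residues, 0L, b))
    add_contig(sc_id[i], res, base_cov * noise(), "mito")
  }

  # one contig per distinct repeat unit, at copy-number coverage
  units <- unique(cutf$repeat_unit[cutf$kind == "repeat_copy"])
  for (u in units[!is.na(units)]) {
    copies <- cutf[cutf$kind == "repeat_copy" & !is.na(cutf$repeat_unit) &
                     cutf$repeat_unit == u, , drop = FALSE]
    c1 <- copies[copies$copy_index == 1L, ]
    res <- sub_seq(genome$residues, c1$start, c1$end)
    cn <- nrow(copies)
    add_contig(paste0("rep_", u), res, cn * base_cov * noise(),
               "repeat", cn = cn)
  }

  # read-pair evidence: one link per true pass through a repeat unit;
  # MTPT adjacencies are left for plastome-coordinate pairing
  links <- list()
  truth_junctions <- 0L
  for (i in seq_len(nseg)) {
    f <- cutf[i, ]            # feature between segment i-1 and segment i
    prev <- sc_id[if (i == 1L) nseg else i - 1L]
    nxt <- sc_id[i]
    if (f$kind == "repeat_copy") {
      links[[length(links) + 1L]] <- data.frame(
        end_a_contig = prev, end_a_side = "R",
        end_b_contig = nxt, end_b_side = "L",
        through_contig = paste0("rep_", f$repeat_unit),
        through_orient = f$strand, kind = "repeat",
        stringsAsFactors = FALSE)
      truth_junctions <- truth_junctions + 2L
    } else {
      truth_junctions <- truth_junctions + 1L
    }
  }
  links <- if (length(links)) do.call(rbind, links) else .empty_links()

  # per-base divergence evidence for MTPT interiors (the analogue of the
  # re-mapped reads that disagree with the plastome)
  ev <- sim$truth$mtpt_divergences
  mtpt_evidence <- if (nrow(ev)) {
    data.frame(plastome_pos = ev$plastome_pos, base = ev$base,
               support_alt = 5L, support_ref = 0L,
               stringsAsFactors = FALSE)
  } else .empty_evidence()

  # background: plastid at high depth, nuclear at low depth
  if (plastid_cov_factor > 0)
    add_contig("plastid_ctg", sim$plastome$residues,
               plastid_cov_factor * base_cov * noise(), "plastid")
  if (n_nuclear > 0L) {
    for (i in seq_len(n_nuclear))
      add_contig(sprintf("nuc%02d", i), random_dna(.rint(3000L, 8000L), 0.36),
                 0.05 * base_cov * noise(), "nuclear")
  }
  if (!is.null(sim$plasmid))
    add_contig(sim$plasmid$id, sim$plasmid$residues, base_cov * noise(),
               "plasmid", circ = TRUE)

  list(contigs = contigs, links = links, mtpt_evidence = mtpt_evidence,
       base_cov = base_cov, truth_junctions = truth_junctions)
}

.empty_links <- function() {
  data.frame(end_a_contig = character(), end_a_side = character(),
             end_b_contig = character(), end_b_side = character(),
             through_contig = character(), through_orient = character(),
             kind = character(), stringsAsFactors = FALSE)
}
.empty_evidence <- function() {
  data.frame(plastome_pos = integer(), base = character(),
             support_alt = integer(), support_ref = integer(),
             stringsAsFactors = FALSE)
}

#' Generate a multi-genus genome set with ground truth
#'
#' Genomes share a mutated common core (cross-genus homologous,
#' genus-level divergence ~3 percent, within-genus ~0.5 percent)
#' interleaved with genus-private random segments and donor-derived
#' HGT-like segments (each donor entry used in at most one genus).
#' Optionally one genome is "expansion-by-shared-sequence": enlarged by
#' an extra, slightly diverged copy of core sequence rather than by
#' private sequence, so it shows the highest cross-genus shared fraction
#' but not the largest genus-specific total.
#'
#' @param n_genera Number of genera (>= 2).
#' @param genomes_per_genus Genomes per genus.
#' @param genome_length Base genome length (bp).
#' @param private_fraction Fraction of each genome that is genus-private
#'   random sequence.
#' @param hgt_per_genome Donor-derived segments planted per genome.
#' @param hgt_len_range Donor segment length range (bp).
#' @param donor_pools Labelled donors (\code{\link{make_donor_pools}}).
#' @param carpinus_like Add the enlarged-by-shared-sequence genome.
#' @param seed Integer seed.
#' @return List: \code{set} (genomes + taxon table), \code{truth}
#'   (per-genome feature tables; planted private/HGT intervals),
#'   \code{donor_pools}.
#' @export
generate_genus_set <- function(n_genera = 3L, genomes_per_genus = 2L,
                               genome_length = 40000L,
                               private_fraction = 0.2,
                               hgt_per_genome = 1L,
                               hgt_len_range = c(500L, 2000L),
                               donor_pools = NULL,
                               carpinus_like = FALSE, seed = 1L) {
  if (n_genera < 2L) stop("need at least 2 genera for specificity")
  if (private_fraction < 0 || private_fraction >= 1)
    stop("private_fraction must be in [0, 1)")
  set.seed(seed)
  if (is.null(donor_pools)) donor_pools <- make_donor_pools(seed = seed + 7L)
  L <- genome_length
  core_len <- round(L * (1 - private_fraction)) -
    hgt_per_genome * round(mean(hgt_len_range))
  if (core_len < 2000L) stop("genome_length too small for the fractions")
  ancestral <- random_dna(core_len, 0.45)
  genera <- paste0("Genus", LETTERS[seq_len(n_genera)])

  # donors are assigned to genera without reuse across genera
  donor_ids <- names(donor_pools)
  donor_ids <- donor_ids[sample.int(length(donor_ids))]
  need <- n_genera * genomes_per_genus * hgt_per_genome
  if (need > length(donor_ids))
    stop("not enough donor entries for the requested HGT plantings")

  genomes <- list(); taxon <- list(); truth <- list()
  di <- 0L
  for (gi in seq_len(n_genera)) {
    genus_core <- mutate_seq(ancestral, round(core_len * 0.03))$res
    for (si in seq_len(genomes_per_genus)) {
      gid <- sprintf("%s_sp%d", genera[gi], si)
      is_carp <- carpinus_like && gi == 1L && si == 1L
      core <- mutate_seq(genus_core, round(core_len * 0.005))$res
      pf <- if (is_carp) private_fraction / 2 else private_fraction
      private_total <- round(L * pf)
      priv_lens <- integer(0)
      while (sum(priv_lens) < private_total) {
        rem <- private_total - sum(priv_lens)
        if (rem < 400L) break
        priv_lens <- c(priv_lens, min(.rint(400L, 3000L), rem))
      }
      hgt_seqs <- list()
      for (h in seq_len(hgt_per_genome)) {
        di <- di + 1L
        donor <- donor_pools[[donor_ids[di]]]
        len <- min(.rint(hgt_len_range[1], hgt_len_range[2]),
                   seq_length(donor))
        off <- sample.int(seq_length(donor) - len + 1L, 1L) - 1L
        hgt_seqs[[h]] <- list(seq = substr(donor$residues, off + 1L, off + len),
                              donor_id = donor$id, order = donor$order,
                              compartment = donor$compartment)
      }
      inserts <- c(
        lapply(priv_lens, function(n)
          list(kind = "private", seq = random_dna(n, 0.45))),
        lapply(hgt_seqs, function(h)
          c(list(kind = "hgt"), h)))
      if (is_carp) {
        # extra shared sequence: a second, slightly diverged copy of a
        # large core slice (homologous to every other genome)
        extra_len <- round(0.5 * core_len)
        eoff <- sample.int(core_len - extra_len + 1L, 1L) - 1L
        extra <- mutate_seq(substr(genus_core, eoff + 1L, eoff + extra_len),
                            round(extra_len * 0.01))$res
        inserts <- c(inserts, list(list(kind = "shared_extra", seq = extra)))
      }
      if (length(inserts)) inserts <- inserts[sample.int(length(inserts))]
      # interleave: core split into length(inserts)+1 chunks
      k <- length(inserts) + 1L
      cuts <- if (k > 1L)
        sort(sample(seq(500L, core_len - 500L), k - 1L)) else integer(0)
      chunk_bounds <- cbind(c(0L, cuts), c(cuts, core_len))
      pieces <- character(0); rows <- list(); pos <- 0L
      for (ci in seq_len(k)) {
        chunk <- substr(core, chunk_bounds[ci, 1] + 1L, chunk_bounds[ci, 2])
        pieces <- c(pieces, chunk)
        rows[[length(rows) + 1L]] <- .truth_row(
          pos, pos + nchar(chunk), "shared_core",
          sprintf("core%02d", ci))
        pos <- pos + nchar(chunk)
        if (ci <= length(inserts)) {
          ins <- inserts[[ci]]
          pieces <- c(pieces, ins$seq)
          rows[[length(rows) + 1L]] <- .truth_row(
            pos, pos + nchar(ins$seq), ins$kind,
            sprintf("%s%02d", ins$kind, ci),
            donor_id = if (is.null(ins$donor_id)) NA else ins$donor_id,
            order = if (is.null(ins$order)) NA else ins$order,
            compartment = if (is.null(ins$compartment)) NA else ins$compartment)
          pos <- pos + nchar(ins$seq)
        }
      }
      genomes[[gid]] <- dna_seq(gid, paste(pieces, collapse = ""),
                                "circular", "simulated set genome")
      taxon[[gid]] <- data.frame(
        seq_id = gid, species = gsub("_", " ", gid), genus = genera[gi],
        family = "SimFamily", carpinus_like = is_carp,
        stringsAsFactors = FALSE)
      tf <- do.call(rbind, rows)
      tf$seq_id <- gid
      truth[[gid]] <- tf
    }
  }
  list(set = list(genomes = genomes, taxon = do.call(rbind, taxon)),
       truth = truth, donor_pools = donor_pools)
}
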