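# Fixtures for the finishing stages come from the truth-carrying
# simulator; the reference mitogenome used for classification is the
# simulated genome itself.

sim_fixture <- function(seed, length = 70000, n_repeats = 2, n_mtpt = 2,
                        ...) {
  sim <- generate_mitogenome(genome_spec(length = length,
                                         n_repeats = n_repeats,
                                         n_mtpt = n_mtpt, min_gap = 800,
                                         seed = seed, ...))
  frag <- fragment_to_contigs(sim)
  list(sim = sim, frag = frag)
}

test_that("contigs classify by reference homology, depth and the 500-bp rule", {
  fx <- sim_fixture(101)
  cls <- classify_contigs(fx$frag$contigs, fx$sim$genome, fx$sim$plastome)
  labels <- vapply(cls$contigs, `[[`, "", "class_label")
  truth <- vapply(fx$frag$contigs, `[[`, "", "truth_label")
  expect_true(all(labels[truth == "mito"] == "mito"))
  expect_true(all(labels[truth == "repeat"] == "mito"))
  expect_identical(unname(labels[truth == "plastid"]), "plastid")
  expect_true(all(labels[truth == "nuclear"] == "unassigned"))
  expect_lt(abs(cls$base_cov - fx$frag$base_cov) / fx$frag$base_cov, 0.15)

  # a 600-bp contig whose only reference hit is 400 bp stays unassigned
  short <- paste0(substr(fx$sim$genome$residues, 10001, 10400),
                  rand_dna(200))
  ctgs <- fx$frag$contigs
  ctgs$short1 <- list(seq = dna_seq("short1", short),
                      mean_cov = fx$frag$base_cov, is_circular = FALSE)
  cls2 <- classify_contigs(ctgs, fx$sim$genome, fx$sim$plastome)
  expect_identical(cls2$contigs$short1$class_label, "unassigned")

  # nothing matching the reference at all is an error
  bogus <- list(x = list(seq = dna_seq("x", rand_dna(5000)), mean_cov = 50))
  expect_error(classify_contigs(bogus, fx$sim$genome, fx$sim$plastome),
               "empty classification")
})

test_that("coverage baiting promotes only the mitochondrial depth band", {
  mk <- function(id, cov) list(seq = dna_seq(id, rand_dna(2000)),
                               mean_cov = cov, is_circular = FALSE,
                               class_label = "unassigned", mito_bp = 0L)
  ctgs <- list(a = mk("a", 50), b = mk("b", 2.5), c = mk("c", 105))
  res <- bait_by_coverage(ctgs, base_cov = 50, tolerance_frac = 0.4)
  expect_identical(res$contigs$a$class_label, "mito")     # 1.0x
  expect_identical(res$contigs$b$class_label, "unassigned")  # 0.05x
  expect_identical(res$contigs$c$class_label, "unassigned")  # 2.1x
  expect_equal(res$promotions$contig, "a")
})

test_that("copy numbers round from coverage ratios with an ambiguity band", {
  expect_equal(as.integer(estimate_copy_number(50, 50)), 1L)
  expect_equal(as.integer(estimate_copy_number(102, 50)), 2L)  # 2.04x
  expect_warning(cn <- estimate_copy_number(74.5, 50), "ambiguous")  # 1.49x
  expect_equal(as.integer(cn), 1L)
  expect_true(attr(cn, "ambiguous"))
  expect_equal(as.integer(suppressWarnings(
    estimate_copy_number(c(50, 149, 200), 50))), c(1L, 3L, 4L))
  expect_error(estimate_copy_number(50, 0), "positive")
})

test_that("MTPT ends pair by closest same-orientation plastome gap", {
  set.seed(110)
  plast <- dna_seq("p", rand_dna(30000, 0.37), "circular")
  ends <- data.frame(
    contig = c("ctgA", "ctgB"), side = c("R", "L"),
    sstart = c(10000L, 10450L), send = c(10150L, 10600L),
    strand = c("+", "+"), stringsAsFactors = FALSE)
  res <- pair_mtpt_ends(ends, plast)
  expect_equal(nrow(res$junctions), 1)
  j <- res$junctions
  expect_equal(nchar(j$filler), 300)
  expect_identical(j$filler, substr(plast$residues, 10151, 10450))
  expect_equal(j$plastome_from, 10150)
  expect_equal(j$plastome_to, 10450)

  # opposite orientations at close distance never pair without evidence
  ends2 <- ends
  ends2$strand <- c("+", "-")
  res2 <- pair_mtpt_ends(ends2, plast)
  expect_equal(nrow(res2$junctions), 0)
  expect_equal(nrow(res2$unresolved), 2)

  # a gap beyond the fill ceiling stays unresolved
  ends3 <- ends
  ends3[2, c("sstart", "send")] <- c(25000L, 25150L)
  res3 <- pair_mtpt_ends(ends3, plast)
  expect_equal(nrow(res3$junctions), 0)
})

test_that("ambiguous end pairings resolve deterministically", {
  set.seed(111)
  plast <- dna_seq("p", rand_dna(30000, 0.37), "circular")
  ends <- data.frame(
    contig = c("ctgA", "ctgZ", "ctgB", "ctgC"),
    side = c("R", "R", "L", "L"),
    sstart = c(1000L, 1000L, 1500L, 1500L),
    send = c(1150L, 1150L, 1650L, 1650L),
    strand = "+", stringsAsFactors = FALSE)
  r1 <- pair_mtpt_ends(ends, plast)
  r2 <- pair_mtpt_ends(ends[c(2, 4, 1, 3), ], plast)
  expect_equal(nrow(r1$junctions), 2)
  # ties broken by contig id: A pairs before Z, B before C
  expect_identical(r1$junctions$end_a_contig, c("ctgA", "ctgZ"))
  expect_identical(r1$junctions$end_b_contig, c("ctgB", "ctgC"))
  expect_identical(r1$junctions$end_a_contig, r2$junctions$end_a_contig)
  expect_identical(r1$junctions$end_b_contig, r2$junctions$end_b_contig)
})

test_that("filler correction applies majority evidence, keeps ties", {
  set.seed(112)
  filler <- rand_dna(500)
  ev <- data.frame(plastome_pos = c(1010L, 1100L, 1200L, 1300L, 1450L),
                   base = c("A", "C", "G", "T", "A"),
                   support_alt = c(5L, 5L, 5L, 5L, 5L),
                   support_ref = c(0L, 0L, 0L, 0L, 0L),
                   stringsAsFactors = FALSE)
  # force divergence: make sure the filler differs at those offsets
  chars <- strsplit(filler, "")[[1]]
  for (k in seq_len(nrow(ev))) {
    off <- ev$plastome_pos[k] - 1000L
    chars[off + 1] <- setdiff(c("A", "C", "G", "T"), ev$base[k])[1]
  }
  filler <- paste(chars, collapse = "")
  out <- correct_mtpt_bases(filler, 1000L, "+", ev, 30000L)
  expect_equal(out$n_changed, 5)
  for (k in seq_len(nrow(ev)))
    expect_identical(substr(out$filler, ev$plastome_pos[k] - 999,
                            ev$plastome_pos[k] - 999), ev$base[k])

  # identical evidence-free filler comes back unchanged and flagged
  out2 <- correct_mtpt_bases(filler, 1000L, "+", NULL)
  expect_false(out2$corrected)
  expect_identical(out2$filler, filler)

  # a 50/50 tie keeps the plastome base and is logged
  ev3 <- ev[1, ]; ev3$support_ref <- 5L
  out3 <- correct_mtpt_bases(filler, 1000L, "+", ev3, 30000L)
  expect_equal(out3$n_changed, 0)
  expect_equal(out3$n_ambiguous, 1)
})

test_that("simulated assemblies round-trip to the truth genome", {
  for (s in c(201, 202, 203)) {
    fx <- sim_fixture(s)
    rep <- assemble(fx$frag$contigs, fx$sim$genome, fx$sim$plastome,
                    gene_db = fx$sim$gene_db, links = fx$frag$links,
                    mtpt_evidence = fx$frag$mtpt_evidence)
    expect_length(rep$chromosomes, 1)
    expect_identical(rep$chromosomes[[1]]$topology, "circular")
    expect_identical(canonical_rotation(rep$chromosomes[[1]]),
                     canonical_rotation(fx$sim$genome))
    expect_equal(nrow(rep$unresolved_ends), 0)
    # conservation: emitted length == contig bp (with multiplicity) + fillers
    expect_equal(seq_length(rep$chromosomes[[1]]),
                 rep$total_contig_bp + rep$total_filler_bp)
    expect_true(all(rep$gene_completeness$status == "intact"))
  }
})

test_that("withholding a junction splits topology but never corrupts content", {
  fx <- sim_fixture(204)
  full <- assemble(fx$frag$contigs, fx$sim$genome, fx$sim$plastome,
                   links = fx$frag$links,
                   mtpt_evidence = fx$frag$mtpt_evidence)
  expect_identical(full$chromosomes[[1]]$topology, "circular")
  doubled_truth <- paste0(fx$sim$genome$residues, fx$sim$genome$residues)
  for (drop_k in seq_len(nrow(fx$frag$links))) {
    rep <- assemble(fx$frag$contigs, fx$sim$genome, fx$sim$plastome,
                    links = fx$frag$links[-drop_k, , drop = FALSE],
                    mtpt_evidence = fx$frag$mtpt_evidence)
    expect_gte(nrow(rep$unresolved_ends), 1)
    for (chrom in rep$chromosomes) {
      expect_identical(chrom$topology, "linear")
      # every emitted chromosome is a contiguous slice of the truth circle
      expect_true(grepl(chrom$residues, doubled_truth, fixed = TRUE) ||
                    grepl(mitomosaic::revcomp(chrom$residues),
                          doubled_truth, fixed = TRUE))
    }
  }
})

test_that("disjoint junction graphs traverse into separate circles", {
  set.seed(120)
  mk <- function(id, n) list(seq = dna_seq(id, rand_dna(n)),
                             mean_cov = 50, copy_number = 1L)
  contigs <- list(c1 = mk("c1", 900), c2 = mk("c2", 700),
                  c3 = mk("c3", 800), c4 = mk("c4", 600))
  j <- function(a, b) data.frame(
    end_a_contig = a, end_a_side = "R", end_b_contig = b,
    end_b_side = "L", kind = "overlap", strand = "+",
    plastome_from = NA_integer_, plastome_to = NA_integer_,
    gap = NA_integer_, filler = "", through_contig = "",
    through_orient = "", stringsAsFactors = FALSE)
  junctions <- rbind(j("c1", "c2"), j("c2", "c1"),
                     j("c3", "c4"), j("c4", "c3"))
  rep <- traverse(contigs, junctions)
  expect_length(rep$chromosomes, 2)
  expect_identical(unname(vapply(rep$chromosomes, `[[`, "", "topology")),
                   c("circular", "circular"))
  expect_equal(sort(unname(vapply(rep$chromosomes, seq_length, 0L)),
                    decreasing = TRUE), c(1600L, 1400L))
})

test_that("gene completeness distinguishes intact, rescued and pseudo", {
  set.seed(121)
  db <- make_core_gene_db()
  g1 <- db[[1]]; g2 <- db[[2]]; g3 <- db[[3]]
  # g1 intact on a mito contig; g3 with a 1-bp insertion (frameshift)
  g3res <- g3$residues
  g3shift <- paste0(substr(g3res, 1, 50), "A",
                    substr(g3res, 51, nchar(g3res)))
  mito <- list(
    m1 = list(seq = dna_seq("m1", paste0(rand_dna(800), g1$residues,
                                         rand_dna(800))), mean_cov = 50),
    m2 = list(seq = dna_seq("m2", paste0(rand_dna(500), g3shift,
                                         rand_dna(500))), mean_cov = 50))
  other <- list(
    u1 = list(seq = dna_seq("u1", paste0(rand_dna(400), g2$residues,
                                         rand_dna(400))), mean_cov = 48))
  res <- check_gene_completeness(mito, db[1:3], other)
  expect_identical(unname(res$status[g1$id]), "intact")
  expect_identical(unname(res$status[g3$id]), "pseudo")
  expect_identical(unname(res$status[g2$id]), "missing")
  expect_equal(res$rescue$gene, g2$id)
  expect_equal(res$rescue$contig, "u1")
})

test_that("inverted repeats reconstruct and are reported as isomers", {
  sim <- generate_mitogenome(genome_spec(
    length = 70000, n_repeats = 1, repeat_len_range = c(900, 900),
    repeat_inverted = TRUE, n_mtpt = 1, min_gap = 800, seed = 205))
  frag <- fragment_to_contigs(sim)
  rep <- assemble(frag$contigs, sim$genome, sim$plastome,
                  links = frag$links, mtpt_evidence = frag$mtpt_evidence)
  expect_identical(canonical_rotation(rep$chromosomes[[1]]),
                   canonical_rotation(sim$genome))
  expect_gte(rep$isomers, 2)
  # a direct-repeat-only assembly reports a single isomer
  fx <- sim_fixture(206, n_repeats = 1, n_mtpt = 1)
  rep2 <- assemble(fx$frag$contigs, fx$sim$genome, fx$sim$plastome,
                   links = fx$frag$links,
                   mtpt_evidence = fx$frag$mtpt_evidence)
  expect_equal(rep2$isomers, 1)
})

test_that("verification flags zero coverage and unsupported junctions", {
  fx <- sim_fixture(207)
  rep <- assemble(fx$frag$contigs, fx$sim$genome, fx$sim$plastome,
                  links = fx$frag$links,
                  mtpt_evidence = fx$frag$mtpt_evidence)
  L <- seq_length(rep$chromosomes[[1]])
  clean <- verify_assembly(rep, coverage = list(chr1 = rep(8, L)),
                           reference = fx$sim$genome)
  expect_equal(nrow(clean$flags), 0)
  expect_true(clean$pass[["chr1"]])

  cov <- rep(8, L); cov[4321] <- 0
  one <- verify_assembly(rep, coverage = list(chr1 = cov))
  expect_equal(nrow(one$flags), 1)
  expect_equal(one$flags$pos, 4320)
  expect_identical(one$flags$type, "zero_coverage")

  # scramble the sequence around one junction: its window loses support
  bad <- rep
  p <- rep$junction_positions$pos[1]
  res <- rep$chromosomes[[1]]$residues
  bad$chromosomes[[1]]$residues <- paste0(
    substr(res, 1, p - 300), rand_dna(600),
    substr(res, p + 301, nchar(res)))
  v <- verify_assembly(bad, reference = fx$sim$genome)
  expect_true(any(v$flags$type == "junction_unsupported" &
                    v$flags$pos == p))
})
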