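# A hand-built three-genus toy set for the masking rules, plus simulator
# sets for recovery and attribution.

toy_set <- function(seed = 301) {
  set.seed(seed)
  core <- rand_dna(8000)
  island60 <- rand_dna(60)
  blockAA <- rand_dna(500)   # shared within genus A only
  privA1 <- rand_dna(1000)
  gA1 <- dna_seq("gA1", paste0(core, privA1, island60, rand_dna(400),
                               blockAA), "linear")
  gA2 <- dna_seq("gA2", paste0(mutate_k(core, 80), rand_dna(1500),
                               blockAA), "linear")
  gB1 <- dna_seq("gB1", paste0(mutate_k(core, 80), rand_dna(300),
                               island60, rand_dna(1200)), "linear")
  gC1 <- dna_seq("gC1", paste0(mutate_k(core, 80), rand_dna(2000)),
                 "linear")
  taxon <- data.frame(
    seq_id = c("gA1", "gA2", "gB1", "gC1"),
    genus = c("GenA", "GenA", "GenB", "GenC"),
    stringsAsFactors = FALSE)
  genome_set(list(gA1 = gA1, gA2 = gA2, gB1 = gB1, gC1 = gC1), taxon)
}

test_that("the mask marks only cross-genus homology of qualifying length", {
  set <- toy_set()
  mask <- build_cross_genus_mask("gA1", set)
  L <- seq_length(set$genomes$gA1)
  expect_length(mask, L)
  expect_true(all(mask[1:7900]))            # shared core: masked
  expect_true(all(!mask[8001:9000]))        # private segment: open
  expect_true(all(!mask[9001:9060]))        # 60-bp island: below the floor
  expect_true(all(!mask[(L - 499):L]))      # same-genus block: open

  # a genome identical to one of another genus is fully masked
  set2 <- set
  set2$genomes$gA1 <- dna_seq("gA1", set$genomes$gB1$residues)
  expect_true(all(build_cross_genus_mask("gA1", set2)))

  one <- genome_set(set$genomes["gA1"],
                    set$taxon[set$taxon$seq_id == "gA1", ])
  expect_error(build_cross_genus_mask("gA1", one), "two genera")
  expect_error(build_cross_genus_mask("nope", set), "not in the set")
})

test_that("specific runs respect the 300-bp floor and wrap the origin", {
  set.seed(302)
  g <- dna_seq("g", rand_dna(5000), "linear")
  mask <- rep(TRUE, 5000)
  mask[1001:1250] <- FALSE                  # 250 bp: below the floor
  expect_equal(nrow(extract_gss(g, mask, 300)), 0)
  mask[2001:2400] <- FALSE                  # 400 bp
  mask[3001:4200] <- FALSE                  # 1,200 bp
  rec <- extract_gss(g, mask, 300)
  expect_equal(nrow(rec), 2)
  expect_equal(sum(rec$length), 1600)
  expect_identical(rec$sequence[1], substr(g$residues, 2001, 2400))

  expect_equal(nrow(extract_gss(g, rep(TRUE, 5000), 300)), 0)
  expect_error(extract_gss(g, mask[1:100], 300), "mask length")

  # circular: a run across the origin joins into one record
  gc <- dna_seq("gc", rand_dna(5000), "circular")
  maskc <- rep(TRUE, 5000)
  maskc[4801:5000] <- FALSE
  maskc[1:200] <- FALSE
  recc <- extract_gss(gc, maskc, 300)
  expect_equal(nrow(recc), 1)
  expect_equal(recc$length, 400)
  expect_equal(recc$start, 4800)
  expect_identical(recc$sequence,
                   paste0(substr(gc$residues, 4801, 5000),
                          substr(gc$residues, 1, 200)))
})

test_that("mask and specific runs complement each other exactly", {
  gs <- generate_genus_set(n_genera = 3, genomes_per_genus = 2,
                           genome_length = 30000, seed = 303)
  set <- genome_set(gs$set$genomes, gs$set$taxon)
  th <- default_thresholds()
  for (gid in names(set$genomes)[1:3]) {
    L <- seq_length(set$genomes[[gid]])
    mask <- build_cross_genus_mask(gid, set, th)
    rec <- extract_gss(set$genomes[[gid]], mask, th$gss_min_bp)
    open <- sum(!mask)
    short_open <- open - sum(rec$length)   # sub-300-bp runs absorbed
    expect_equal(sum(mask) + short_open + sum(rec$length), L)
    expect_gte(short_open, 0)
  }
})

test_that("attribution finds planted provenance and splits two donors", {
  pools <- make_donor_pools(seed = 304)
  donA <- pools[[which(vapply(pools, `[[`, "", "order") == "OrderA" &
                         vapply(pools, `[[`, "", "compartment") ==
                           "mitochondrial")[1]]]
  donB <- pools[[which(vapply(pools, `[[`, "", "order") == "OrderB" &
                         vapply(pools, `[[`, "", "compartment") ==
                           "mitochondrial")[1]]]
  # verbatim single-donor GSS
  rec1 <- data.frame(gss_id = "g1", seq_id = "x", start = 0L, end = 800L,
                     length = 800L,
                     sequence = substr(donA$residues, 101, 900),
                     stringsAsFactors = FALSE)
  att1 <- attribute_gss(rec1, pools)
  expect_equal(nrow(att1), 1)
  expect_identical(att1$ref_id, donA$id)
  expect_identical(att1$order, "OrderA")

  # two-donor chimera: one best hit per half
  rec2 <- rec1
  rec2$sequence <- paste0(substr(donA$residues, 101, 500),
                          substr(donB$residues, 1001, 1400))
  att2 <- attribute_gss(rec2, pools)
  expect_equal(nrow(att2), 2)
  expect_setequal(att2$order, c("OrderA", "OrderB"))

  # only a 90-bp reference match: unlinked
  set.seed(305)
  rec3 <- rec1
  rec3$sequence <- paste0(rand_dna(200), substr(donA$residues, 1, 90),
                          rand_dna(200))
  expect_equal(nrow(attribute_gss(rec3, pools)), 0)
  expect_error(attribute_gss(rec1, list()), "empty reference")
})

test_that("plastid best hits over known MTPTs are flagged as artifacts", {
  pools <- make_donor_pools(seed = 306)
  donP <- pools[[which(vapply(pools, `[[`, "", "compartment") ==
                         "plastid")[1]]]
  rec <- data.frame(gss_id = "g1", seq_id = "x", start = 5000L,
                    end = 5600L, length = 600L,
                    sequence = substr(donP$residues, 201, 800),
                    stringsAsFactors = FALSE)
  mtpt <- intervals("x", 4900, 5700)
  att <- attribute_gss(rec, pools, mtpt_intervals = mtpt)
  expect_true(all(att$is_mtpt_artifact))
  att2 <- attribute_gss(rec, pools)
  expect_false(any(att2$is_mtpt_artifact))
})

test_that("linkage totals recover the planted donor design", {
  gs <- generate_genus_set(n_genera = 3, genomes_per_genus = 2,
                           genome_length = 30000, hgt_per_genome = 2,
                           seed = 307)
  set <- genome_set(gs$set$genomes, gs$set$taxon)
  all_rec <- list(); all_att <- list()
  for (gid in names(set$genomes)) {
    mask <- build_cross_genus_mask(gid, set)
    rec <- extract_gss(set$genomes[[gid]], mask, 300)
    all_rec[[gid]] <- rec
    all_att[[gid]] <- attribute_gss(rec, gs$donor_pools)
  }
  rec <- do.call(rbind, all_rec)
  att <- do.call(rbind, all_att)
  lt <- linkage_table(att, rec, set)
  # per-genus totals equal the summed record lengths
  for (g in unique(set$taxon$genus)) {
    ids <- set$taxon$seq_id[set$taxon$genus == g]
    expect_equal(lt$gss_totals$total_gss_bp[lt$gss_totals$genus == g],
                 sum(rec$length[rec$seq_id %in% ids]))
  }
  # each planted (genus, order) donor transfer appears within 5%
  for (gid in names(gs$truth)) {
    tf <- gs$truth[[gid]]
    g <- set$taxon$genus[set$taxon$seq_id == gid]
    for (k in which(tf$kind == "hgt")) {
      row <- lt$links[lt$links$genus == g & lt$links$order == tf$order[k], ]
      expect_equal(nrow(row), 1)
    }
  }
  planted_by_go <- list()
  for (gid in names(gs$truth)) {
    tf <- gs$truth[[gid]]
    g <- set$taxon$genus[set$taxon$seq_id == gid]
    for (k in which(tf$kind == "hgt")) {
      key <- paste(g, tf$order[k])
      planted_by_go[[key]] <- (planted_by_go[[key]] %||% 0) +
        (tf$end[k] - tf$start[k])
    }
  }
  for (key in names(planted_by_go)) {
    parts <- strsplit(key, " ")[[1]]
    got <- lt$links$total_linked_bp[lt$links$genus == parts[1] &
                                      lt$links$order == parts[2]]
    expect_lte(abs(got - planted_by_go[[key]]) / planted_by_go[[key]], 0.05)
  }
  # compartment proportions per genus sum to one
  for (g in unique(lt$compartments$genus))
    expect_equal(sum(lt$compartments$proportion[
      lt$compartments$genus == g]), 1)
})

test_that("shared-homology fractions behave at the extremes", {
  set <- toy_set(310)
  set2 <- set
  set2$genomes$gA1 <- dna_seq("gA1", set$genomes$gB1$residues)
  expect_equal(shared_homology_fraction("gA1", set2)$overall, 1.0)
  set3 <- set
  set3$genomes$gA1 <- dna_seq("gA1", rand_dna(6000))
  expect_equal(shared_homology_fraction("gA1", set3)$overall, 0.0)
})

test_that("the enlarged-by-shared genome tops sharing, not specificity", {
  gs <- generate_genus_set(n_genera = 3, genomes_per_genus = 2,
                           genome_length = 35000, carpinus_like = TRUE,
                           seed = 311)
  set <- genome_set(gs$set$genomes, gs$set$taxon)
  carp <- gs$set$taxon$seq_id[gs$set$taxon$carpinus_like]
  frac <- vapply(names(set$genomes), function(g)
    shared_homology_fraction(g, set)$overall, 0)
  gssbp <- vapply(names(set$genomes), function(g) {
    mask <- build_cross_genus_mask(g, set)
    sum(extract_gss(set$genomes[[g]], mask, 300)$length)
  }, 0)
  expect_identical(names(which.max(frac)), carp)
  expect_false(identical(names(which.max(gssbp)), carp))
})

test_that("a genus override changes only rows involving that taxon", {
  gs <- generate_genus_set(n_genera = 3, genomes_per_genus = 2,
                           genome_length = 25000, seed = 312)
  set <- genome_set(gs$set$genomes, gs$set$taxon)
  split_id <- set$taxon$seq_id[3]
  set_ov <- genome_set(gs$set$genomes, gs$set$taxon,
                       genus_override = setNames("OwnGenus", split_id))
  affected_genus <- gs$set$taxon$genus[gs$set$taxon$seq_id == split_id]
  for (gid in names(set$genomes)) {
    g <- set$taxon$genus[set$taxon$seq_id == gid]
    if (g == affected_genus) next  # partner gains a cross-genus genome
    m1 <- build_cross_genus_mask(gid, set)
    m2 <- build_cross_genus_mask(gid, set_ov)
    expect_identical(as.logical(m1), as.logical(m2))
  }
})

test_that("labelled reference collections round-trip through FASTA", {
  pools <- make_donor_pools(n_orders = 2, entries_per_order = 1,
                            entry_len = 300, seed = 313)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(pools, f)
  back <- read_refdb(f)
  expect_identical(names(back), names(pools))
  for (id in names(pools)) {
    expect_identical(back[[id]]$order, pools[[id]]$order)
    expect_identical(back[[id]]$compartment, pools[[id]]$compartment)
    expect_identical(back[[id]]$taxon, pools[[id]]$taxon)
  }
})
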