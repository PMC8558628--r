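test_that("a sequence matched against itself yields one full-length hit", {
  set.seed(2)
  s <- rand_dna(200)
  h <- find_local_matches(s, s, min_len = 50, min_identity = 95)
  expect_equal(nrow(h), 1)
  expect_equal(h$qstart, 0)
  expect_equal(h$qend, 200)
  expect_equal(h$sstart, 0)
  expect_equal(h$send, 200)
  expect_equal(h$identity_pct, 100)
  expect_identical(h$strand, "+")
})

test_that("a reverse-complemented block is found on the minus strand", {
  set.seed(3)
  q <- rand_dna(5000)
  block <- substr(q, 2001, 2200)
  s <- paste0(rand_dna(3000), rc(block), rand_dna(1800))
  h <- find_local_matches(q, s, min_len = 100, min_identity = 95)
  expect_equal(nrow(h), 1)
  expect_identical(h$strand, "-")
  # planted coordinates, allowing a few bp of chance-flank extension
  expect_lte(abs(h$qstart - 2000), 5)
  expect_lte(abs(h$qend - 2200), 5)
  expect_lte(abs(h$sstart - 3000), 5)
  expect_lte(abs(h$send - 3200), 5)
})

test_that("independent random sequences share no long near-identical hit", {
  set.seed(4)
  q <- rand_dna(5000)
  s <- rand_dna(5000)
  expect_equal(nrow(find_local_matches(q, s, min_len = 100,
                                       min_identity = 95)), 0)
})

test_that("parameter preconditions are enforced", {
  expect_error(find_local_matches("ACGT", "ACGT", word_size = 4),
               "word_size")
  expect_error(find_local_matches(rand_dna(100), rand_dna(100),
                                  min_len = 10, word_size = 16), "min_len")
  expect_error(find_local_matches("", rand_dna(50)), "empty")
})

test_that("hits are symmetric under query/subject exchange", {
  set.seed(5)
  for (i in 1:10) {
    bg1 <- rand_dna(3000)
    bg2 <- rand_dna(3000)
    block <- rand_dna(sample(150:600, 1))
    a <- plant_into(bg1, list(block), sample(0:2300, 1))
    b <- plant_into(bg2, list(mutate_k(block, 3)), sample(0:2300, 1))
    hab <- find_local_matches(a, b, min_len = 100, min_identity = 95)
    hba <- find_local_matches(b, a, min_len = 100, min_identity = 95)
    expect_equal(nrow(hab), nrow(hba))
    o1 <- order(hab$qstart)
    o2 <- order(hba$sstart)
    expect_equal(hab$qstart[o1], hba$sstart[o2])
    expect_equal(hab$sstart[o1], hba$qstart[o2])
    expect_equal(hab$length[o1], hba$length[o2])
  }
})

test_that("planted shared blocks are recovered and nothing else is", {
  set.seed(6)
  n_missed <- 0
  for (i in 1:25) {
    k <- sample(2:4, 1)
    lens <- sample(100:2000, k)
    idents <- sample(c(90, 93, 95, 97, 99, 100), k, replace = TRUE)
    blocks <- lapply(lens, rand_dna)
    # one 2.2-kb slot per block, shuffled independently per sequence
    qlen <- 2200L * k + 400L
    slot <- function() 2200L * (sample(k) - 1L) + sample(0:150, k) + 100L
    qoff <- sort(slot())
    soff <- sort(slot())
    q <- plant_into(rand_dna(qlen), blocks, qoff)
    s <- plant_into(rand_dna(qlen), lapply(seq_len(k), function(j)
      mutate_k(blocks[[j]], round(lens[j] * (100 - idents[j]) / 100))),
      soff)
    h <- find_local_matches(q, s, min_len = 100, min_identity = 95)
    covered <- logical(qlen)
    for (r in seq_len(nrow(h)))
      covered[(h$qstart[r] + 1):h$qend[r]] <- TRUE
    for (j in seq_len(k)) {
      inside <- covered[(qoff[j] + 1):(qoff[j] + lens[j])]
      if (idents[j] >= 96 && lens[j] >= 100) {
        if (mean(inside) < 0.95) n_missed <- n_missed + 1
      }
    }
    # no hit of >= 100 bp wholly outside planted blocks
    planted <- logical(qlen)
    for (j in seq_len(k))
      planted[(qoff[j] + 1):(qoff[j] + lens[j])] <- TRUE
    for (r in seq_len(nrow(h)))
      expect_true(any(planted[(h$qstart[r] + 1):h$qend[r]]))
  }
  expect_equal(n_missed, 0)
})

test_that("self_matches drops the diagonal and canonicalizes pairs", {
  set.seed(9)
  expect_equal(nrow(self_matches(rand_dna(10000), min_len = 50,
                                 min_identity = 95)), 0)
  g <- rand_dna(20000)
  unit <- substr(g, 3001, 4000)
  g2 <- paste0(substr(g, 1, 10000), unit, substr(g, 10001, 20000))
  sm <- self_matches(g2, min_len = 50, min_identity = 95)
  expect_equal(nrow(sm), 1)
  expect_lt(sm$qstart, sm$sstart)
  expect_gte(sm$length, 1000)
  expect_lte(sm$length, 1010)
})

test_that("a dispersed triplication reports every pair once", {
  set.seed(10)
  unit <- rand_dna(300)
  g <- paste0(rand_dna(2000), unit, rand_dna(1500), unit,
              rand_dna(1500), unit, rand_dna(2000))
  sm <- self_matches(g, min_len = 50, min_identity = 95)
  expect_equal(nrow(sm), 3)  # (1,2), (1,3), (2,3)
  expect_true(all(sm$qstart < sm$sstart))
  key <- paste(sm$qstart, sm$sstart)
  expect_equal(anyDuplicated(key), 0)
})

test_that("the tabular adapter converts coordinates and strand", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "q\ts\t98.0\t150\t3\t0\t1\t150\t500\t649\t1e-50\t270",
    "q\ts\t91.0\t120\t10\t0\t200\t319\t900\t781\t1e-20\t130"), f)
  h <- external_search_adapter(f)
  expect_equal(h$qstart[1], 0)
  expect_equal(h$qend[1], 150)
  expect_equal(h$sstart[1], 499)
  expect_equal(h$send[1], 649)
  expect_identical(h$strand[1], "+")
  expect_identical(h$strand[2], "-")  # descending subject coordinates
  expect_equal(h$sstart[2], 780)
  expect_equal(h$send[2], 900)
  expect_equal(nrow(external_search_adapter(f, max_evalue = 1e-30)), 1)

  fe <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), fe)
  expect_equal(nrow(external_search_adapter(fe)), 0)

  fb <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q\ts\tonly\tfour\tcolumns", fb)
  expect_error(external_search_adapter(fb), "dialect")
})

test_that("hit tables round-trip through the tabular dialect", {
  set.seed(12)
  q <- rand_dna(4000)
  s <- paste0(rand_dna(1000), substr(q, 501, 1500), rand_dna(500),
              rc(substr(q, 2501, 3000)), rand_dna(800))
  h <- find_local_matches(q, s, min_len = 100, min_identity = 95)
  expect_gte(nrow(h), 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(h, f)
  back <- external_search_adapter(f)
  expect_equal(back$qstart, h$qstart)
  expect_equal(back$qend, h$qend)
  expect_equal(back$sstart, h$sstart)
  expect_equal(back$send, h$send)
  expect_identical(back$strand, h$strand)
})

test_that("the matcher agrees with an external aligner on a planted block", {
  set.seed(13)
  dir <- withr::local_tempdir()
  q <- rand_dna(12000)
  block <- substr(q, 3001, 4500)
  s <- paste0(rand_dna(5000), block, rand_dna(4000))
  write_fasta(dna_seq("q", q), file.path(dir, "q.fa"))
  write_fasta(dna_seq("s", s), file.path(dir, "s.fa"))
  out <- file.path(dir, "hits.tsv")
  status <- system2("blastn",
                    c("-query", file.path(dir, "q.fa"),
                      "-subject", file.path(dir, "s.fa"),
                      "-task", "blastn", "-word_size", "16",
                      "-outfmt", "6", "-out", out),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0)
  ext <- external_search_adapter(out, max_evalue = 1e-10)
  mine <- find_local_matches(q, s, min_len = 100, min_identity = 90)
  expect_equal(nrow(mine), 1)
  expect_gte(nrow(ext), 1)
  # same planted block: near-complete reciprocal overlap on the query
  ov <- min(mine$qend[1], ext$qend[1]) - max(mine$qstart[1], ext$qstart[1])
  expect_gte(ov / 1500, 0.99)
})
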