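# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths where they stand
# as the reference: union counting marks positions in a boolean array,
# the ORF oracle walks codons frame by frame.

rand_dna <- function(n, gc = 0.45) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

rc <- function(s) chartr("ACGT", "TGCA",
                         paste(rev(strsplit(s, "")[[1]]), collapse = ""))

# position-marking union oracle (0-based half-open intervals)
oracle_union <- function(starts, ends, size = max(ends, 0L)) {
  v <- logical(size)
  for (i in seq_along(starts))
    if (ends[i] > starts[i]) v[(starts[i] + 1L):ends[i]] <- TRUE
  sum(v)
}

# brute-force ORF scan of a linear residue string, forward strand only:
# maximal ATG..stop frames, stop excluded, >= min_aa sense codons
oracle_orfs_fwd <- function(res, min_aa) {
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  n <- nchar(res)
  for (f in 0:2) {
    i <- f + 1L
    atg <- NA_integer_
    while (i + 2L <= n) {
      cod <- substr(res, i, i + 2L)
      if (is.na(atg) && cod == "ATG") atg <- i
      if (cod %in% stops) {
        if (!is.na(atg)) {
          aa <- (i - atg) %/% 3L
          if (aa >= min_aa)
            out[[length(out) + 1L]] <- c(start = atg - 1L, end = i - 1L,
                                         aa = aa)
        }
        atg <- NA_integer_
      }
      i <- i + 3L
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(), aa = integer()))
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$start), ]
}

# six-frame oracle: forward frames plus reverse-strand frames mapped back
oracle_orfs <- function(res, min_aa) {
  fwd <- oracle_orfs_fwd(res, min_aa)
  if (nrow(fwd)) fwd$strand <- "+"
  n <- nchar(res)
  rev <- oracle_orfs_fwd(rc(res), min_aa)
  if (nrow(rev)) {
    rev <- data.frame(start = n - rev$end, end = n - rev$start,
                      aa = rev$aa, strand = "-")
  }
  out <- rbind(fwd, rev)
  out[order(out$start, out$strand), , drop = FALSE]
}

# plant `blocks` (list of residue strings) into a random background at
# given 0-based offsets, returning the composite string
plant_into <- function(background, blocks, offsets) {
  chars <- strsplit(background, "")[[1]]
  for (i in seq_along(blocks)) {
    b <- strsplit(blocks[[i]], "")[[1]]
    chars[(offsets[i] + 1L):(offsets[i] + length(b))] <- b
  }
  paste(chars, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# substitute exactly k positions of a residue string
mutate_k <- function(s, k) {
  chars <- strsplit(s, "")[[1]]
  pos <- sample.int(length(chars), k)
  for (p in pos)
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste(chars, collapse = "")
}
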