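# Independent oracles used by the unit and acceptance tests. These
# deliberately avoid the package's optimized code paths: Tm values are
# recomputed per candidate with the scalar melting_temperature(),
# searches are exhaustive loops, and reconstruction overlays fragments
# onto a coordinate buffer instead of stitching.

# brute-force overlap choice: every suffix length, scalar Tm calls,
# ties to the shorter suffix
oracle_select_overlap <- function(context, tm_target, params) {
  n <- nchar(context)
  ks <- params$overlap_len_min:params$overlap_len_max
  best_k <- NA_integer_
  best_dev <- Inf
  for (k in ks) {
    s <- substr(context, n - k + 1L, n)
    dev <- abs(melting_temperature(s, params$tm_par) - tm_target)
    if (dev < best_dev) {
      best_dev <- dev
      best_k <- k
    }
  }
  best_k
}

# brute-force screening: re-run every candidate annealing temperature
# and recompute the max deviation from the scalar Tm path
oracle_best_tm_set <- function(gene, params) {
  cands <- params$tm_screen_min:(params$tm_screen_max - 1L)
  dev_max <- vapply(cands, function(tm_set) {
    fr <- partition_gene(gene, tm_set, params)
    tms <- melting_temperature(fr$overlap_seq[!is.na(fr$overlap_seq)],
                               params$tm_par)
    if (length(tms) == 0L) 0 else max(abs(tms - mean(tms)))
  }, numeric(1))
  list(tm_set = cands[which.min(dev_max)], dev_max = min(dev_max))
}

# coordinate-overlay reconstruction: place every fragment at its
# declared coordinates, failing on any conflict or gap
oracle_reconstruct <- function(fragments, gene_length) {
  buf <- rep(NA_character_, gene_length)
  for (i in seq_len(nrow(fragments))) {
    chars <- strsplit(fragments$seq[i], "", fixed = TRUE)[[1L]]
    idx <- fragments$start[i]:fragments$end[i]
    if (length(chars) != length(idx)) return(NA_character_)
    clash <- !is.na(buf[idx]) & buf[idx] != chars
    if (any(clash)) return(NA_character_)
    buf[idx] <- chars
  }
  if (anyNA(buf)) return(NA_character_)
  paste(buf, collapse = "")
}

# flip a random subset of oligos to the opposite strand
flip_random_oligos <- function(seqs, seed) {
  set.seed(seed)
  flip <- sample(c(TRUE, FALSE), length(seqs), replace = TRUE)
  seqs[flip] <- reverse_complement(seqs[flip])
  seqs
}

# search gene lengths until the default partition has exactly n fragments
gene_with_n_fragments <- function(n, tm_set = 58L,
                                  params = design_parameters(),
                                  seed = 99L) {
  len <- params$fragment_len + (n - 1L) * 34L
  for (i in 1:40) {
    gene <- random_gene(max(len, params$fragment_len + 1L), gc = 0.5,
                        seed = seed + i)
    fr <- partition_gene(gene, tm_set, params)
    if (nrow(fr) == n) return(list(gene = gene, fragments = fr))
    len <- len + (n - nrow(fr)) * 34L
  }
  stop("could not construct a gene with exactly ", n, " fragments")
}
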