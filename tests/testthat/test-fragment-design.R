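# Core design algorithm: overlap selection, gene partitioning,
# primer design and annealing-temperature screening.

test_that("parameter validation catches inconsistent settings", {
  expect_error(design_parameters(overlap_len_min = 4), "minimum duplex length")
  expect_error(design_parameters(overlap_len_max = 59), "smaller than fragment_len")
  expect_error(design_parameters(overlap_len_min = 30, overlap_len_max = 20),
               "overlap_len_min")
  expect_error(design_parameters(tm_screen_min = 60, tm_screen_max = 60),
               "tm_screen_min")
  expect_error(design_parameters(fragment_len = 20, overlap_len_max = 15),
               "remainder_min")
})

test_that("overlap selection equals exhaustive search with shortest-wins ties", {
  params <- design_parameters()
  for (seed in 1:50) {
    ctx <- random_gene(59, gc = runif(1, 0.3, 0.7), seed = seed)$seq
    ov <- select_overlap(ctx, 58, params)
    expect_identical(ov$length, oracle_select_overlap(ctx, 58, params))
    # returned metadata is internally consistent
    expect_identical(ov$seq, substr(ctx, 59 - ov$length + 1L, 59))
    expect_equal(ov$tm, melting_temperature(ov$seq), tolerance = 1e-9)
    # the tie rule: no shorter suffix achieves the same minimal deviation
    devs <- vapply(params$overlap_len_min:params$overlap_len_max, function(k) {
      abs(melting_temperature(substr(ctx, 59 - k + 1L, 59)) - 58)
    }, numeric(1))
    kmin <- params$overlap_len_min + which(devs == min(devs)) - 1L
    expect_identical(ov$length, min(kmin))
  }
})

test_that("a singleton overlap search range returns that suffix regardless of Tm", {
  params <- design_parameters(overlap_len_min = 20, overlap_len_max = 20)
  ctx <- random_gene(59, seed = 3)$seq
  ov <- select_overlap(ctx, 99, params)
  expect_identical(ov$length, 20L)
  expect_identical(ov$seq, substr(ctx, 40, 59))
  expect_error(select_overlap("ACGTACGT", 58, params), "shorter than overlap_len_max")
})

test_that("a gene no longer than the fragment length is a single fragment", {
  g <- random_gene(59, seed = 5)
  fr <- suppressWarnings(partition_gene(g, 58))
  expect_identical(nrow(fr), 1L)
  expect_identical(fr$seq, g$seq)
  expect_true(is.na(fr$overlap_seq))
  expect_warning(
    partition_gene(random_gene(80, seed = 5), 58,
                   design_parameters(fragment_len = 90)),
    "annealed"
  )
  expect_error(partition_gene(random_gene(30, seed = 5), 58), "shorter than")
})

test_that("partitions are lossless with full-length interior fragments", {
  params <- design_parameters()
  for (seed in c(11, 12, 13)) {
    g <- random_gene(1000, gc = 0.5, seed = seed)
    fr <- partition_gene(g, 58, params)
    expect_gt(nrow(fr), 10)
    # every fragment re-extracted from the gene by coordinates matches
    expect_identical(fr$seq, substring(g$seq, fr$start, fr$end))
    # all but the last fragment have the set length
    expect_true(all(fr$length[-nrow(fr)] == params$fragment_len))
    # independent coordinate-overlay reconstruction
    expect_identical(oracle_reconstruct(fr, g$length), g$seq)
    # junction overlaps are prefixes of the right-hand fragment and
    # (except at a borrowed terminal junction) suffixes of the left
    for (i in seq_len(nrow(fr) - 1L)) {
      ov <- fr$overlap_seq[i]
      expect_identical(substr(fr$seq[i + 1L], 1L, nchar(ov)), ov)
      shared <- fr$end[i] - fr$start[i + 1L] + 1L
      if (shared == fr$overlap_len[i]) {
        expect_identical(substr(fr$seq[i], fr$length[i] - nchar(ov) + 1L,
                                fr$length[i]), ov)
      }
    }
    # overlap lengths stay within the search bounds
    expect_true(all(fr$overlap_len[-nrow(fr)] >= params$overlap_len_min))
    expect_true(all(fr$overlap_len[-nrow(fr)] <= params$overlap_len_max))
  }
})

test_that("a short terminal remainder borrows from the penultimate fragment", {
  params <- design_parameters()
  found <- FALSE
  for (seed in 1:60) {
    g <- random_gene(600 + seed * 7, gc = 0.5, seed = seed)
    fr <- partition_gene(g, 58, params)
    n <- nrow(fr)
    if (n < 3) next
    shared <- fr$end[n - 1L] - fr$start[n] + 1L
    if (shared == fr$overlap_len[n - 1L]) next  # no borrowing here
    found <- TRUE
    # borrowed junction: the last fragment starts remainder_min nt
    # deeper into the penultimate fragment than the reported overlap
    expect_identical(shared, fr$overlap_len[n - 1L] + params$remainder_min)
    # the reported overlap is a prefix of the last fragment...
    expect_identical(substr(fr$seq[n], 1L, fr$overlap_len[n - 1L]),
                     fr$overlap_seq[n - 1L])
    # ...and sits exactly remainder_min nt before the penultimate 3' end
    tail_start <- fr$length[n - 1L] - params$remainder_min -
      fr$overlap_len[n - 1L] + 1L
    expect_identical(
      substr(fr$seq[n - 1L], tail_start,
             fr$length[n - 1L] - params$remainder_min),
      fr$overlap_seq[n - 1L]
    )
    # the pre-borrow remainder really was short, and no tiny fragment exists
    expect_lt(g$length - fr$end[n - 1L], params$remainder_min)
    expect_true(all(fr$length >= params$overlap_len_min))
    # partition is still lossless
    expect_identical(oracle_reconstruct(fr, g$length), g$seq)
    break
  }
  expect_true(found)
})

test_that("gene primers are the brute-force Tm-closest prefix and suffix", {
  params <- design_parameters()
  for (seed in c(21, 22, 23)) {
    g <- random_gene(1000, gc = 0.5, seed = seed)
    target <- 57.3
    pr <- design_gene_primers(g, target, params)
    ks <- params$overlap_len_min:params$overlap_len_max
    pre_dev <- vapply(ks, function(k) {
      abs(melting_temperature(substr(g$seq, 1, k)) - target)
    }, numeric(1))
    suf_dev <- vapply(ks, function(k) {
      abs(melting_temperature(substr(g$seq, g$length - k + 1, g$length)) - target)
    }, numeric(1))
    expect_identical(nchar(pr$sense), ks[which.min(pre_dev)])
    expect_identical(nchar(pr$antisense), ks[which.min(suf_dev)])
    # structural invariants
    expect_identical(pr$sense, substr(g$seq, 1, nchar(pr$sense)))
    expect_identical(
      reverse_complement(pr$antisense),
      substr(g$seq, g$length - nchar(pr$antisense) + 1, g$length)
    )
    # determinism
    expect_identical(pr, design_gene_primers(g, target, params))
  }
  expect_error(design_gene_primers(random_gene(60, seed = 1), 58, params),
               "too short")
})

test_that("screening a single candidate temperature equals a direct partition", {
  g <- random_gene(700, seed = 31)
  params <- design_parameters(tm_screen_min = 58, tm_screen_max = 59)
  d <- screen_tm_settings(g, params)
  expect_identical(d$tm_set, 58L)
  expect_identical(d$fragments, partition_gene(g, 58, params))
})

test_that("screening picks the candidate minimizing the max Tm deviation", {
  params <- design_parameters()
  for (seed in c(41, 42)) {
    g <- random_gene(800, gc = 0.5, seed = seed)
    d <- screen_tm_settings(g, params)
    oracle <- oracle_best_tm_set(g, params)
    expect_identical(d$tm_set, oracle$tm_set)
    expect_equal(d$tm_dev_max, oracle$dev_max, tolerance = 1e-9)
    # reported statistics match the fragment table
    tms <- d$fragments$overlap_tm[!is.na(d$fragments$overlap_tm)]
    expect_equal(d$tm_mean, mean(tms), tolerance = 1e-12)
    expect_equal(d$tm_dev_max, max(abs(tms - d$tm_mean)), tolerance = 1e-12)
    # gene primers are tuned to the winning design's mean overlap Tm
    expect_identical(d$primers$tm_target, d$tm_mean)
    expect_equal(
      d$primer_dev_max,
      max(abs(c(d$primers$tm_sense, d$primers$tm_antisense) - d$tm_mean)),
      tolerance = 1e-12
    )
  }
})
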