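#' Design parameters for fragment partitioning
#'
#' Bundles every tunable of the design pipeline. Defaults reflect
#' common synthesis practice: 59-nt fragments (a good price/quality
#' point for column-synthesized oligos), candidate annealing
#' temperatures screened over the half-open range \[54, 69) degrees
#' Celsius, junction overlap lengths searched in \[15, 35\] nt, a
#' 20-nt minimum terminal remainder before borrowing from the
#' penultimate fragment, and at most 9 fragments per assembly block.
#'
#' @param fragment_len Uniform fragment length in nt.
#' @param tm_screen_min,tm_screen_max Integer bounds (degrees Celsius)
#'   of the half-open screened range of candidate annealing
#'   temperatures: `tm_screen_min, tm_screen_min + 1, ...,
#'   tm_screen_max - 1`.
#' @param remainder_min Minimum length (nt) of the terminal remainder;
#'   below this, `remainder_min` nt are borrowed from the 3' end of
#'   the penultimate fragment and the final overlap is re-selected.
#' @param overlap_len_min,overlap_len_max Search bounds (nt) for the
#'   junction-overlap length.
#' @param max_block_size Maximum fragments per assembly block.
#' @param tm_par Melting-temperature conditions, see [tm_parameters].
#' @return A list of class `design_parameters`.
#' @export
design_parameters <- function(fragment_len = 59L,
                              tm_screen_min = 54L,
                              tm_screen_max = 69L,
                              remainder_min = 20L,
                              overlap_len_min = 15L,
                              overlap_len_max = 35L,
                              max_block_size = 9L,
                              tm_par = tm_parameters()) {
  p <- list(
    fragment_len = as.integer(fragment_len),
    tm_screen_min = as.integer(tm_screen_min),
    tm_screen_max = as.integer(tm_screen_max),
    remainder_min = as.integer(remainder_min),
    overlap_len_min = as.integer(overlap_len_min),
    overlap_len_max = as.integer(overlap_len_max),
    max_block_size = as.integer(max_block_size),
    tm_par = tm_par
  )
  if (p$overlap_len_min < tm_par$min_len) {
    stop("overlap_len_min must be >= the minimum duplex length (",
         tm_par$min_len, " nt)", call. = FALSE)
  }
  if (p$overlap_len_min > p$overlap_len_max) {
    stop("overlap_len_min must be <= overlap_len_max", call. = FALSE)
  }
  if (p$overlap_len_max >= p$fragment_len) {
    stop("overlap_len_max must be smaller than fragment_len", call. = FALSE)
  }
  if (p$tm_screen_min >= p$tm_screen_max) {
    stop("tm_screen_min must be < tm_screen_max", call. = FALSE)
  }
  if (p$fragment_len <= p$remainder_min) {
    stop("fragment_len must exceed remainder_min", call. = FALSE)
  }
  if (p$max_block_size < 1L) {
    stop("max_block_size must be >= 1", call. = FALSE)
  }
  structure(p, class = "design_parameters")
}

#' Select the Tm-matched junction overlap from a 3' context
#'
#' Examines every suffix of `context` with length in
#' `[overlap_len_min, overlap_len_max]` and returns the one whose
#' melting temperature is closest to `tm_target`. Ties are broken
#' toward the shorter suffix (cheaper to synthesize, same Tm fit).
#'
#' @param context Sense-strand sequence whose 3' end provides the
#'   candidate overlaps; must be at least `overlap_len_max` nt.
#' @param tm_target Target annealing temperature in degrees Celsius.
#' @param params A [design_parameters] object.
#' @return A list of class `overlap_junction` with fields `seq`,
#'   `length`, `tm` and `tm_target`.
#' @export
select_overlap <- function(context, tm_target, params = design_parameters()) {
  stopifnot(inherits(params, "design_parameters"))
  n <- nchar(context)
  if (n < params$overlap_len_max) {
    stop("context (", n, " nt) is shorter than overlap_len_max (",
         params$overlap_len_max, " nt)", call. = FALSE)
  }
  tms <- .suffix_tms(context, params$overlap_len_min, params$overlap_len_max,
                     params$tm_par)
  dev <- abs(tms - tm_target)
  # which.min returns the first (= shortest suffix) among exact ties
  best <- unname(which.min(dev))
  k <- params$overlap_len_min + best - 1L
  structure(
    list(
      seq = substr(context, n - k + 1L, n),
      length = k,
      tm = unname(tms[best]),
      tm_target = tm_target
    ),
    class = "overlap_junction"
  )
}

#' Partition a gene into Tm-matched overlapping fragments
#'
#' Implements the greedy 5'-to-3' partition: the first fragment is the
#' first `fragment_len` nt of the gene; at each junction the overlap
#' is the suffix of the current fragment whose Tm is closest to
#' `tm_set` (see [select_overlap]); the next fragment starts at the 5'
#' end of that overlap and again spans `fragment_len` nt. When the
#' prospective last fragment (overlap + remainder) would be shorter
#' than `fragment_len`, it simply becomes that shorter fragment --
#' unless the remainder is below `remainder_min` nt, in which case
#' `remainder_min` nt are borrowed from the 3' end of the penultimate
#' fragment, the overlap is re-selected on the sequence immediately 5'
#' of the extended remainder, and the last fragment is overlap +
#' borrowed bases + remainder. At such a borrowed junction the
#' reported overlap is a prefix of the last fragment but sits
#' `remainder_min` nt short of the penultimate fragment's 3' end; the
#' physically shared terminal region is correspondingly longer.
#'
#' A gene no longer than `fragment_len` yields a single fragment with
#' no junction (genes under ~100 nt are more cheaply made as two
#' annealed complementary strands; a warning says so).
#'
#' @param gene A [gene_sequence].
#' @param tm_set Target annealing temperature (degrees Celsius) for
#'   every junction overlap.
#' @param params A [design_parameters] object.
#' @return A data.frame with one row per fragment and columns `index`,
#'   `seq` (sense strand), `start`, `end` (1-based inclusive gene
#'   coordinates), `length`, `overlap_seq`, `overlap_len`,
#'   `overlap_tm` (the junction to the *next* fragment; NA on the last
#'   row).
#' @export
partition_gene <- function(gene, tm_set, params = design_parameters()) {
  stopifnot(inherits(gene, "gene_sequence"), inherits(params, "design_parameters"))
  G <- gene$length
  FL <- params$fragment_len
  if (G < params$overlap_len_max) {
    stop("gene (", G, " nt) is shorter than overlap_len_max (",
         params$overlap_len_max, " nt); nothing to design", call. = FALSE)
  }
  if (G <= FL) {
    if (G < 100L) {
      warning("gene is only ", G, " nt; genes under ~100 nt are usually ",
              "synthesized directly as two annealed complementary strands",
              call. = FALSE)
    }
    return(data.frame(
      index = 1L, seq = gene$seq, start = 1L, end = G, length = G,
      overlap_seq = NA_character_, overlap_len = NA_integer_,
      overlap_tm = NA_real_, stringsAsFactors = FALSE
    ))
  }

  starts <- 1L
  ends <- FL
  ov_seq <- character(0)
  ov_len <- integer(0)
  ov_tm <- numeric(0)

  repeat {
    e <- ends[length(ends)]
    r <- G - e                             # remainder after current fragment
    if (r == 0L) break
    frag <- substr(gene$seq, starts[length(starts)], e)
    ov <- select_overlap(frag, tm_set, params)
    if (ov$length + r >= FL) {
      # interior fragment: full length, starts at the overlap's 5' end
      s_next <- e - ov$length + 1L
      starts <- c(starts, s_next)
      ends <- c(ends, s_next + FL - 1L)
    } else if (r >= params$remainder_min) {
      # terminal fragment: overlap + remainder, shorter than fragment_len
      starts <- c(starts, e - ov$length + 1L)
      ends <- c(ends, G)
    } else {
      # remainder too short: borrow remainder_min nt from the 3' end of
      # the penultimate fragment and re-select the overlap on the
      # sequence 5' of the extended remainder
      b <- params$remainder_min
      ctx <- substr(gene$seq, starts[length(starts)], e - b)
      ov <- select_overlap(ctx, tm_set, params)
      starts <- c(starts, e - b - ov$length + 1L)
      ends <- c(ends, G)
    }
    ov_seq <- c(ov_seq, ov$seq)
    ov_len <- c(ov_len, ov$length)
    ov_tm <- c(ov_tm, ov$tm)
    if (ends[length(ends)] == G) break
  }

  n <- length(starts)
  data.frame(
    index = seq_len(n),
    seq = substring(gene$seq, starts, ends),
    start = starts,
    end = ends,
    length = ends - starts + 1L,
    overlap_seq = c(ov_seq, NA_character_),
    overlap_len = c(ov_len, NA_integer_),
    overlap_tm = c(ov_tm, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Design full-length gene primers
#'
#' The sense primer is the gene prefix and the antisense primer the
#' reverse complement of the gene suffix whose melting temperatures
#' are closest to `tm_target`, searched over the same length range as
#' junction overlaps; ties go to the shorter primer.
#'
#' @param gene A [gene_sequence].
#' @param tm_target Target Tm in degrees Celsius (typically the mean
#'   junction Tm of the accepted design).
#' @param params A [design_parameters] object.
#' @return A list of class `gene_primers` with fields `sense`,
#'   `antisense`, `tm_sense`, `tm_antisense`, `tm_target`.
#' @export
design_gene_primers <- function(gene, tm_target, params = design_parameters()) {
  stopifnot(inherits(gene, "gene_sequence"), inherits(params, "design_parameters"))
  if (gene$length < 2L * params$overlap_len_max) {
    stop("gene (", gene$length, " nt) is too short for primer design ",
         "(needs >= 2 * overlap_len_max = ", 2L * params$overlap_len_max,
         " nt)", call. = FALSE)
  }
  pre <- .prefix_tms(gene$seq, params$overlap_len_min, params$overlap_len_max,
                     params$tm_par)
  i <- unname(which.min(abs(pre - tm_target)))
  k5 <- params$overlap_len_min + i - 1L
  suf <- .suffix_tms(gene$seq, params$overlap_len_min, params$overlap_len_max,
                     params$tm_par)
  j <- unname(which.min(abs(suf - tm_target)))
  k3 <- params$overlap_len_min + j - 1L
  sense <- substr(gene$seq, 1L, k5)
  tail3 <- substr(gene$seq, gene$length - k3 + 1L, gene$length)
  structure(
    list(
      sense = sense,
      antisense = reverse_complement(tail3),
      tm_sense = unname(pre[i]),
      tm_antisense = unname(suf[j]),
      tm_target = tm_target
    ),
    class = "gene_primers"
  )
}

#' Screen candidate annealing temperatures and return the best design
#'
#' Runs [partition_gene] at every integer candidate temperature in the
#' half-open range `[tm_screen_min, tm_screen_max)` and keeps the
#' design whose junction Tm values cluster most tightly: the one
#' minimizing the maximum absolute deviation from the design's own
#' mean junction Tm (`tm_dev_max`). Ties go to the lowest candidate
#' temperature. Gene primers are then designed against the winning
#' design's mean junction Tm, so every ordered oligo anneals near one
#' common temperature.
#'
#' @param gene A [gene_sequence].
#' @param params A [design_parameters] object.
#' @return An object of class `gene_design`: a list with `gene`,
#'   `params`, `tm_set` (winning candidate), `fragments` (see
#'   [partition_gene]), `primers` (see [design_gene_primers]),
#'   `tm_mean`, `tm_dev_max` and `primer_dev_max`.
#' @export
screen_tm_settings <- function(gene, params = design_parameters()) {
  stopifnot(inherits(gene, "gene_sequence"), inherits(params, "design_parameters"))
  candidates <- params$tm_screen_min:(params$tm_screen_max - 1L)
  best <- NULL
  for (tm_set in candidates) {
    fr <- partition_gene(gene, tm_set, params)
    tms <- fr$overlap_tm[!is.na(fr$overlap_tm)]
    if (length(tms) == 0L) {
      dev_max <- 0
      tm_mean <- NA_real_
    } else {
      tm_mean <- mean(tms)
      dev_max <- max(abs(tms - tm_mean))
    }
    if (is.null(best) || dev_max < best$tm_dev_max) {
      best <- list(tm_set = tm_set, fragments = fr,
                   tm_mean = tm_mean, tm_dev_max = dev_max)
    }
  }
  primer_target <- if (is.na(best$tm_mean)) {
    mean(c(params$tm_screen_min, params$tm_screen_max - 1L))
  } else {
    best$tm_mean
  }
  primers <- design_gene_primers(gene, primer_target, params)
  primer_dev_max <- max(abs(c(primers$tm_sense, primers$tm_antisense) -
                            primer_target))
  structure(
    list(
      gene = gene,
      params = params,
      tm_set = best$tm_set,
      fragments = best$fragments,
      primers = primers,
      tm_mean = best$tm_mean,
      tm_dev_max = best$tm_dev_max,
      primer_dev_max = primer_dev_max
    ),
    class = "gene_design"
  )
}

#' @export
print.gene_design <- function(x, ...) {
  n <- nrow(x$fragments)
  cat(sprintf("<gene_design> %s (%d nt)\n", x$gene$id, x$gene$length))
  cat(sprintf("  fragments: %d (set length %d nt)\n", n, x$params$fragment_len))
  cat(sprintf("  chosen Tm_set: %d C\n", x$tm_set))
  if (!is.na(x$tm_mean)) {
    cat(sprintf("  overlap Tm: mean %.2f C, max |Tm - Tm_mean| %.2f C\n",
                x$tm_mean, x$tm_dev_max))
  }
  cat(sprintf("  gene primers: %s / %s (Tm %.2f / %.2f C, max dev %.2f C)\n",
              x$primers$sense, x$primers$antisense,
              x$primers$tm_sense, x$primers$tm_antisense, x$primer_dev_max))
  invisible(x)
}

# Stitch fragments back together by coordinates: append, from each
# subsequent fragment, only the part past the region shared with the
# previous fragment. Used by validity checks and file round-trips.
.stitch_fragments <- function(fragments) {
  out <- fragments$seq[1L]
  if (nrow(fragments) > 1L) {
    for (i in 2L:nrow(fragments)) {
      shared <- fragments$end[i - 1L] - fragments$start[i] + 1L
      out <- paste0(out, substr(fragments$seq[i], shared + 1L,
                                nchar(fragments$seq[i])))
    }
  }
  out
}
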