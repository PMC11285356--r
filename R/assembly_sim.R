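# In-silico overlap-extension assembly.
#
# Verification model, not a kinetic model: fragments bridge through
# exact terminal sequence identity of at least `min_overlap` nt.
# Because every fragment becomes double-stranded during PCR, each
# oligo may enter the reaction on either strand; the simulator
# therefore tries both orientations of both partners at every merge
# and treats multiple distinct products as predicted mis-assembly.

# canonical strand-insensitive form of a duplex
.canonical_duplex <- function(seq) {
  rc <- reverse_complement(seq)
  if (seq <= rc) seq else rc
}

# longest t in [min_t, min(nchar)] with suffix_t(x) == prefix_t(y); 0 if none
.max_overlap <- function(x, y, min_t) {
  nx <- nchar(x)
  ny <- nchar(y)
  hi <- min(nx, ny)
  if (hi < min_t) return(0L)
  for (t in seq(from = hi, to = min_t, by = -1L)) {
    if (substr(x, nx - t + 1L, nx) == substr(y, 1L, t)) return(t)
  }
  0L
}

# Merge two double-stranded fragments through a bridging overlap.
# Returns list(seq, overlap_len) or a character diagnostic on failure.
.merge_duplexes <- function(x, y, min_t) {
  xs <- c(x, reverse_complement(x))
  ys <- c(y, reverse_complement(y))
  hits <- list()
  for (xi in 1:2) {
    for (yi in 1:2) {
      t <- .max_overlap(xs[xi], ys[yi], min_t)
      if (t > 0L) {
        merged <- paste0(xs[xi], substr(ys[yi], t + 1L, nchar(ys[yi])))
        hits[[length(hits) + 1L]] <- list(seq = merged, overlap_len = t)
      }
    }
  }
  if (length(hits) == 0L) {
    return("no bridging overlap of sufficient length between neighbors")
  }
  canon <- vapply(hits, function(h) .canonical_duplex(h$seq), character(1))
  if (length(unique(canon)) > 1L) {
    return("ambiguous bridging: neighbors can join into more than one product")
  }
  hits[[1L]]
}

#' Simulate overlap-extension assembly of an ordered oligo set
#'
#' Verifies a design by reconstructing the full-length gene from its
#' ordered fragments purely through exact overlap bridging. Any oligo
#' may be supplied on either strand (PCR makes each one
#' double-stranded, so strand choice cannot affect assemblability).
#' `"linear"` mode mimics all-sense assembly: the antisense gene
#' primer first copies the last fragment (one cycle), then each
#' further cycle extends the growing product by one more fragment,
#' right to left. `"pairwise"` mode mimics alternating-strand
#' assembly: every disjoint adjacent pair merges within the same
#' cycle, halving the fragment count per round.
#'
#' Failure (missing or ambiguous bridging, or gene primers that do not
#' match the final product's ends) is reported in the outcome, never
#' thrown.
#'
#' @param oligos Character vector of oligo sequences in gene order, or
#'   a data.frame with a `seq` column (e.g. from [ordered_oligos]).
#' @param primers A `gene_primers` object (see [design_gene_primers]).
#' @param mode `"linear"` or `"pairwise"`.
#' @param min_overlap Minimum exact overlap (nt) accepted as a bridge;
#'   use the design's `overlap_len_min`.
#' @return A list of class `assembly_outcome`: `success` (logical),
#'   `assembled_seq` (sense-oriented product, or NA on failure),
#'   `rounds_used` (integer PCR cycles), `junction_log` (data.frame
#'   `left_index`, `right_index`, `overlap_len`) and `message`.
#' @export
simulate_assembly <- function(oligos, primers,
                              mode = c("linear", "pairwise"),
                              min_overlap = 15L) {
  mode <- match.arg(mode)
  if (is.data.frame(oligos)) oligos <- oligos$seq
  stopifnot(is.character(oligos), length(oligos) >= 1L,
            inherits(primers, "gene_primers"))
  min_overlap <- as.integer(min_overlap)

  fail <- function(msg, rounds) {
    structure(
      list(success = FALSE, assembled_seq = NA_character_,
           rounds_used = rounds,
           junction_log = data.frame(left_index = integer(0),
                                     right_index = integer(0),
                                     overlap_len = integer(0)),
           message = msg),
      class = "assembly_outcome"
    )
  }

  n <- length(oligos)
  # working items: seq + the span of original oligo indices it covers
  items <- lapply(seq_len(n), function(i) list(seq = oligos[i], lo = i, hi = i))
  log_l <- integer(0); log_r <- integer(0); log_t <- integer(0)
  rounds <- 0L

  if (mode == "linear" && n > 1L) {
    rounds <- 1L  # antisense gene primer copies the last fragment
    acc <- items[[n]]
    for (i in seq(n - 1L, 1L)) {
      m <- .merge_duplexes(items[[i]]$seq, acc$seq, min_overlap)
      if (is.character(m)) {
        return(fail(sprintf("%s (between fragments %d and %d)", m, i, i + 1L),
                    rounds))
      }
      log_l <- c(i, log_l); log_r <- c(i + 1L, log_r); log_t <- c(m$overlap_len, log_t)
      acc <- list(seq = m$seq, lo = i, hi = acc$hi)
      rounds <- rounds + 1L
    }
    items <- list(acc)
  } else if (mode == "pairwise") {
    while (length(items) > 1L) {
      rounds <- rounds + 1L
      nxt <- list()
      i <- 1L
      while (i <= length(items)) {
        if (i + 1L <= length(items)) {
          a <- items[[i]]; b <- items[[i + 1L]]
          m <- .merge_duplexes(a$seq, b$seq, min_overlap)
          if (is.character(m)) {
            return(fail(sprintf("%s (between fragments %d and %d)",
                                m, a$hi, b$lo), rounds))
          }
          log_l <- c(log_l, a$hi); log_r <- c(log_r, b$lo)
          log_t <- c(log_t, m$overlap_len)
          nxt[[length(nxt) + 1L]] <- list(seq = m$seq, lo = a$lo, hi = b$hi)
          i <- i + 2L
        } else {
          nxt[[length(nxt) + 1L]] <- items[[i]]
          i <- i + 1L
        }
      }
      items <- nxt
    }
  }

  final <- items[[1L]]$seq
  # orient the product so the sense gene primer reads from its 5' end
  candidates <- c(final, reverse_complement(final))
  ok <- vapply(candidates, function(s) {
    startsWith(s, primers$sense) &&
      endsWith(s, reverse_complement(primers$antisense))
  }, logical(1), USE.NAMES = FALSE)
  if (!any(ok)) {
    return(fail("gene primers do not match the ends of the assembled product",
                rounds))
  }
  structure(
    list(success = TRUE, assembled_seq = candidates[which(ok)[1L]],
         rounds_used = rounds,
         junction_log = data.frame(left_index = log_l, right_index = log_r,
                                   overlap_len = log_t),
         message = "full-length gene assembled"),
    class = "assembly_outcome"
  )
}

#' @export
print.assembly_outcome <- function(x, ...) {
  cat(sprintf("<assembly_outcome> %s after %d round(s): %s\n",
              if (x$success) "SUCCESS" else "FAILURE",
              x$rounds_used, x$message))
  invisible(x)
}

#' Verify a design by simulating both assembly methods
#'
#' Runs [simulate_assembly] on the all-sense oligo set (linear mode)
#' and on the alternating sense/antisense set (pairwise mode) and
#' checks that both reconstruct the input gene exactly.
#'
#' @param design A `gene_design` from [screen_tm_settings].
#' @return A list with elements `method_a`, `method_b` (the two
#'   `assembly_outcome`s) and `ok` (TRUE iff both products equal the
#'   gene sequence).
#' @export
verify_design <- function(design) {
  stopifnot(inherits(design, "gene_design"))
  min_ov <- design$params$overlap_len_min
  a <- simulate_assembly(ordered_oligos(design$fragments, "A"),
                         design$primers, mode = "linear",
                         min_overlap = min_ov)
  b <- simulate_assembly(ordered_oligos(design$fragments, "B"),
                         design$primers, mode = "pairwise",
                         min_overlap = min_ov)
  ok <- isTRUE(a$success) && isTRUE(b$success) &&
    identical(a$assembled_seq, design$gene$seq) &&
    identical(b$assembled_seq, design$gene$seq)
  list(method_a = a, method_b = b, ok = ok)
}
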