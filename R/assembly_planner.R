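#' Convert a fragment set to alternating sense/antisense oligos
#'
#' Assembly method A orders every fragment as its sense strand; method
#' B orders odd-indexed fragments as sense and even-indexed fragments
#' as antisense (their reverse complements), which lets neighboring
#' pairs prime each other so that each PCR cycle can merge every
#' adjacent pair at once. Overlap metadata is not carried here; it
#' stays on the sense-strand fragment table.
#'
#' @param fragments Fragment table from [partition_gene] (or the
#'   `fragments` element of a `gene_design`).
#' @param method `"A"` (all sense) or `"B"` (alternating).
#' @return A data.frame with columns `index`, `seq` (as ordered from
#'   the vendor), `strand` (`"sense"`/`"antisense"`) and `method`.
#' @export
ordered_oligos <- function(fragments, method = c("B", "A")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(fragments), nrow(fragments) >= 1L)
  strand <- rep("sense", nrow(fragments))
  seq <- fragments$seq
  if (method == "B") {
    even <- which(fragments$index %% 2L == 0L)
    strand[even] <- "antisense"
    seq[even] <- reverse_complement(seq[even])
  }
  data.frame(
    index = fragments$index, seq = seq, strand = strand,
    method = method, stringsAsFactors = FALSE
  )
}

#' @rdname ordered_oligos
#' @export
to_method_b <- function(fragments) ordered_oligos(fragments, method = "B")

#' Partition fragments into balanced assembly blocks
#'
#' Splits `n_fragments` consecutive fragments into the fewest blocks
#' of at most `max_block_size` fragments each, with sizes as equal as
#' possible (differing by at most one) and smaller blocks first. For
#' example 20 fragments with at most 7 per block gives blocks of 6, 7
#' and 7; 22 gives 5, 5, 6 and 6.
#'
#' @param n_fragments Total number of fragments (>= 1).
#' @param max_block_size Maximum fragments per block (>= 1).
#' @return Integer vector of block sizes, non-decreasing, summing to
#'   `n_fragments`.
#' @examples
#' plan_blocks(20, 7)
#' plan_blocks(27, 9)
#' @export
plan_blocks <- function(n_fragments, max_block_size) {
  if (!is.numeric(n_fragments) || n_fragments < 1 ||
      n_fragments != round(n_fragments)) {
    stop("'n_fragments' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(max_block_size) || max_block_size < 1 ||
      max_block_size != round(max_block_size)) {
    stop("'max_block_size' must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n_fragments)
  m <- as.integer(max_block_size)
  k <- as.integer(ceiling(n / m))
  base <- n %/% k
  extra <- n %% k
  c(rep(base, k - extra), rep(base + 1L, extra))
}

#' Derive block primer pairs for a design
#'
#' Each block is PCR-amplified from its constituent fragments with one
#' forward and one reverse primer. The first block's forward primer is
#' the sense gene primer and the last block's reverse primer is the
#' antisense gene primer; every interior boundary re-uses the junction
#' overlap that the two neighboring blocks share: the sense overlap
#' sequence of the previous block's last fragment is the next block's
#' forward primer, and its reverse complement is the previous block's
#' reverse primer. Block primers therefore inherit the design's
#' Tm-matched overlaps and are not re-optimized.
#'
#' @param design A `gene_design` from [screen_tm_settings].
#' @param block_sizes Integer vector of block sizes (default
#'   [plan_blocks] on the design); must sum to the fragment count.
#' @return A data.frame of class `block_plan` with columns `block`,
#'   `first`, `last` (fragment indices), `n_fragments`, `fwd_primer`,
#'   `rev_primer`, `fwd_tm`, `rev_tm`, `amplicon_len`.
#' @export
derive_block_primers <- function(design,
                                 block_sizes = plan_blocks(
                                   nrow(design$fragments),
                                   design$params$max_block_size)) {
  stopifnot(inherits(design, "gene_design"))
  fr <- design$fragments
  n <- nrow(fr)
  block_sizes <- as.integer(block_sizes)
  if (sum(block_sizes) != n) {
    stop("block sizes (sum ", sum(block_sizes),
         ") do not cover the ", n, " fragments", call. = FALSE)
  }
  k <- length(block_sizes)
  last <- cumsum(block_sizes)
  first <- c(1L, utils::head(last, -1L) + 1L)
  fwd <- rev <- character(k)
  for (b in seq_len(k)) {
    fwd[b] <- if (b == 1L) design$primers$sense else fr$overlap_seq[last[b - 1L]]
    rev[b] <- if (b == k) design$primers$antisense else
      reverse_complement(fr$overlap_seq[last[b]])
  }
  tm_par <- design$params$tm_par
  out <- data.frame(
    block = seq_len(k),
    first = first,
    last = last,
    n_fragments = block_sizes,
    fwd_primer = fwd,
    rev_primer = rev,
    fwd_tm = melting_temperature(fwd, tm_par),
    rev_tm = melting_temperature(rev, tm_par),
    amplicon_len = fr$end[last] - fr$start[first] + 1L,
    stringsAsFactors = FALSE
  )
  class(out) <- c("block_plan", class(out))
  out
}

#' Minimal PCR cycles to assemble n fragments
#'
#' Method A (all-sense) assembles linearly: the first cycle copies the
#' last fragment off the antisense gene primer and every later cycle
#' extends the growing strand by one more fragment, so `n` fragments
#' need `n` cycles. Method B (alternating strands) lets every adjacent
#' pair merge in the same cycle, halving the fragment count each
#' round, so `ceiling(log2(n))` cycles suffice. A single fragment is
#' already full length: 0 cycles either way.
#'
#' @param n_fragments Number of fragments (>= 1).
#' @param method `"A"` or `"B"`.
#' @return Integer cycle count.
#' @examples
#' minimal_cycles(27, "A")
#' minimal_cycles(8, "B")
#' @export
minimal_cycles <- function(n_fragments, method = c("A", "B")) {
  method <- match.arg(method)
  if (!is.numeric(n_fragments) || n_fragments < 1 ||
      n_fragments != round(n_fragments)) {
    stop("'n_fragments' must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n_fragments)
  if (n == 1L) return(0L)
  if (method == "A") n else as.integer(ceiling(log2(n)))
}
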