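#' Construct a validated gene sequence
#'
#' A `gene_sequence` is the package's representation of a single
#' (already codon-optimized) target gene: an identifier plus a DNA
#' sequence restricted to the unambiguous alphabet A/C/G/T. Input is
#' uppercased and whitespace-stripped before validation; ambiguity
#' codes (including N) and RNA (U) are rejected because synthesis
#' vendors take unambiguous DNA.
#'
#' @param seq Character scalar, the nucleotide sequence.
#' @param id Character scalar, free-text record identifier.
#' @return An object of class `gene_sequence` with fields `id`, `seq`
#'   (uppercase) and `length` (nucleotides).
#' @examples
#' g <- gene_sequence("acgtACGT", id = "demo")
#' g$length
#' @export
gene_sequence <- function(seq, id = "gene") {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  stopifnot(is.character(id), length(id) == 1L, !is.na(id))
  seq <- toupper(gsub("[ \t\r\n]", "", seq))
  if (nchar(seq) == 0L) {
    stop("sequence is empty after removing whitespace", call. = FALSE)
  }
  .check_acgt(seq)
  structure(
    list(id = id, seq = seq, length = nchar(seq)),
    class = "gene_sequence"
  )
}

# Validate the unambiguous DNA alphabet; report every offending
# character with its 1-based position.
.check_acgt <- function(seq) {
  bad <- gregexpr("[^ACGT]", seq)[[1L]]
  if (bad[1L] != -1L) {
    chars <- vapply(bad, function(i) substr(seq, i, i), character(1))
    msg <- paste(sprintf("position %d: '%s'", bad, chars), collapse = ", ")
    stop("invalid nucleotide(s), expected only A/C/G/T: ", msg, call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.gene_sequence <- function(x, ...) {
  shown <- if (x$length > 60L) {
    paste0(substr(x$seq, 1L, 57L), "...")
  } else {
    x$seq
  }
  cat(sprintf("<gene_sequence> %s (%d nt)\n%s\n", x$id, x$length, shown))
  invisible(x)
}

#' Read a single-record FASTA file
#'
#' Reads a FASTA file that must contain exactly one record and returns
#' it as a validated [gene_sequence]. Lowercase input is normalized to
#' uppercase; any character outside A/C/G/T is an error naming its
#' 1-based position in the record.
#'
#' @param path Path to a FASTA file.
#' @return A [gene_sequence].
#' @export
read_gene_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  recs <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(recs) == 0L) {
    stop("no FASTA records found in ", path, call. = FALSE)
  }
  if (length(recs) > 1L) {
    stop(
      "expected exactly one FASTA record in ", path,
      " but found ", length(recs), call. = FALSE
    )
  }
  id <- sub("\\s.*$", "", names(recs)[1L])
  if (is.na(id) || id == "") id <- "gene"
  gene_sequence(as.character(recs[[1L]]), id = id)
}

#' Write a gene sequence as FASTA
#'
#' @param gene A [gene_sequence].
#' @param path Output file path.
#' @param width Line width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(gene, path, width = 70L) {
  stopifnot(inherits(gene, "gene_sequence"))
  x <- Biostrings::DNAStringSet(gene$seq)
  names(x) <- gene$id
  Biostrings::writeXStringSet(x, path, width = as.integer(width))
  invisible(path)
}

#' Watson-Crick reverse complement
#'
#' @param seq Character vector of DNA sequences over A/C/G/T.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAGT")
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  vapply(seq, function(s) {
    .check_acgt(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a reproducible random gene
#'
#' Fixture generator: bases are drawn i.i.d. with P(G) = P(C) = gc/2
#' and P(A) = P(T) = (1 - gc)/2, the simplest model that exercises the
#' GC-dependent spread of overlap melting temperatures. The global RNG
#' state is left untouched.
#'
#' @param length Gene length in nucleotides (>= 1).
#' @param gc Target GC fraction in \[0, 1\].
#' @param seed Integer seed; the same seed yields the identical gene.
#' @param id Record identifier for the generated gene.
#' @return A [gene_sequence].
#' @examples
#' random_gene(100, gc = 0.5, seed = 1)
#' @export
random_gene <- function(length, gc = 0.5, seed = 1L, id = NULL) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length < 1 || length != round(length)) {
    stop("'length' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(gc) || length(gc) != 1L || is.na(gc) || gc < 0 || gc > 1) {
    stop("'gc' must be a number in [0, 1]", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  bases <- sample(
    c("A", "C", "G", "T"), size = length, replace = TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  )
  if (is.null(id)) id <- sprintf("random_gene_len%d_seed%d", length, seed)
  gene_sequence(paste(bases, collapse = ""), id = id)
}
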