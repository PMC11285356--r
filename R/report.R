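# Result writers: the three vendor-facing text tables, the overlap-Tm
# scatter plot and a machine-readable JSON export.

.fmt2 <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))

.fragment_table <- function(design, oligos) {
  fr <- design$fragments
  dev <- fr$overlap_tm - design$tm_mean
  data.frame(
    fragment_seq = oligos$seq,
    overlap_seq = ifelse(is.na(fr$overlap_seq), "", fr$overlap_seq),
    Tm = .fmt2(fr$overlap_tm),
    `Tm-Tm_mean` = .fmt2(dev),
    fragment_len = fr$length,
    overlap_len = ifelse(is.na(fr$overlap_len), "", fr$overlap_len),
    `start_pos-end_pos` = sprintf("%d-%d", fr$start, fr$end),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

#' Write the design tables of a run
#'
#' Writes the three tab-separated tables a bench scientist orders
#' from: `all_sense_fragments.txt` (every fragment on the sense
#' strand), `sense_antisense_fragments.txt` (odd fragments sense, even
#' fragments antisense) -- both with the seven columns fragment
#' sequence, sense-strand overlap sequence, overlap Tm, Tm-Tm_mean,
#' fragment_len, overlap_len and start_pos-end_pos -- and
#' `gene_primers.txt` (primer sequence, Tm, Tm-Tm_mean). Temperatures
#' are rendered to two decimals; the last fragment row has empty
#' overlap columns. A full `design.json` export is written alongside.
#'
#' @param design A `gene_design` from [screen_tm_settings].
#' @param dir Output directory, created if absent.
#' @param force Overwrite existing output files (default FALSE).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_design_tables <- function(design, dir = "gene_synthesis_results",
                                force = FALSE) {
  stopifnot(inherits(design, "gene_design"))
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  paths <- c(
    all_sense = file.path(dir, "all_sense_fragments.txt"),
    sense_antisense = file.path(dir, "sense_antisense_fragments.txt"),
    primers = file.path(dir, "gene_primers.txt"),
    json = file.path(dir, "design.json")
  )
  clash <- paths[file.exists(paths)]
  if (length(clash) > 0L && !force) {
    stop("output file(s) already exist (use force = TRUE to overwrite): ",
         paste(clash, collapse = ", "), call. = FALSE)
  }

  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  write_tsv(.fragment_table(design, ordered_oligos(design$fragments, "A")),
            paths[["all_sense"]])
  write_tsv(.fragment_table(design, ordered_oligos(design$fragments, "B")),
            paths[["sense_antisense"]])

  pr <- design$primers
  ref <- if (is.na(design$tm_mean)) pr$tm_target else design$tm_mean
  write_tsv(
    data.frame(
      primer = c("gene_5", "gene_3"),
      sequence = c(pr$sense, pr$antisense),
      Tm = .fmt2(c(pr$tm_sense, pr$tm_antisense)),
      `Tm-Tm_mean` = .fmt2(c(pr$tm_sense - ref, pr$tm_antisense - ref)),
      check.names = FALSE, stringsAsFactors = FALSE
    ),
    paths[["primers"]]
  )

  jsonlite::write_json(
    list(
      gene = list(id = design$gene$id, seq = design$gene$seq,
                  length = design$gene$length),
      parameters = unclass(design$params)[setdiff(names(design$params), "tm_par")],
      tm_model = unclass(design$params$tm_par),
      tm_set = design$tm_set,
      tm_mean = design$tm_mean,
      tm_dev_max = design$tm_dev_max,
      primer_dev_max = design$primer_dev_max,
      fragments = design$fragments,
      primers = unclass(design$primers),
      blocks = derive_block_primers(design)
    ),
    paths[["json"]],
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(paths)
}

#' Read design tables back from a results directory
#'
#' Parses the files written by [write_design_tables] back into the
#' fragment table and primer set, mainly to support round-trip checks
#' and downstream scripting.
#'
#' @param dir Directory containing the result files.
#' @return A list with `fragments` (data.frame: `index`, `seq`,
#'   `start`, `end`, `length`, `overlap_seq`, `overlap_len`, `tm`,
#'   `tm_dev`), `oligos_b` (the alternating-strand sequences) and
#'   `primers` (data.frame as written).
#' @export
read_design_tables <- function(dir) {
  read_tsv <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      colClasses = "character", stringsAsFactors = FALSE)
  }
  a <- read_tsv(file.path(dir, "all_sense_fragments.txt"))
  b <- read_tsv(file.path(dir, "sense_antisense_fragments.txt"))
  pos <- strsplit(a[["start_pos-end_pos"]], "-", fixed = TRUE)
  fragments <- data.frame(
    index = seq_len(nrow(a)),
    seq = a$fragment_seq,
    start = as.integer(vapply(pos, `[`, character(1), 1L)),
    end = as.integer(vapply(pos, `[`, character(1), 2L)),
    length = as.integer(a$fragment_len),
    overlap_seq = ifelse(a$overlap_seq == "", NA_character_, a$overlap_seq),
    overlap_len = suppressWarnings(as.integer(a$overlap_len)),
    tm = suppressWarnings(as.numeric(a$Tm)),
    tm_dev = suppressWarnings(as.numeric(a[["Tm-Tm_mean"]])),
    stringsAsFactors = FALSE
  )
  list(
    fragments = fragments,
    oligos_b = b$fragment_seq,
    primers = read_tsv(file.path(dir, "gene_primers.txt"))
  )
}

#' Scatter plot of junction melting temperatures
#'
#' One point per junction overlap (x = junction index, y = Tm in
#' degrees Celsius) with a horizontal line at the design's mean
#' junction Tm. Written straight to a PNG file, so it works on
#' headless machines.
#'
#' @param design A `gene_design` with at least one junction.
#' @param path Output PNG path.
#' @param width,height,res Device geometry passed to [grDevices::png].
#' @return `path`, invisibly.
#' @export
plot_tm_scatter <- function(design, path, width = 900, height = 600, res = 120) {
  stopifnot(inherits(design, "gene_design"))
  tms <- design$fragments$overlap_tm
  tms <- tms[!is.na(tms)]
  if (length(tms) == 0L) {
    stop("design has no junction overlaps to plot", call. = FALSE)
  }
  grDevices::png(path, width = width, height = height, res = res)
  on.exit(grDevices::dev.off())
  graphics::plot(
    seq_along(tms), tms,
    xlab = "overlap (junction index)", ylab = "Tm (°C)",
    main = sprintf("%s: overlap Tm at Tm_set = %d °C",
                   design$gene$id, design$tm_set),
    pch = 19, col = "steelblue",
    ylim = range(c(tms, design$tm_mean)) + c(-0.5, 0.5)
  )
  graphics::abline(h = design$tm_mean, col = "firebrick", lty = 2)
  graphics::legend(
    "topright", bty = "n", lty = 2, col = "firebrick",
    legend = sprintf("Tm_mean = %.2f °C", design$tm_mean)
  )
  invisible(path)
}
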