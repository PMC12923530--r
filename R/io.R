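# Plain-text interchange for the pipeline's intermediate products.  All
# writers emit canonically ordered rows and fixed number formatting so a
# given master seed reproduces byte-identical files.

#' Write fragment or repaired intervals as BED3
#'
#' @param intervals Data frame with `start`, `end` (0-based half-open).
#' @param path Output path.
#' @param chrom Chromosome/sequence name for column 1.
#' @return Invisibly, `path`.
#' @export
write_intervals_bed <- function(intervals, path, chrom = "synthetic") {
  df <- data.frame(chrom = rep(chrom, nrow(intervals)),
                   start = as.integer(intervals$start),
                   end = as.integer(intervals$end))
  df <- df[order(df$start, df$end), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read fragment intervals from BED3 (or wider BED)
#'
#' Entry point for real data: externally aligned, deduplicated fragments
#' converted to BED.  Only the first three columns are used.
#'
#' @param path BED path.
#' @return Data frame of class `RepairedIntervals` with `start`, `end`.
#' @export
read_intervals_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    out <- data.frame(start = integer(0), end = integer(0))
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    n <- vapply(fields, length, integer(1))
    if (any(n < 3L))
      stop("BED line ", which(n < 3L)[1L], ": expected at least 3 fields")
    start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
    if (anyNA(start) || anyNA(end))
      stop("BED line ", which(is.na(start) | is.na(end))[1L],
           ": non-integer coordinates")
    if (any(end <= start))
      stop("BED line ", which(end <= start)[1L], ": empty or inverted interval")
    out <- data.frame(start = start, end = end)
  }
  class(out) <- c("RepairedIntervals", "data.frame")
  out
}

#' Write a gap histogram as TSV
#'
#' Two columns, `gap` and `count`, sorted by gap.
#'
#' @param hist A [gap_distribution()] `GapHistogram`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gap_histogram_tsv <- function(hist, path) {
  stopifnot(inherits(hist, "GapHistogram"))
  g <- as.integer(names(hist$counts))
  df <- data.frame(gap = g, count = as.integer(hist$counts))
  df <- df[order(df$gap), , drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("gap\tcount", con)
  if (nrow(df))
    writeLines(sprintf("%d\t%d", df$gap, df$count), con)
  invisible(path)
}

#' Write a nick pileup as BED
#'
#' One row per nick boundary and strand: `chrom, boundary, boundary, nick
#' label, count, strand` (`+` for top-strand nicks, `-` for bottom).
#' Boundaries are inter-base indices, hence the zero-width intervals.
#'
#' @param pileup A [reconstruct_nicks()] `NickPileup`.
#' @param path Output path.
#' @param chrom Sequence name.
#' @return Invisibly, `path`.
#' @export
write_nick_pileup_bed <- function(pileup, path, chrom = "synthetic") {
  stopifnot(inherits(pileup, "NickPileup"))
  loci <- pileup$loci
  df <- rbind(
    data.frame(chrom = chrom, pos = loci$top, name = "top_nick",
               count = loci$count, strand = "+"),
    data.frame(chrom = chrom, pos = loci$bottom, name = "bottom_nick",
               count = loci$count, strand = "-"))
  df <- df[order(df$pos, df$strand), , drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(df))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", df$chrom, df$pos, df$pos,
                       df$name, df$count, df$strand), con)
  else writeLines(character(0), con)
  invisible(path)
}

#' Write a flank PFM (with information content) as TSV
#'
#' Columns: `column` (position relative to the nick boundary), `A`, `C`,
#' `G`, `T` (frequencies) and `bits` (relative-entropy information) — a
#' logo-ready matrix.
#'
#' @param pfm A [flank_pfm()].
#' @param path Output path.
#' @param background Background for [column_information()].
#' @return Invisibly, `path`.
#' @export
write_pfm_tsv <- function(pfm, path, background = rep(0.25, 4)) {
  stopifnot(inherits(pfm, "FlankPFM"))
  bits <- column_information(pfm, background)
  cols <- colnames(pfm$prob)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("column\tA\tC\tG\tT\tbits", con)
  writeLines(sprintf("%s\t%.6f\t%.6f\t%.6f\t%.6f\t%.6f", cols,
                     pfm$prob["A", ], pfm$prob["C", ], pfm$prob["G", ],
                     pfm$prob["T", ], bits), con)
  invisible(path)
}

#' Write the cartography report as JSON
#'
#' Aggregates the overhang call, recovered rule parameters, consensus and
#' geometry (plus optional coverage and plating results) into one
#' machine-readable report.
#'
#' @param report A list, typically [run_cartography()] output.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  keep <- list(
    genome = list(id = report$genome$id, length = nchar(report$genome$seq),
                  n_modified = nrow(report$genome$mods)),
    n_cuts = nrow(report$digest$cuts),
    n_fragments = nrow(report$digest$fragments),
    overhang = list(length = report$call$length,
                    polarity = report$call$polarity,
                    support = report$call$support),
    nicks = list(n_loci = nrow(report$pileup$loci),
                 flagged = report$pileup$flagged),
    consensus = report$consensus$consensus,
    rule_estimate = list(u = report$params$u, v = report$params$v,
                         s = report$params$s),
    geometry = list(spacing_bp = report$geometry$spacing_bp,
                    rise_per_bp = report$geometry$rise_per_bp,
                    span_angstrom = report$geometry$span_angstrom))
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
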