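mod_lookup <- function(genome, strand) {
  m <- genome$mods[genome$mods$strand == strand, , drop = FALSE]
  setNames(m$mod, as.character(m$pos))
}

#' Scan a genome for bipartite recognition sites
#'
#' Finds all and only the top-strand positions `p` with a top-strand `C` at
#' `p`, a top-strand `G` at `p + s` (i.e. a bottom-strand cytosine), and
#' both strand-wise cytosines carrying a modification class in
#' `rule$required_classes`.  Both half-sites are required: singly modified
#' constructs and genomes carrying only non-cleavable classes (`C`, `m5C`)
#' yield no sites.  Windows extending past either genome end are never
#' reported.
#'
#' @param genome A [modified_genome()].
#' @param rule A [recognition_rule()].
#' @return Data frame of class `RecognitionSites`, sorted by `p`, with
#'   columns `p` (0-based top-strand coordinate of the upstream modified
#'   C), `class_top`, `class_bottom`.
#' @examples
#' g <- modified_genome(paste0("C", strrep("A", 20), "G"))
#' g <- apply_modification_scheme(g, modification_scheme("all"))
#' find_recognition_sites(g, recognition_rule())$p  # one site at p = 0
#' @export
find_recognition_sites <- function(genome, rule) {
  stopifnot(inherits(genome, "ModifiedGenome"),
            inherits(rule, "RecognitionRule"))
  L <- genome_length(genome)
  s <- strsplit(genome$seq, "", fixed = TRUE)[[1L]]
  p <- which(s == "C") - 1L                       # candidate upstream C
  p <- p[p + rule$s <= L - 1L]                    # full window in genome
  p <- p[s[p + rule$s + 1L] == "G"]               # distal G / bottom C
  top_mod <- mod_lookup(genome, "top")
  bot_mod <- mod_lookup(genome, "bottom")
  ct <- unname(top_mod[as.character(p)])
  cb <- unname(bot_mod[as.character(p + rule$s)])
  ok <- !is.na(ct) & !is.na(cb) &
    ct %in% rule$required_classes & cb %in% rule$required_classes
  out <- data.frame(p = p[ok], class_top = ct[ok], class_bottom = cb[ok],
                    stringsAsFactors = FALSE)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("RecognitionSites", "data.frame")
  out
}

#' Nick boundaries of a recognition site
#'
#' Converts site positions into dual-strand cut coordinates.  Boundaries
#' are 0-based inter-base indices: boundary `b` lies between base `b - 1`
#' and base `b`.  The top strand is nicked at `p + u + 1` and the bottom
#' strand at `p + v + 1`; their difference is the signed overhang
#' `o = u - v` (positive: 3' overhang).  With the default `CN11/N9G` rule
#' and `p = 0` the cut is `(top 12, bottom 10)`.
#'
#' @param sites A `RecognitionSites` data frame (or any data frame with a
#'   `p` column).
#' @param rule The generating [recognition_rule()].
#' @param genome_length If supplied, sites whose nick boundaries fall
#'   outside `[0, genome_length]` are rejected (dropped).
#' @return Data frame of class `DuplexCuts` with columns `p`, `top_nick`,
#'   `bottom_nick`.
#' @export
cut_positions <- function(sites, rule, genome_length = NULL) {
  p <- as.integer(sites$p)
  top <- p + rule$u + 1L
  bottom <- p + rule$v + 1L
  out <- data.frame(p = p, top_nick = top, bottom_nick = bottom)
  if (!is.null(genome_length)) {
    keep <- pmin(top, bottom) >= 0L & pmax(top, bottom) <= genome_length
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("DuplexCuts", "data.frame")
  out
}

#' Simulate digestion of a modified genome
#'
#' Scans for recognition sites, cuts each independently with probability
#' equal to the minimum of its two half-site class efficiencies, resolves
#' overlaps greedily left-to-right (an accepted cut suppresses any later
#' cut whose top nick lies closer than `|overhang| + 1` bp, which
#' guarantees every fragment keeps a positive-length duplex core), and
#' returns the resulting fragments.  `k` accepted cuts on a linear genome
#' yield `k + 1` fragments; genome-end termini are blunt and every internal
#' end carries the rule's overhang chemistry.
#'
#' Fragments record each strand's extent separately (`top_start`,
#' `top_end`, `bottom_start`, `bottom_end`, all 0-based half-open
#' boundaries), from which end chemistry follows: at a 3' overhang the
#' protruding strand extends `|o|` bases past the duplex core.
#'
#' @param genome A [modified_genome()].
#' @param rule A [recognition_rule()].
#' @param seed Integer master seed; site acceptance uses the `"digest"`
#'   stage stream.
#' @return An object of class `DigestResult`: list with `fragments` (data
#'   frame with per-strand extents and `left_end` / `right_end` chemistry,
#'   each `"blunt"`, `"3prime"` or `"5prime"`), `cuts` (the accepted
#'   `DuplexCuts` — simulation ground truth), `rule`, `genome_id`, `L`.
#' @examples
#' g <- modified_genome(paste0(strrep("T", 8), "C", strrep("A", 20), "G",
#'                             strrep("T", 8)))
#' g <- apply_modification_scheme(g, modification_scheme("all"))
#' simulate_digest(g, recognition_rule(), seed = 1)$fragments
#' @export
simulate_digest <- function(genome, rule, seed = 1L) {
  stopifnot(inherits(genome, "ModifiedGenome"),
            inherits(rule, "RecognitionRule"))
  L <- genome_length(genome)
  sites <- find_recognition_sites(genome, rule)
  eff <- pmin(rule$efficiency[sites$class_top],
              rule$efficiency[sites$class_bottom])
  hit <- if (nrow(sites) == 0L) logical(0) else {
    with_stage_seed(seed, "digest", runif(nrow(sites)) < eff)
  }
  cuts <- cut_positions(sites[hit, , drop = FALSE], rule, genome_length = L)
  # greedy left-to-right overlap resolution on top-nick distance
  min_gap <- abs(rule$overhang) + 1L
  keep <- logical(nrow(cuts))
  last <- -Inf
  for (i in seq_len(nrow(cuts))) {
    if (cuts$top_nick[i] - last >= min_gap) {
      keep[i] <- TRUE
      last <- cuts$top_nick[i]
    }
  }
  cuts <- cuts[keep, , drop = FALSE]
  rownames(cuts) <- NULL

  k <- nrow(cuts)
  tb <- c(0L, cuts$top_nick, L)      # top-strand boundaries
  bb <- c(0L, cuts$bottom_nick, L)   # bottom-strand boundaries
  o <- rule$overhang
  internal_chem <- if (o > 0) "3prime" else if (o < 0) "5prime" else "blunt"
  frags <- data.frame(
    top_start    = tb[seq_len(k + 1L)],
    top_end      = tb[seq_len(k + 1L) + 1L],
    bottom_start = bb[seq_len(k + 1L)],
    bottom_end   = bb[seq_len(k + 1L) + 1L],
    left_end  = c("blunt", rep(internal_chem, k)),
    right_end = c(rep(internal_chem, k), "blunt"),
    stringsAsFactors = FALSE)
  structure(list(fragments = frags, cuts = cuts, rule = rule,
                 genome_id = genome$id, L = L),
            class = "DigestResult")
}

#' @export
print.DigestResult <- function(x, ...) {
  cat(sprintf("DigestResult '%s': %d cut(s), %d fragment(s) on %d bp\n",
              x$genome_id, nrow(x$cuts), nrow(x$fragments), x$L))
  invisible(x)
}

#' End-repair fragments into blunt mapped intervals
#'
#' Emulates the library-preparation chemistry applied to digestion
#' products before sequencing: 3' overhangs are chewed back to the duplex
#' core (the mapped interval shrinks by the overhang length on that side),
#' 5' overhangs are filled in (the interval grows to the protruding
#' strand's extent), blunt ends are untouched.  dA tailing and adapter
#' ligation are length-neutral here, as adapters are trimmed before
#' mapping in real pipelines.  It is exactly this chew-back that turns a
#' 2-nt 3' overhang into a +2 bp gap between adjacent mapped fragments.
#'
#' @param x A `DigestResult` or its `fragments` data frame.
#' @return Data frame of class `RepairedIntervals` with 0-based half-open
#'   columns `start`, `end`.
#' @export
end_repair <- function(x) {
  frags <- if (inherits(x, "DigestResult")) x$fragments else x
  stopifnot(is.data.frame(frags),
            all(c("top_start", "top_end", "bottom_start", "bottom_end",
                  "left_end", "right_end") %in% names(frags)))
  start <- ifelse(frags$left_end == "3prime",
                  pmax(frags$top_start, frags$bottom_start),   # chew back
                  pmin(frags$top_start, frags$bottom_start))   # fill / blunt
  end <- ifelse(frags$right_end == "3prime",
                pmin(frags$top_end, frags$bottom_end),
                pmax(frags$top_end, frags$bottom_end))
  out <- data.frame(start = as.integer(start), end = as.integer(end))
  class(out) <- c("RepairedIntervals", "data.frame")
  out
}

#' Emit error-free paired-end reads from repaired intervals
#'
#' For each interval, mate 1 is the first `min(read_len, width)` bases of
#' the top strand from the left end and mate 2 the reverse complement of
#' the last `min(read_len, width)` bases — the outermost mapped termini of
#' such a pair reproduce the interval ends exactly, which is what makes
#' fragment-end cartography possible.  Reads are error-free; the true
#' interval is encoded in the read name for truth tracking.
#'
#' @param intervals A `RepairedIntervals` data frame.
#' @param genome The [modified_genome()] the intervals live on.
#' @param read_len Read length in bp (default 150, as in a 2 x 150 bp
#'   paired-end run).
#' @param seed Master seed (stage `"reads"`); retained for interface
#'   stability although the default error-free model draws nothing.
#' @param fastq1,fastq2 Optional output paths; when given, mates are
#'   written as FASTQ with constant maximal base qualities.
#' @return Invisibly (when writing) or visibly, a list with `mate1` and
#'   `mate2` as [Biostrings::DNAStringSet] objects named
#'   `<genome>:<start>-<end>/<mate>`.
#' @export
emit_read_pairs <- function(intervals, genome, read_len = 150L, seed = 1L,
                            fastq1 = NULL, fastq2 = NULL) {
  stopifnot(is.data.frame(intervals), read_len >= 1L)
  start <- as.integer(intervals$start)
  end <- as.integer(intervals$end)
  w <- pmin(end - start, as.integer(read_len))
  m1 <- substring(genome$seq, start + 1L, start + w)
  m2 <- substring(genome$seq, end - w + 1L, end)
  mate1 <- Biostrings::DNAStringSet(m1)
  mate2 <- Biostrings::reverseComplement(Biostrings::DNAStringSet(m2))
  nm <- sprintf("%s:%d-%d", genome$id, start, end)
  names(mate1) <- paste0(nm, "/1")
  names(mate2) <- paste0(nm, "/2")
  out <- list(mate1 = mate1, mate2 = mate2)
  if (!is.null(fastq1) || !is.null(fastq2)) {
    stopifnot(!is.null(fastq1), !is.null(fastq2))
    write_fastq(mate1, fastq1)
    write_fastq(mate2, fastq2)
    return(invisible(out))
  }
  out
}

write_fastq <- function(reads, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  seqs <- as.character(reads)
  for (i in seq_along(seqs)) {
    writeLines(c(paste0("@", names(reads)[i]), seqs[i], "+",
                 strrep("I", nchar(seqs[i]))), con)
  }
  invisible(path)
}
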