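#' @importFrom stats runif setNames
#' @importFrom utils read.delim write.table
NULL

#' Cytosine modification classes
#'
#' The closed set of per-base cytosine states the pipeline tracks:
#' unmodified cytosine (`C`), 5-methylcytosine (`m5C`),
#' 5-hydroxymethylcytosine (`hm5C`) and glucosyl-5-hydroxymethylcytosine
#' (`ghm5C`).  T-even phages substitute their genomic cytosines with
#' hm5C/ghm5C, which is what a modification-dependent restriction
#' endonuclease detects; `C` and `m5C` are non-cleavable controls.
#'
#' @format Character vector of the four class names.
#' @export
MOD_CLASSES <- c("C", "m5C", "hm5C", "ghm5C")

STRANDS <- c("top", "bottom")

canonical_mods <- function(mods) {
  stopifnot(is.data.frame(mods), all(c("pos", "strand", "mod") %in% names(mods)))
  mods <- data.frame(pos    = as.integer(mods$pos),
                     strand = as.character(mods$strand),
                     mod    = as.character(mods$mod),
                     stringsAsFactors = FALSE)
  mods <- unique(mods)
  ord <- order(mods$pos, match(mods$strand, STRANDS))
  mods <- mods[ord, , drop = FALSE]
  rownames(mods) <- NULL
  mods
}

empty_mods <- function() {
  data.frame(pos = integer(0), strand = character(0), mod = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a modified genome
#'
#' A `ModifiedGenome` couples a double-stranded DNA sequence (stored as its
#' top strand) with a per-(position, strand) cytosine-modification track.
#' Coordinates are 0-based; a bottom-strand cytosine is keyed by the
#' top-strand coordinate of its paired base (a top-strand `G`).  An absent
#' key means unmodified cytosine.
#'
#' @param seq Uppercase DNA string over `{A,C,G,T}` (top strand).
#' @param mods Data frame with columns `pos` (0-based integer), `strand`
#'   (`"top"` or `"bottom"`) and `mod` (one of [MOD_CLASSES]).  Every row
#'   must point at a genuine cytosine on the stated strand: `seq[pos] == "C"`
#'   for `top`, `seq[pos] == "G"` for `bottom`.
#' @param id Sequence identifier used in FASTA/BED output.
#' @return An object of class `ModifiedGenome`: a list with elements `id`,
#'   `seq` and `mods` (canonically sorted by position then strand).
#' @seealso [generate_genome()], [apply_modification_scheme()]
#' @export
modified_genome <- function(seq, mods = empty_mods(), id = "synthetic") {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (grepl("[^ACGT]", seq))
    stop("sequence must be uppercase DNA over {A,C,G,T}")
  mods <- canonical_mods(mods)
  validate_mods(seq, mods)
  structure(list(id = id, seq = seq, mods = mods), class = "ModifiedGenome")
}

validate_mods <- function(seq, mods) {
  if (nrow(mods) == 0L) return(invisible(TRUE))
  L <- nchar(seq)
  if (any(mods$pos < 0L | mods$pos >= L))
    stop("modification position outside [0, ", L, ")")
  bad_strand <- !mods$strand %in% STRANDS
  if (any(bad_strand))
    stop("invalid strand: ", mods$strand[bad_strand][1L])
  bad_class <- !mods$mod %in% MOD_CLASSES
  if (any(bad_class))
    stop("unknown modification class: ", mods$mod[bad_class][1L])
  base <- substring(seq, mods$pos + 1L, mods$pos + 1L)
  need <- ifelse(mods$strand == "top", "C", "G")
  off <- base != need
  if (any(off)) {
    i <- which(off)[1L]
    stop(sprintf(
      "site (%d, %s) is not a cytosine on that strand (top-strand base '%s')",
      mods$pos[i], mods$strand[i], base[i]))
  }
  invisible(TRUE)
}

#' @export
print.ModifiedGenome <- function(x, ...) {
  cat(sprintf("ModifiedGenome '%s': %d bp, %d modified site(s)\n",
              x$id, nchar(x$seq), nrow(x$mods)))
  if (nrow(x$mods) > 0L) {
    tab <- table(x$mods$mod)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

genome_length <- function(genome) nchar(genome$seq)

#' Generate a seeded random genome
#'
#' Draws a linear genome of i.i.d. bases with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`.  Defaults emulate a T-even-phage-like
#' substrate at desk scale: the real T4 genome is ~168 kb at ~35% GC, and
#' 100 kb at gc 0.35 keeps a comparable density of candidate recognition
#' sites while staying fast to scan.  The modification track starts empty;
#' see [apply_modification_scheme()].
#'
#' @param length Genome length in bp (positive integer).
#' @param gc Target GC fraction in `[0, 1]`.
#' @param seed Integer master seed; the draw uses the `"genome"` stage
#'   stream derived from it (see [derive_seed()]).
#' @param id Sequence identifier.
#' @return A [modified_genome()] with empty modification track.
#' @examples
#' g <- generate_genome(1000, gc = 0.35, seed = 1)
#' nchar(g$seq)
#' @export
generate_genome <- function(length, gc = 0.35, seed = 1L, id = "synthetic") {
  stopifnot(is.numeric(length), length(length) == 1L)
  if (length < 1 || length != floor(length))
    stop("length must be a positive integer")
  if (!is.numeric(gc) || gc < 0 || gc > 1)
    stop("gc must lie in [0, 1]")
  bases <- with_stage_seed(seed, "genome", {
    sample(c("A", "C", "G", "T"), size = length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  })
  modified_genome(paste(bases, collapse = ""), id = id)
}

#' Enumerate strand-wise cytosines
#'
#' Lists every position carrying a cytosine on either strand: top-strand
#' `C`s, and bottom-strand cytosines (positions whose top-strand base is
#' `G`), keyed by top-strand coordinate.
#'
#' @param genome A [modified_genome()].
#' @return Data frame with columns `pos` (0-based) and `strand`, in
#'   canonical order.
#' @export
cytosine_positions <- function(genome) {
  s <- strsplit(genome$seq, "", fixed = TRUE)[[1L]]
  top <- which(s == "C") - 1L
  bot <- which(s == "G") - 1L
  out <- data.frame(
    pos    = c(top, bot),
    strand = c(rep("top", length(top)), rep("bottom", length(bot))),
    stringsAsFactors = FALSE)
  ord <- order(out$pos, match(out$strand, STRANDS))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Describe a cytosine-modification scheme
#'
#' Captures how cytosines of a genome are to be marked, mirroring the
#' substrate panel used to characterise modification-dependent nucleases:
#' fully modified genomes (T-even-phage-like, `mode = "all"`), partially
#' modified ones (`mode = "fraction"`), defined synthetic constructs
#' (`mode = "explicit"`) and unmodified controls (`mode = "none"`).
#'
#' @param mode One of `"none"`, `"all"`, `"fraction"`, `"explicit"`.
#' @param mod_class Modification class to apply (one of [MOD_CLASSES]).
#' @param fraction Marginal marking probability per cytosine; required iff
#'   `mode = "fraction"`.
#' @param sites Data frame with columns `pos` and `strand`; required iff
#'   `mode = "explicit"`.
#' @param seed Integer master seed for `mode = "fraction"` (stage
#'   `"modify"`).
#' @return An object of class `ModificationScheme`.
#' @export
modification_scheme <- function(mode = c("all", "none", "fraction", "explicit"),
                                mod_class = "hm5C", fraction = NULL,
                                sites = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(mod_class %in% MOD_CLASSES)
  if (mode == "fraction") {
    if (is.null(fraction) || !is.numeric(fraction) ||
        fraction < 0 || fraction > 1)
      stop("mode='fraction' requires fraction in [0, 1]")
  } else if (!is.null(fraction)) {
    stop("fraction is only meaningful for mode='fraction'")
  }
  if (mode == "explicit") {
    if (is.null(sites) || !is.data.frame(sites) ||
        !all(c("pos", "strand") %in% names(sites)))
      stop("mode='explicit' requires a sites data frame with pos and strand")
  } else if (!is.null(sites)) {
    stop("sites are only meaningful for mode='explicit'")
  }
  structure(list(mode = mode, mod_class = mod_class, fraction = fraction,
                 sites = sites, seed = seed),
            class = "ModificationScheme")
}

#' Apply a modification scheme to a genome
#'
#' Returns a new genome whose modification track follows the scheme; the
#' input is never mutated.  `mode = "all"` marks every strand-wise cytosine
#' (as in a fully hydroxymethylated T-even phage genome); `"fraction"`
#' marks a seeded Bernoulli subset; `"explicit"` marks the listed sites and
#' rejects any that is not a cytosine on its stated strand, naming the
#' offending coordinate; `"none"` clears the track.
#'
#' @param genome A [modified_genome()].
#' @param scheme A [modification_scheme()].
#' @return A new `ModifiedGenome`.
#' @examples
#' g <- modified_genome("ACGT")
#' apply_modification_scheme(g, modification_scheme("all"))$mods
#' @export
apply_modification_scheme <- function(genome, scheme) {
  stopifnot(inherits(genome, "ModifiedGenome"),
            inherits(scheme, "ModificationScheme"))
  cys <- cytosine_positions(genome)
  mods <- switch(
    scheme$mode,
    none = empty_mods(),
    all = data.frame(cys, mod = rep(scheme$mod_class, nrow(cys)),
                     stringsAsFactors = FALSE),
    fraction = {
      keep <- with_stage_seed(scheme$seed, "modify",
                              runif(nrow(cys)) < scheme$fraction)
      data.frame(cys[keep, , drop = FALSE],
                 mod = rep(scheme$mod_class, sum(keep)),
                 stringsAsFactors = FALSE)
    },
    explicit = {
      sites <- scheme$sites
      key <- paste(cys$pos, cys$strand)
      ask <- paste(as.integer(sites$pos), as.character(sites$strand))
      miss <- !ask %in% key
      if (any(miss)) {
        i <- which(miss)[1L]
        stop(sprintf("explicit site (%d, %s) is not a cytosine on that strand",
                     as.integer(sites$pos[i]), as.character(sites$strand[i])))
      }
      mod <- if ("mod" %in% names(sites)) as.character(sites$mod)
             else rep(scheme$mod_class, nrow(sites))
      data.frame(pos = as.integer(sites$pos),
                 strand = as.character(sites$strand), mod = mod,
                 stringsAsFactors = FALSE)
    })
  modified_genome(genome$seq, mods, id = genome$id)
}

#' Write a modified genome to FASTA plus a BED6+1 modification track
#'
#' The sequence goes to FASTA; the modification track to BED6+1 with one
#' row per modified cytosine: `chrom, start, start+1, name = class,
#' score = 0, strand (+ for top, - for bottom), class` (column 7 repeats
#' the class so the file survives tools that rewrite the name field).
#' Rows are emitted in canonical order (position, then top before bottom),
#' so serialisation is a fixed point: writing what was read reproduces the
#' bytes.
#'
#' @param genome A [modified_genome()].
#' @param fasta_path,track_path Output paths.
#' @return Invisibly, the two paths.
#' @seealso [read_modified_genome()]
#' @export
write_modified_genome <- function(genome, fasta_path, track_path) {
  stopifnot(inherits(genome, "ModifiedGenome"))
  dna <- Biostrings::DNAStringSet(genome$seq)
  names(dna) <- genome$id
  Biostrings::writeXStringSet(dna, fasta_path, width = 70L)
  m <- genome$mods
  bed <- data.frame(chrom = rep(genome$id, nrow(m)),
                    start = m$pos,
                    end = m$pos + 1L,
                    name = m$mod,
                    score = rep(0L, nrow(m)),
                    strand = ifelse(m$strand == "top", "+", "-"),
                    mod = m$mod,
                    stringsAsFactors = FALSE)
  write.table(bed, track_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(fasta = fasta_path, track = track_path))
}

#' Read a modified genome from FASTA plus a BED6+1 modification track
#'
#' Inverse of [write_modified_genome()]: `read(write(g))` reproduces `g`
#' exactly.  Malformed track lines (wrong column count, unknown strand or
#' class, position not a cytosine on the stated strand) raise an error
#' naming the line number.
#'
#' @param fasta_path,track_path Input paths as written by
#'   [write_modified_genome()].
#' @return A [modified_genome()].
#' @export
read_modified_genome <- function(fasta_path, track_path) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dna) != 1L)
    stop("expected exactly one sequence in ", fasta_path)
  seq <- as.character(dna[[1L]])
  id <- names(dna)[1L]
  lines <- readLines(track_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(modified_genome(seq, id = id))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (any(n < 7L))
    stop("track line ", which(n < 7L)[1L], ": expected 7 tab-separated fields")
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  strand_sym <- vapply(fields, `[[`, "", 6L)
  mod <- vapply(fields, `[[`, "", 7L)
  if (anyNA(pos))
    stop("track line ", which(is.na(pos))[1L], ": start is not an integer")
  bad <- !strand_sym %in% c("+", "-")
  if (any(bad))
    stop("track line ", which(bad)[1L], ": strand must be '+' or '-'")
  bad <- !mod %in% MOD_CLASSES
  if (any(bad))
    stop("track line ", which(bad)[1L], ": unknown modification class '",
         mod[bad][1L], "'")
  strand <- ifelse(strand_sym == "+", "top", "bottom")
  base <- substring(seq, pos + 1L, pos + 1L)
  need <- ifelse(strand == "top", "C", "G")
  bad <- is.na(base) | base != need
  if (any(bad))
    stop("track line ", which(bad)[1L], ": position ", pos[bad][1L],
         " is not a cytosine on the ", strand[bad][1L], " strand")
  modified_genome(seq,
                  data.frame(pos = pos, strand = strand, mod = mod,
                             stringsAsFactors = FALSE),
                  id = id)
}

#' Reverse-complement a modified genome
#'
#' Remaps the sequence and the modification track to the opposite strand:
#' a top-strand mark at position `p` becomes a bottom-strand mark at
#' `L - 1 - p` and vice versa.  Useful for checking that site scanning is
#' invariant under strand flipping (the bipartite site is symmetric).
#'
#' @param genome A [modified_genome()].
#' @return The reverse-complemented `ModifiedGenome`.
#' @export
reverse_complement_genome <- function(genome) {
  L <- genome_length(genome)
  seq_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(genome$seq)))
  m <- genome$mods
  modified_genome(seq_rc,
                  data.frame(pos = L - 1L - m$pos,
                             strand = ifelse(m$strand == "top",
                                             "bottom", "top"),
                             mod = m$mod, stringsAsFactors = FALSE),
                  id = genome$id)
}
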