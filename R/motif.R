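DNA_BASES <- c("A", "C", "G", "T")

pfm_columns <- function(W) c(-W:-1, 1:W)

#' Base-frequency matrix of nick-flanking sequence
#'
#' Extracts the `W` bases on each side of every reconstructed top-strand
#' nick boundary (top-strand sequence, weighted by pileup count) and
#' accumulates per-column base frequencies.  Columns are indexed
#' `-W..-1` (left of the nick, `-1` adjacent) and `+1..+W` (right of the
#' nick, `+1` adjacent); the nick boundary itself sits between columns
#' `-1` and `+1`.  Nicks with fewer than `W` bases of sequence on either
#' side are dropped and counted.  No pseudocounts are added by default, so
#' perfectly conserved positions reach a frequency of exactly 1; supply a
#' positive `pseudocount` for sparse real data.
#'
#' The bipartite site is symmetric, so the bottom-strand logo is the
#' reverse complement of this one and is not computed separately.
#'
#' @param pileup A [reconstruct_nicks()] `NickPileup`.
#' @param genome The [modified_genome()] the nicks live on.
#' @param W Flank half-width in bp (default 20).
#' @param pseudocount Added to every cell before normalisation (default 0).
#' @return An object of class `FlankPFM`: list with `prob` (4 x 2W matrix,
#'   rows A/C/G/T, columns as above), `counts`, `n_sites` (total weight
#'   used), `W`, `dropped`.
#' @export
flank_pfm <- function(pileup, genome, W = 20L, pseudocount = 0) {
  stopifnot(inherits(pileup, "NickPileup"),
            inherits(genome, "ModifiedGenome"), W >= 1L)
  loci <- pileup$loci
  if (nrow(loci) == 0L) stop("no sites: empty nick pileup")
  L <- genome_length(genome)
  W <- as.integer(W)
  ok <- loci$top - W >= 0L & loci$top + W <= L
  dropped <- sum(loci$count[!ok])
  loci <- loci[ok, , drop = FALSE]
  if (nrow(loci) == 0L) stop("no sites: all nicks too close to a genome end")
  cols <- pfm_columns(W)
  counts <- matrix(0, nrow = 4L, ncol = 2L * W,
                   dimnames = list(DNA_BASES, as.character(cols)))
  flanks <- substring(genome$seq, loci$top - W + 1L, loci$top + W)
  chars <- matrix(unlist(strsplit(flanks, "", fixed = TRUE), use.names = FALSE),
                  nrow = nrow(loci), byrow = TRUE)
  for (j in seq_len(2L * W)) {
    tab <- tapply(loci$count, factor(chars[, j], levels = DNA_BASES), sum)
    tab[is.na(tab)] <- 0
    counts[, j] <- tab
  }
  counts <- counts + pseudocount
  prob <- sweep(counts, 2L, colSums(counts), "/")
  structure(list(prob = prob, counts = counts, n_sites = sum(loci$count),
                 W = W, dropped = dropped),
            class = "FlankPFM")
}

#' @export
print.FlankPFM <- function(x, ...) {
  cat(sprintf("FlankPFM: +/-%d bp around %d weighted nick(s) (%d dropped)\n",
              x$W, x$n_sites, x$dropped))
  invisible(x)
}

#' Per-column information content of a flank PFM
#'
#' Relative entropy of each column against a background distribution:
#' `sum_b p_b log2(p_b / q_b)` with `0 log 0 := 0`.  Under a uniform
#' background this is `2 - H(p)` bits — the column heights of a standard
#' sequence logo; a one-hot column scores 2 bits, a uniform one 0.
#'
#' @param pfm A [flank_pfm()].
#' @param background Strictly positive base probabilities over A/C/G/T
#'   (default uniform); normalised internally.
#' @return Named numeric vector of bits, one per PFM column.
#' @export
column_information <- function(pfm, background = rep(0.25, 4)) {
  stopifnot(inherits(pfm, "FlankPFM"), length(background) == 4L)
  if (any(background <= 0)) stop("background must be strictly positive")
  q <- background / sum(background)
  apply(pfm$prob, 2L, function(p) {
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / q[nz]))
  })
}

#' Call the recognition consensus from a flank PFM
#'
#' A column is conserved iff its maximum base frequency reaches
#' `threshold`.  The consensus string runs from the leftmost to the
#' rightmost conserved column, with non-conserved columns rendered `N`,
#' `N` runs length-compressed, and the top-strand nick boundary marked
#' `/` — the default simulation yields `CN11/N9G`.  The recovered offsets
#' count intervening bases: `u_hat` is the number of columns strictly
#' between the nearest conserved column left of `/` and the nick, `v_hat`
#' the same on the right, and `s_hat = u_hat + v_hat + 1`.
#'
#' @param pfm A [flank_pfm()].
#' @param threshold Conservation threshold in `(0.5, 1]` (default 0.9: in
#'   a fully modified genome the anchor columns are exactly 1.0 while
#'   background columns stay near GC-derived frequencies).
#' @return An object of class `ConsensusModel`: list with `consensus`,
#'   `conserved` (data frame `column`, `base`, `frequency`), `u_hat`,
#'   `v_hat`, `s_hat`, `overhang_hat`, `flagged` (`TRUE` when no conserved
#'   column exists and the offsets are undefined).
#' @export
consensus_call <- function(pfm, threshold = 0.9) {
  stopifnot(inherits(pfm, "FlankPFM"))
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1]")
  cols <- as.integer(colnames(pfm$prob))
  top_base <- DNA_BASES[apply(pfm$prob, 2L, which.max)]
  top_freq <- apply(pfm$prob, 2L, max)
  conserved <- top_freq >= threshold
  cons_df <- data.frame(column = cols[conserved], base = top_base[conserved],
                        frequency = unname(top_freq[conserved]))
  if (!any(conserved)) {
    return(structure(list(consensus = "N", conserved = cons_df,
                          u_hat = NA_integer_, v_hat = NA_integer_,
                          s_hat = NA_integer_, overhang_hat = NA_integer_,
                          flagged = TRUE),
                     class = "ConsensusModel"))
  }
  left_cols <- cols[conserved & cols < 0L]
  right_cols <- cols[conserved & cols > 0L]
  u_hat <- if (length(left_cols)) -max(left_cols) - 1L else NA_integer_
  v_hat <- if (length(right_cols)) min(right_cols) - 1L else NA_integer_
  s_hat <- if (!is.na(u_hat) && !is.na(v_hat)) u_hat + v_hat + 1L
           else NA_integer_
  span <- cols >= min(cols[conserved]) & cols <= max(cols[conserved])
  letters <- ifelse(conserved[span], top_base[span], "N")
  consensus <- paste0(render_consensus(letters, cols[span]), collapse = "")
  structure(list(consensus = consensus, conserved = cons_df,
                 u_hat = u_hat, v_hat = v_hat, s_hat = s_hat,
                 overhang_hat = if (is.na(u_hat) || is.na(v_hat)) NA_integer_
                                else u_hat - v_hat,
                 flagged = is.na(u_hat) || is.na(v_hat)),
            class = "ConsensusModel")
}

# Render per-column letters into a run-length-compressed consensus with
# the nick boundary (between columns -1 and +1) marked "/".
render_consensus <- function(letters, cols) {
  out <- character(0)
  run <- 0L
  flush <- function(out, run) {
    if (run == 0L) return(out)
    c(out, if (run == 1L) "N" else paste0("N", run))
  }
  for (i in seq_along(letters)) {
    if (i > 1L && cols[i - 1L] == -1L && cols[i] == 1L) {
      out <- flush(out, run); run <- 0L
      out <- c(out, "/")
    }
    if (letters[i] == "N") run <- run + 1L
    else { out <- flush(out, run); run <- 0L; out <- c(out, letters[i]) }
  }
  flush(out, run)
}

#' @export
print.ConsensusModel <- function(x, ...) {
  cat("ConsensusModel:", x$consensus, "\n")
  if (!x$flagged)
    cat(sprintf("  u=%d, v=%d, s=%d, overhang %+d nt\n",
                x$u_hat, x$v_hat, x$s_hat, x$overhang_hat))
  else cat("  offsets undefined (no conserved anchor on one side)\n")
  invisible(x)
}

#' Recover rule parameters from nicks and the ground-truth track
#'
#' Uses the simulation's (or any annotated genome's) modification track to
#' measure the cut geometry directly.  For each reconstructed locus it
#' enumerates every top-strand modified cytosine within `s_max` bases
#' upstream of the top nick (recording the intervening-base count `a`) and
#' every bottom-strand modified cytosine within `s_max` bases downstream
#' (recording `b`, counted from the top nick to the partner base), plus
#' the spacing of every upstream/downstream candidate pair.  The true site
#' contributes its `(u, v, s)` at every locus while incidental modified
#' cytosines spread over all values, so the modal `a`, `b` and spacing
#' recover `u`, `v` and `s` — exactly, under full digestion.
#'
#' @param pileup A [reconstruct_nicks()] `NickPileup`.
#' @param genome A [modified_genome()] carrying a non-empty track.
#' @param s_max Search radius in bp on each side of the nick (default 30;
#'   must be at least the enzyme's `u` and `v`).
#' @param required_classes Track classes treated as modified (default
#'   `hm5C`/`ghm5C`, matching the cleavable classes).
#' @return List of class `RuleEstimate`: `u`, `v`, `s` (modal estimates),
#'   `u_hist`, `v_hist`, `s_hist` (named count vectors), `n_loci_used`,
#'   `n_excluded` (loci with no tracked modification within `s_max` on one
#'   side, excluded with a warning count).
#' @export
infer_rule_parameters <- function(pileup, genome, s_max = 30L,
                                  required_classes = c("hm5C", "ghm5C")) {
  stopifnot(inherits(pileup, "NickPileup"),
            inherits(genome, "ModifiedGenome"))
  loci <- pileup$loci
  if (nrow(loci) == 0L) stop("empty nick pileup")
  m <- genome$mods[genome$mods$mod %in% required_classes, , drop = FALSE]
  if (nrow(m) == 0L) stop("empty modification track")
  top_pos <- sort(m$pos[m$strand == "top"])
  bot_pos <- sort(m$pos[m$strand == "bottom"])
  a_all <- list(); b_all <- list(); s_all <- list(); w_all <- list()
  excluded <- 0L
  for (i in seq_len(nrow(loci))) {
    t <- loci$top[i]
    # upstream top-strand modified Cs: base at p, nick at t, a = t - p - 1
    up <- top_pos[top_pos <= t - 1L & top_pos >= t - 1L - s_max]
    # downstream bottom-strand modified Cs (partner base at q >= t):
    # intervening bases between nick and partner: b = q - t
    dn <- bot_pos[bot_pos >= t & bot_pos <= t + s_max]
    if (!length(up) || !length(dn)) { excluded <- excluded + 1L; next }
    a_all[[length(a_all) + 1L]] <- t - up - 1L
    b_all[[length(b_all) + 1L]] <- dn - t
    s_all[[length(s_all) + 1L]] <- as.vector(outer(dn, up, "-"))
    w_all[[length(w_all) + 1L]] <-
      list(a = rep(loci$count[i], length(up)),
           b = rep(loci$count[i], length(dn)),
           s = rep(loci$count[i], length(up) * length(dn)))
  }
  if (!length(a_all))
    stop("no locus had tracked modifications within s_max on both sides")
  wtab <- function(vals, w) {
    v <- unlist(vals, use.names = FALSE)
    ww <- unlist(w, use.names = FALSE)
    tt <- tapply(ww, v, sum)
    setNames(as.integer(tt), names(tt))
  }
  u_hist <- wtab(a_all, lapply(w_all, `[[`, "a"))
  v_hist <- wtab(b_all, lapply(w_all, `[[`, "b"))
  s_hist <- wtab(s_all, lapply(w_all, `[[`, "s"))
  modal <- function(h) as.integer(names(h)[order(-h, as.integer(names(h)))[1L]])
  structure(list(u = modal(u_hist), v = modal(v_hist), s = modal(s_hist),
                 u_hist = u_hist, v_hist = v_hist, s_hist = s_hist,
                 n_loci_used = nrow(loci) - excluded, n_excluded = excluded),
            class = "RuleEstimate")
}

#' @export
print.RuleEstimate <- function(x, ...) {
  cat(sprintf("RuleEstimate: u=%d, v=%d, s=%d (%d locus/loci used, %d excluded)\n",
              x$u, x$v, x$s, x$n_loci_used, x$n_excluded))
  invisible(x)
}
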