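dedup_intervals <- function(intervals) {
  df <- data.frame(start = as.integer(intervals$start),
                   end = as.integer(intervals$end))
  df <- unique(df)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Distribution of signed gaps between mapped fragment ends
#'
#' For every interval end `e`, pairs it with every start `s` of a
#' different interval satisfying `|s - e| <= window` and records the
#' signed gap `g = s - e` in half-open coordinates.  The sign convention
#' is the crux of overhang inference: abutting blunt fragments give
#' `g = 0`; a chewed-back 3' overhang of `o` nt leaves `g = +o`; a
#' filled-in 5' overhang leaves `g = -o`.  Duplicate intervals (PCR
#' duplicates) are collapsed before pairing.
#'
#' @param intervals Data frame with `start` and `end` (0-based half-open),
#'   e.g. from [end_repair()] or [read_intervals_bed()].
#' @param window Maximum absolute gap considered a candidate pair, in bp
#'   (default 10; real restriction overhangs are at most ~6 nt, so a small
#'   window keeps coincidental pairings rare).
#' @param dedup Collapse duplicate intervals first (default `TRUE`).
#' @return An object of class `GapHistogram`: list with `counts` (named
#'   integer vector, names the signed gaps), `window`, `n_pairs`.
#' @examples
#' iv <- data.frame(start = c(0, 12), end = c(10, 20))
#' gap_distribution(iv, window = 10)$counts  # one pair at gap +2
#' @export
gap_distribution <- function(intervals, window = 10L, dedup = TRUE) {
  if (window < 0) stop("window must be non-negative")
  df <- if (dedup) dedup_intervals(intervals) else
    data.frame(start = as.integer(intervals$start),
               end = as.integer(intervals$end))
  gaps <- integer(0)
  if (nrow(df) >= 2L) {
    ord <- order(df$start)
    starts <- df$start[ord]
    id <- seq_len(nrow(df))[ord]
    gap_list <- vector("list", nrow(df))
    for (i in seq_len(nrow(df))) {
      e <- df$end[i]
      lo <- findInterval(e - window - 0.5, starts) + 1L
      hi <- findInterval(e + window + 0.5, starts)
      if (hi >= lo) {
        j <- lo:hi
        j <- j[id[j] != i]            # never pair an interval with itself
        if (length(j)) gap_list[[i]] <- starts[j] - e
      }
    }
    gaps <- unlist(gap_list, use.names = FALSE)
    if (is.null(gaps)) gaps <- integer(0)
  }
  counts <- table(gaps)
  counts <- setNames(as.integer(counts), names(counts))
  structure(list(counts = counts, window = as.integer(window),
                 n_pairs = sum(counts)),
            class = "GapHistogram")
}

#' @export
print.GapHistogram <- function(x, ...) {
  cat(sprintf("GapHistogram: %d pair(s), window %d bp\n", x$n_pairs, x$window))
  if (length(x$counts)) print(x$counts)
  invisible(x)
}

#' Call overhang length and polarity from a gap histogram
#'
#' The modal gap `g*` encodes the cut chemistry: `g* > 0` means the end
#' repair chewed something back, i.e. a 3' overhang of `g*` nt; `g* < 0`
#' means a fill-in of a 5' overhang of `|g*|` nt; `g* = 0` means blunt
#' cutting.  Ties are broken toward smaller `|g|`, then toward the
#' positive sign.  `support` is the modal fraction of all pairs.
#'
#' @param hist A `GapHistogram` from [gap_distribution()].
#' @return An object of class `OverhangCall`: list with `length`
#'   (non-negative integer nt), `polarity` (`"3prime"`, `"5prime"` or
#'   `"blunt"`), `support`, `modal_gap`.
#' @examples
#' h <- gap_distribution(data.frame(start = c(0, 12), end = c(10, 20)))
#' infer_overhang(h)  # 2-nt 3' overhang
#' @export
infer_overhang <- function(hist) {
  stopifnot(inherits(hist, "GapHistogram"))
  if (length(hist$counts) == 0L)
    stop("no cleavage detected: empty gap histogram")
  g <- as.integer(names(hist$counts))
  n <- hist$counts
  ord <- order(-n, abs(g), g < 0)     # max count, then |g|, then positive
  gstar <- g[ord[1L]]
  polarity <- if (gstar > 0L) "3prime" else if (gstar < 0L) "5prime" else "blunt"
  structure(list(length = abs(gstar), polarity = polarity,
                 support = unname(n[ord[1L]] / sum(n)),
                 modal_gap = gstar),
            class = "OverhangCall")
}

#' @export
print.OverhangCall <- function(x, ...) {
  lab <- c("3prime" = "3'", "5prime" = "5'", blunt = "blunt")[x$polarity]
  cat(sprintf("OverhangCall: %d nt %s (modal gap %+d, support %.3f)\n",
              x$length, lab, x$modal_gap, x$support))
  invisible(x)
}

#' Reconstruct dual-strand nick boundaries from repaired intervals
#'
#' Inverts the end-repair chemistry.  Under a 3' call, the downstream
#' fragment's mapped start is the unshifted top-strand nick boundary and
#' the paired upstream fragment's end — shifted by the chew-back — is the
#' bottom-strand nick (`bottom = top - length`).  Under a 5' call the
#' picture is mirrored (`bottom = top + length`); blunt cuts have
#' `top = bottom`.  A locus requires both the upstream end and the
#' downstream start present, at exactly the gap the overhang call
#' predicts, within `window`; ends whose nearby starts all disagree with
#' the expected gap are flagged and counted, not piled up.
#'
#' @param intervals Repaired intervals (`start`, `end`).
#' @param call An [infer_overhang()] `OverhangCall`.
#' @param window Pairing window in bp (default 10).
#' @param dedup Collapse duplicate intervals first (default `TRUE`).
#' @return An object of class `NickPileup`: list with `loci` (data frame
#'   `top`, `bottom`, `count`, one row per reconstructed cut locus),
#'   `flagged` (number of candidate loci excluded for inconsistent
#'   pairing), `call`, `window`.
#' @examples
#' iv <- data.frame(start = c(0, 12), end = c(10, 20))
#' cl <- infer_overhang(gap_distribution(iv))
#' reconstruct_nicks(iv, cl)$loci  # top 12, bottom 10
#' @export
reconstruct_nicks <- function(intervals, call, window = 10L, dedup = TRUE) {
  stopifnot(inherits(call, "OverhangCall"))
  df <- if (dedup) dedup_intervals(intervals) else
    data.frame(start = as.integer(intervals$start),
               end = as.integer(intervals$end))
  expected <- switch(call$polarity,
                     "3prime" = call$length,
                     "5prime" = -call$length,
                     blunt = 0L)
  top <- integer(0); bottom <- integer(0); count <- integer(0)
  flagged <- 0L
  if (nrow(df) >= 2L) {
    ord <- order(df$start)
    starts <- df$start[ord]
    id <- seq_len(nrow(df))[ord]
    for (i in seq_len(nrow(df))) {
      e <- df$end[i]
      lo <- findInterval(e - window - 0.5, starts) + 1L
      hi <- findInterval(e + window + 0.5, starts)
      if (hi < lo) next
      j <- (lo:hi)[id[lo:hi] != i]
      if (!length(j)) next
      hitn <- sum(starts[j] - e == expected)
      if (hitn > 0L) {
        top <- c(top, e + expected)   # downstream mapped start
        bottom <- c(bottom, e)        # upstream mapped end
        count <- c(count, hitn)
      } else {
        flagged <- flagged + 1L
      }
    }
  }
  loci <- data.frame(top = top, bottom = bottom, count = count)
  loci <- loci[order(loci$bottom), , drop = FALSE]
  rownames(loci) <- NULL
  structure(list(loci = loci, flagged = flagged, call = call,
                 window = as.integer(window)),
            class = "NickPileup")
}

#' @export
print.NickPileup <- function(x, ...) {
  cat(sprintf("NickPileup: %d locus/loci, %d flagged (call: %d nt %s)\n",
              nrow(x$loci), x$flagged, x$call$length, x$call$polarity))
  invisible(x)
}
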