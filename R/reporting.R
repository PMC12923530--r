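#' Convert a base-pair span to a physical distance
#'
#' Multiplies a spacing in bp by the helical rise.  B-form DNA rises
#' ~3.4 Angstrom per base pair, so the 21-bp spacing between the two
#' modified cytosines of the bipartite site corresponds to about 71
#' Angstrom — the span a nuclease dimer must bridge to engage both
#' half-sites.
#'
#' @param n_bp Number of base pairs (non-negative).
#' @param rise Helical rise in Angstrom per bp (default 3.4, B-form).
#' @return Span in Angstrom.
#' @examples
#' bp_to_angstrom(21)  # 71.4
#' @export
bp_to_angstrom <- function(n_bp, rise = 3.4) {
  if (any(n_bp < 0)) stop("n_bp must be non-negative")
  if (any(rise <= 0)) stop("rise must be positive")
  n_bp * rise
}

#' Geometry report for a recognition spacing
#'
#' Packages the bp-to-Angstrom conversion together with the reference
#' distances relevant to a dimer-recognition model: the intra-dimer
#' distance between the two engaged modified cytosines (~53 Angstrom in
#' the crystal) and the minimum inter-dimer distance (>80 Angstrom).
#' These constants are carried as annotations only; no structural
#' computation is performed.
#'
#' @param spacing_bp Site spacing in bp (default 21).
#' @param rise Helical rise in Angstrom/bp (default 3.4).
#' @return List of class `GeometryReport` with `spacing_bp`,
#'   `rise_per_bp`, `span_angstrom`, `reference_distances`.
#' @export
geometry_report <- function(spacing_bp = 21L, rise = 3.4) {
  structure(list(spacing_bp = as.integer(spacing_bp), rise_per_bp = rise,
                 span_angstrom = bp_to_angstrom(spacing_bp, rise),
                 reference_distances = c(intra_dimer = 53,
                                         inter_dimer_min = 80)),
            class = "GeometryReport")
}

#' @export
print.GeometryReport <- function(x, ...) {
  cat(sprintf("GeometryReport: %d bp x %.2f A/bp = %.1f A\n",
              x$spacing_bp, x$rise_per_bp, x$span_angstrom))
  invisible(x)
}

#' Coverage depletion fold between a target and a control genome
#'
#' Ratio of control to target read density on library-size-normalised
#' per-kb scales, with a pseudocount guarding against empty bins — the
#' summary behind "the modified genome is severely depleted relative to
#' the host".  Swapping target and control inverts the fold when the
#' pseudocount terms match.
#'
#' @param target_reads_per_kb,control_reads_per_kb Non-negative
#'   normalised densities.
#' @param pseudocount Strictly positive stabiliser (default 0.5).
#' @return Depletion fold (>1 means the target is depleted).
#' @examples
#' depletion_fold(10, 1000)  # ~95.3
#' @export
depletion_fold <- function(target_reads_per_kb, control_reads_per_kb,
                           pseudocount = 0.5) {
  if (pseudocount <= 0) stop("pseudocount must be strictly positive")
  if (any(target_reads_per_kb < 0) || any(control_reads_per_kb < 0))
    stop("densities must be non-negative")
  (control_reads_per_kb + pseudocount) / (target_reads_per_kb + pseudocount)
}

#' Binned coverage comparison between two genomes
#'
#' Tiles each genome with fixed-width bins, counts fragment midpoints per
#' bin, normalises to reads per kb per million counted fragments across
#' both genomes, and summarises the overall depletion of the target
#' relative to the control via [depletion_fold()] on the mean densities.
#'
#' @param target_intervals,control_intervals Data frames with `start`,
#'   `end` (0-based half-open fragment intervals).
#' @param target_length,control_length Genome lengths in bp.
#' @param bin Bin width in bp (default 1000).
#' @param pseudocount Passed to [depletion_fold()].
#' @return List of class `CoverageComparison` with `bins_target`,
#'   `bins_control` (data frames `start`, `end`, `count`, `density`),
#'   `depletion_fold`, `bin`, `pseudocount`.
#' @export
coverage_comparison <- function(target_intervals, target_length,
                                control_intervals, control_length,
                                bin = 1000L, pseudocount = 0.5) {
  stopifnot(bin >= 1L)
  bin_one <- function(iv, L) {
    edges <- seq(0L, L, by = bin)
    if (edges[length(edges)] < L) edges <- c(edges, L)
    mid <- (as.numeric(iv$start) + as.numeric(iv$end)) / 2
    idx <- findInterval(mid, edges, rightmost.closed = TRUE)
    nb <- length(edges) - 1L
    count <- tabulate(idx, nbins = nb)
    data.frame(start = edges[-length(edges)], end = edges[-1L],
               count = count)
  }
  bt <- bin_one(target_intervals, target_length)
  bc <- bin_one(control_intervals, control_length)
  total <- sum(bt$count) + sum(bc$count)
  per_million <- if (total > 0) 1e6 / total else 0
  bt$density <- bt$count / ((bt$end - bt$start) / 1000) * per_million
  bc$density <- bc$count / ((bc$end - bc$start) / 1000) * per_million
  structure(list(bins_target = bt, bins_control = bc,
                 depletion_fold = depletion_fold(mean(bt$density),
                                                 mean(bc$density),
                                                 pseudocount),
                 bin = as.integer(bin), pseudocount = pseudocount),
            class = "CoverageComparison")
}

#' Plaque counts from a serial-dilution titration
#'
#' @param count Plaques counted on the plate (non-negative integer).
#' @param dilution Dilution factor of the plated aliquot, expressed as the
#'   inverse of the dilution (e.g. `1e-6` for a 10^-6 dilution).
#' @param volume_ml Plated volume in mL (default 0.1).
#' @return List of class `PlateCounts` with `count`, `dilution`,
#'   `volume_ml`, `titer` (PFU/mL = count / dilution / volume).
#' @export
plate_counts <- function(count, dilution, volume_ml = 0.1) {
  if (count < 0) stop("count must be non-negative")
  if (dilution <= 0 || volume_ml <= 0)
    stop("dilution and volume must be positive")
  structure(list(count = count, dilution = dilution, volume_ml = volume_ml,
                 titer = count / dilution / volume_ml),
            class = "PlateCounts")
}

#' Efficiency of plating from test and control titrations
#'
#' EOP is the ratio of the phage titer on the defended (test) host to the
#' titer on the permissive control; `log10_reduction = -log10(eop)`
#' summarises the strength of the defence.  A zero test count cannot give
#' a titer, so the standard convention is applied: the titer is bounded by
#' substituting a count of 1 and the result is reported as an upper bound
#' with `censored = TRUE`.
#'
#' @param test,control [plate_counts()] objects; the control count must be
#'   positive.
#' @return List of class `PlatingResult` with `eop`, `log10_reduction`,
#'   `censored` (TRUE when the EOP is a "<" upper bound), `test_titer`,
#'   `control_titer`.
#' @examples
#' efficiency_of_plating(plate_counts(3, 1e-1), plate_counts(3, 1e-6))
#' @export
efficiency_of_plating <- function(test, control) {
  stopifnot(inherits(test, "PlateCounts"), inherits(control, "PlateCounts"))
  if (control$count == 0) stop("control plate has zero plaques: no titer")
  censored <- test$count == 0
  test_titer <- if (censored) 1 / test$dilution / test$volume_ml
                else test$titer
  eop <- test_titer / control$titer
  structure(list(eop = eop, log10_reduction = -log10(eop),
                 censored = censored, test_titer = test_titer,
                 control_titer = control$titer),
            class = "PlatingResult")
}

#' @export
print.PlatingResult <- function(x, ...) {
  cat(sprintf("PlatingResult: EOP %s%.3g (%.2f log10 reduction%s)\n",
              if (x$censored) "< " else "", x$eop, x$log10_reduction,
              if (x$censored) ", zero-count bound" else ""))
  invisible(x)
}
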