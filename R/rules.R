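#' Bipartite recognition and cleavage rule
#'
#' Describes the geometry of a bipartite modification-dependent cut site.
#' The enzyme recognises two modified cytosines on opposite strands: a
#' top-strand modified C at position `p` and a bottom-strand modified C
#' paired with the top-strand G at `p + s`.  Each strand is nicked `u`
#' intervening bases downstream (5' to 3') of its own modified C, which on
#' the top strand places the nick boundary at `p + u + 1` and on the bottom
#' strand at `p + v + 1`, where `v = s - u - 1` is the number of intervening
#' bases between the top-strand nick and the distal conserved G.  The
#' default geometry is the `CN11/N9G` consensus: `u = 11`, `v = 9`,
#' `s = 21`, leaving a 2-nt 3' overhang (`overhang = u - v`; positive means
#' 3', negative 5', zero blunt).
#'
#' `s = u + v + 1` is enforced because the three parameters describe one
#' site jointly (C, `u` spacer bases, nick, `v` spacer bases, G — the site
#' spans `s + 1` bases).  Hypothetical enzymes that decouple spacing from
#' nick placement can be expressed with `enforce_spacing = FALSE`.
#'
#' @param u Intervening bases between the modified C and the nick on its
#'   own strand (modified-strand offset; default 11).
#' @param v Intervening bases between the nick and the distal conserved
#'   base on the same strand (other-strand offset; default 9).
#' @param s Top-strand distance between the two modified cytosines
#'   (default `u + v + 1` = 21).
#' @param required_classes Modification classes both half-sites must carry
#'   for the site to be recognised (default `hm5C` and `ghm5C`; `C` and
#'   `m5C` substrates are not cleaved).
#' @param efficiency Named vector mapping each modification class to a
#'   per-site cleavage probability in `[0, 1]`.  A site's efficiency is the
#'   minimum over its two half-site classes (both must engage).
#' @param enforce_spacing Enforce `s == u + v + 1` (default `TRUE`).
#' @return An object of class `RecognitionRule` with fields `u`, `v`, `s`,
#'   `overhang`, `required_classes`, `efficiency`.
#' @examples
#' recognition_rule()            # CN11/N9G, 2-nt 3' overhang
#' recognition_rule(u = 5, v = 5) # blunt cutter
#' @export
recognition_rule <- function(u = 11L, v = 9L, s = u + v + 1L,
                             required_classes = c("hm5C", "ghm5C"),
                             efficiency = c(C = 0, m5C = 0,
                                            hm5C = 1, ghm5C = 1),
                             enforce_spacing = TRUE) {
  u <- as.integer(u); v <- as.integer(v); s <- as.integer(s)
  if (u < 0L || v < 0L) stop("offsets u and v must be non-negative")
  if (enforce_spacing && s != u + v + 1L)
    stop("spacing must satisfy s = u + v + 1 (got s=", s,
         ", u=", u, ", v=", v, ")")
  if (!all(required_classes %in% MOD_CLASSES))
    stop("unknown required class")
  eff <- setNames(rep(0, length(MOD_CLASSES)), MOD_CLASSES)
  eff[names(efficiency)] <- efficiency
  if (any(eff < 0 | eff > 1)) stop("efficiencies must lie in [0, 1]")
  structure(list(u = u, v = v, s = s, overhang = u - v,
                 required_classes = required_classes, efficiency = eff),
            class = "RecognitionRule")
}

#' @export
print.RecognitionRule <- function(x, ...) {
  pol <- if (x$overhang > 0) "3'" else if (x$overhang < 0) "5'" else "blunt"
  cat(sprintf("RecognitionRule CN%d/N%dG: s=%d, u=%d, v=%d, overhang %d nt (%s)\n",
              x$u, x$v, x$s, x$u, x$v, abs(x$overhang), pol))
  cat("  required classes:", paste(x$required_classes, collapse = ", "), "\n")
  eff <- x$efficiency[x$efficiency > 0]
  cat("  efficiency:",
      if (length(eff)) paste(sprintf("%s=%g", names(eff), eff), collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
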