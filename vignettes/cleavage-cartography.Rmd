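---
title: "Cleavage-site cartography for bipartite modification-dependent endonucleases"
author: "cleavemap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleavage-site cartography for bipartite modification-dependent endonucleases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleavemap)
```

## Scope and model

`cleavemap` reconstructs the cut-site geometry of a bipartite
modification-dependent restriction endonuclease (MDRE) from mapped
fragment ends, and provides the simulator needed to validate that
reconstruction against known ground truth.

The recognition model is a two-anchor site: a top-strand modified
cytosine at position $p$ and a bottom-strand modified cytosine whose
partner base is the top-strand G at $p + s$. Each strand is nicked $u$
intervening bases 3′ of its own modified C; equivalently, $v = s - u - 1$
bases separate the top-strand nick from the distal G. In 0-based
half-open coordinates (a boundary $b$ lies between bases $b-1$ and $b$)
the nicks are

$$\text{top} = p + u + 1, \qquad \text{bottom} = p + v + 1,$$

and the signed overhang is $o = u - v$: positive for a 3′ overhang,
negative for 5′, zero for blunt. The default rule is `CN11/N9G`
($u = 11$, $v = 9$, $s = 21$, $o = +2$), requiring both cytosines to be
5hmC or 5ghmC; C- or 5mC-only substrates and singly modified sites are
never cleaved, matching the enzyme class's substrate panel. Note the
site is symmetric — each modified C sees 11 bases to the nick on its own
strand — which is what makes recognition by a homodimer geometrically
natural.

Assumptions worth stating explicitly:

* **Independent Bernoulli cutting.** Each recognised site is cut
  independently with probability $\min$ of its two half-site class
  efficiencies (both half-sites must engage). Processivity or
  single-turnover behaviour is not modelled.
* **Opposite-strand pairs only.** The consensus is read literally: the
  two modified cytosines sit on opposite strands at spacing $s$.
  Same-strand pairs are not recognised.
* **Linear genomes.** T-even virion DNA is linear; circular topology and
  terminal redundancy are not modelled.
* **Greedy overlap resolution.** Cuts are accepted left-to-right; a cut
  closer than $|o| + 1$ bp to the previously accepted one is skipped.
  This is deterministic given the site draws and guarantees every
  fragment keeps a positive-length duplex core.

## From fragment ends back to the cut

End repair (chew-back of 3′ overhangs, fill-in of 5′) maps each fragment
to a blunt interval. The central convention — stated here prominently
because every downstream number depends on it — is the **signed gap**
between an upstream interval's end $e$ and a downstream interval's start
$st$ in half-open coordinates, $g = st - e$: abutting blunt fragments
give $g = 0$, chewed 3′ overhangs $g = +o$, filled 5′ overhangs
$g = -|o|$. The modal gap calls the overhang; ties break toward smaller
$|g|$, then the positive sign (the smallest chemistry consistent with
the data, preferring the commoner 3′ case).

Nick reconstruction inverts the repair: the downstream mapped start is
the unshifted top-strand nick and the paired upstream end the
bottom-strand nick. Loci are accepted only when the observed gap equals
the called one exactly; mismatched pairings are counted in a diagnostics
field rather than piled up. PCR duplicates are collapsed before pairing.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| genome `length` | 100,000 | bp | desk-scale stand-in for a ~168-kb phage genome; ~3,000 sites at the default rule, enough for exact modal statistics in seconds |
| `gc` | 0.35 | fraction | T-even-like base composition; also keeps background column frequencies ≤ ~0.33, far from the conservation threshold |
| pairing `window` | 10 | bp | real restriction overhangs are ≤ ~6 nt; a small window keeps coincidental end/start pairings rare. Must be raised to cover the overhang range when sweeping exotic rules (the tests use 16 for overhangs up to 15 nt) |
| flank width `W` | 20 | bp | covers the full site ($u_{max}+1$ columns left, $v_{max}+1$ right) with margin |
| conservation `threshold` | 0.9 | frequency | anchor columns are exactly 1.0 under full modification while background columns sit near GC-derived frequencies; 0.9 separates them with a wide margin on ≥ 50 sites |
| offset search `s_max` | 30 | bp | upper bound on plausible $u$, $v$; candidates beyond it are noise |
| helical `rise` | 3.4 | Å/bp | canonical B-form; configurable for A-form analyses |
| `pseudocount` (coverage) | 0.5 | reads/kb | keeps depletion folds finite on empty bins |

Offsets count **intervening bases** (C, then $u$ bases, then the nick),
matching how such geometries are quoted; the alternative convention of
counting to the cut base would shift every offset by one and was
rejected for that reason.

## The offset estimator

With every cytosine modified, the "nearest modified C upstream of the
nick" is usually an incidental cytosine, not the recognition anchor —
its distance is approximately geometric and its mode would be 0. The
estimator therefore enumerates *all* modified cytosines within `s_max`
of each nick (upstream top-strand for $u$, downstream bottom-strand for
$v$, and all upstream/downstream pairs for $s$) and takes the modal
offset. The true anchor contributes its offset at essentially every
locus, while incidental cytosines spread uniformly, so under full
digestion the mode recovers $(u, v, s)$ exactly; loci with no tracked
modification within `s_max` on one side are excluded and counted. One
caveat: a perfectly periodic tandem array of sites can make *cross-site*
pairs pile up at a single spurious spacing; random genomes (and the
jittered-spacing test fixtures) do not have this degeneracy.

## What the simulator does and does not emulate

The generator draws i.i.d. bases and marks cytosines per scheme (`all`,
`fraction`, `explicit`, `none`); digestion is error-free and so is the
emulated 2 × 150 bp paired-end library (coordinates travel in read
names). Real data additionally carry sequencing errors, mapping
ambiguity, incomplete dephosphorylation, chewed termini and uneven
coverage — none of which are modelled. Passing the round-trip tests
therefore demonstrates that the *inference logic* is exact on clean
input, not that real libraries will yield support values this high; on
real data the modal statistics are the robust part, the support fraction
is not. Alignment, duplicate marking on BAMs, and sequencing-error
models are deliberately external: the real-data entry point is
deduplicated fragment intervals as BED.

## Numerical and design choices

* **RNG.** One integer master seed; each stage (genome, modification,
  digestion, reads) derives an independent 32-bit stream from
  `(master, stage name)`, so stages are reorderable without silent
  coupling and every output file is byte-reproducible.
* **$s = u + v + 1$ is enforced** in the rule constructor because the
  three parameters describe one site jointly; decoupling them is an
  explicit flag for hypothetical enzymes.
* **Degenerate inputs.** Empty gap histograms signal "no cleavage
  detected" as an error rather than a blunt call; PFMs refuse empty
  pileups; plating with a zero control count is an error while a zero
  *test* count returns a censored upper bound (count substituted by 1,
  flagged), the standard titration convention.
* **No pseudocounts in PFMs by default**: exact 1.0 anchors matter more
  than smoothing at simulation scale; a pseudocount option exists for
  sparse real data.
* **Fragment representation.** Fragments store each strand's extent
  separately; end chemistry is derived, not annotated, which makes the
  repair arithmetic (`max` of starts for chewed ends, `min` for filled)
  a two-line function and the conservation law
  $\sum \text{repaired lengths} = L - k\,o$ provable by telescoping.
* **Problem sizes.** The bundled analyses run on 10–100-kb genomes with
  ~50–3,000 sites; all modal statistics are exact there, and the whole
  default pipeline takes a few seconds.

## Worked run

```{r pipeline}
report <- run_cartography(length = 30000L, gc = 0.35, seed = 11L)
report
report$call
head(report$params$u_hist)
```

The gap histogram, nick pileup, PFM (with per-column information in
bits) and JSON report can be exported deterministically:

```{r outputs, eval = FALSE}
write_cartography_outputs(report, "cartography_out/")
```

## Known limitations

* Site recognition follows the opposite-strand consensus literally;
  enzymes tolerating same-strand modification pairs would need a second
  scanner.
* The gap statistic assumes fragment ends are mapped at single-base
  resolution; soft-clipped or trimmed alignments would blur the mode
  before this package ever sees them.
* Coverage depletion at real-genome scale (target vs. host) requires
  real sequencing depth; `coverage_comparison()` reproduces the
  normalisation logic, not the published tracks.
* Structural quantities (the ~53 Å intra-dimer and > 80 Å inter-dimer
  references) are carried as annotations only; no coordinate handling
  is performed.
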