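# Independent brute-force site scanner: tests every candidate position p
# one at a time with direct string and track lookups.  Deliberately naive
# (per-position loop, no vectorised shortcuts shared with the package
# scanner) so it can serve as an oracle.
oracle_sites <- function(genome, rule) {
  L <- nchar(genome$seq)
  cls <- setNames(genome$mods$mod,
                  paste(genome$mods$pos, genome$mods$strand))
  hits <- integer(0)
  if (L < rule$s + 1L) return(hits)
  for (p in 0:(L - rule$s - 1L)) {
    if (substr(genome$seq, p + 1L, p + 1L) != "C") next
    if (substr(genome$seq, p + rule$s + 1L, p + rule$s + 1L) != "G") next
    ct <- cls[paste(p, "top")]
    cb <- cls[paste(p + rule$s, "bottom")]
    if (is.na(ct) || is.na(cb)) next
    if (ct %in% rule$required_classes && cb %in% rule$required_classes)
      hits <- c(hits, p)
  }
  hits
}

# Deterministic genome carrying n_sites copies of the (u, v) bipartite
# site on random background, each site explicitly (and exclusively)
# modified.  Inter-site spacers are jittered (a perfectly periodic tandem
# array would let cross-site coincidences pile up at one spurious spacing)
# but stay wide enough that no cut overlaps the next and every nick keeps
# a 20-bp flank inside the genome.
make_rule_genome <- function(u, v, n_sites = 55L, seed = 1L, pad = 25L,
                             mod_class = "hm5C") {
  s <- u + v + 1L
  set.seed(seed)
  spacers <- sample(18:44, n_sites, replace = TRUE)
  ps <- pad + cumsum(c(0L, (s + 1L + spacers)[-n_sites]))  # 0-based sites
  L <- ps[n_sites] + s + 1L + pad
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  bases[ps + 1L] <- "C"
  bases[ps + s + 1L] <- "G"
  g <- modified_genome(paste(bases, collapse = ""))
  sites <- data.frame(pos = c(ps, ps + s),
                      strand = rep(c("top", "bottom"), each = n_sites))
  apply_modification_scheme(
    g, modification_scheme("explicit", mod_class = mod_class, sites = sites))
}

# 22-mer single-site construct from the consensus geometry: top C at 0,
# top G at 21, everything else A/T, with the given marks.
make_single_site_22mer <- function(marks) {
  seq <- paste0("C", strrep("A", 9), strrep("T", 11), "G")
  g <- modified_genome(seq)
  if (nrow(marks) == 0L) return(g)
  apply_modification_scheme(
    g, modification_scheme("explicit", sites = marks))
}
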