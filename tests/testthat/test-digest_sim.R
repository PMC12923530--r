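rule_default <- recognition_rule()

test_that("recognition rule enforces its joint geometry", {
  expect_identical(rule_default$s, 21L)
  expect_identical(rule_default$overhang, 2L)
  expect_error(recognition_rule(u = 11, v = 9, s = 20), "s = u \\+ v \\+ 1")
  relaxed <- recognition_rule(u = 11, v = 9, s = 20, enforce_spacing = FALSE)
  expect_identical(relaxed$s, 20L)
  expect_error(recognition_rule(u = -1, v = 9), "non-negative")
})

test_that("site scanning requires both modified half-sites of a cleavable class", {
  both_hm <- make_single_site_22mer(
    data.frame(pos = c(0, 21), strand = c("top", "bottom"), mod = "hm5C"))
  expect_identical(find_recognition_sites(both_hm, rule_default)$p, 0L)

  # 5mC is bound-but-not-cleaved chemistry: no site
  both_m5 <- make_single_site_22mer(
    data.frame(pos = c(0, 21), strand = c("top", "bottom"), mod = "m5C"))
  expect_identical(nrow(find_recognition_sites(both_m5, rule_default)), 0L)

  # a single modified half-site is not recognised
  one_hm <- make_single_site_22mer(
    data.frame(pos = 0, strand = "top", mod = "hm5C"))
  expect_identical(nrow(find_recognition_sites(one_hm, rule_default)), 0L)

  # unmodified genome: nothing
  none <- make_single_site_22mer(empty <- data.frame(
    pos = integer(0), strand = character(0), mod = character(0)))
  expect_identical(nrow(find_recognition_sites(none, rule_default)), 0L)
})

test_that("scanner matches the brute-force oracle on random genomes", {
  for (seed in c(101, 202, 303)) {
    g <- apply_modification_scheme(
      generate_genome(10000, gc = 0.35, seed = seed),
      modification_scheme("all"))
    expect_identical(find_recognition_sites(g, rule_default)$p,
                     oracle_sites(g, rule_default))
  }
  # and for a non-default geometry
  g <- apply_modification_scheme(
    generate_genome(5000, gc = 0.5, seed = 77),
    modification_scheme("all"))
  r <- recognition_rule(u = 4, v = 7)
  expect_identical(find_recognition_sites(g, r)$p, oracle_sites(g, r))
})

test_that("site list is invariant under reverse complementation", {
  g <- apply_modification_scheme(
    generate_genome(8000, gc = 0.35, seed = 13),
    modification_scheme("all"))
  fwd <- find_recognition_sites(g, rule_default)$p
  rc <- find_recognition_sites(reverse_complement_genome(g), rule_default)$p
  # a site at p maps to a site at L - 1 - (p + s) on the flipped genome
  L <- nchar(g$seq)
  expect_identical(sort(L - 1L - (fwd + rule_default$s)), rc)
})

test_that("cut positions follow the offset arithmetic", {
  cuts <- cut_positions(data.frame(p = 0L), rule_default)
  expect_identical(cuts$top_nick, 12L)
  expect_identical(cuts$bottom_nick, 10L)
  # translation invariance
  cuts100 <- cut_positions(data.frame(p = 100L), rule_default)
  expect_identical(c(cuts100$top_nick, cuts100$bottom_nick), c(112L, 110L))
  # blunt rule nicks coincide
  blunt <- cut_positions(data.frame(p = 5L), recognition_rule(u = 5, v = 5))
  expect_identical(blunt$top_nick, blunt$bottom_nick)
  # a nick outside the genome rejects the site
  kept <- cut_positions(data.frame(p = c(0L, 15L)), rule_default,
                        genome_length = 22L)
  expect_identical(kept$p, 0L)
})

test_that("digestion yields k+1 fragments with the rule's end chemistry", {
  g <- make_single_site_22mer(
    data.frame(pos = c(0, 21), strand = c("top", "bottom"), mod = "hm5C"))
  res <- simulate_digest(g, rule_default, seed = 1)
  expect_identical(nrow(res$cuts), 1L)
  expect_identical(nrow(res$fragments), 2L)
  fr <- res$fragments
  expect_identical(fr$left_end, c("blunt", "3prime"))
  expect_identical(fr$right_end, c("3prime", "blunt"))
  expect_identical(fr$top_end[1], 12L)
  expect_identical(fr$bottom_end[1], 10L)

  # no sites: one whole-genome blunt fragment
  res0 <- simulate_digest(modified_genome("ACGTACGT"), rule_default, seed = 1)
  expect_identical(nrow(res0$fragments), 1L)
  expect_identical(res0$fragments$left_end, "blunt")
  expect_identical(res0$fragments$right_end, "blunt")
  expect_identical(res0$fragments$top_end, 8L)
})

test_that("no cleavage on C-only or 5mC-only tracks", {
  g <- generate_genome(20000, gc = 0.35, seed = 4)
  for (cls in c("C", "m5C")) {
    marked <- apply_modification_scheme(
      g, modification_scheme("all", mod_class = cls))
    res <- simulate_digest(marked, rule_default, seed = 1)
    expect_identical(nrow(res$cuts), 0L)
    expect_identical(end_repair(res),
                     structure(data.frame(start = 0L, end = 20000L),
                               class = c("RepairedIntervals", "data.frame")))
  }
})

test_that("per-site cleavage probability is the minimum over both classes", {
  half_rule <- recognition_rule(efficiency = c(hm5C = 0.5, ghm5C = 1))
  g200 <- make_rule_genome(11, 9, n_sites = 200, seed = 31)
  stopifnot(nrow(find_recognition_sites(g200, half_rule)) == 200L)
  total <- 0L
  for (rep in 1:400)
    total <- total + nrow(simulate_digest(g200, half_rule, seed = rep)$cuts)
  # exact 99.9% binomial interval for the pooled Bernoulli(0.5) draws
  expect_gte(total, qbinom(0.0005, 400L * 200L, 0.5))
  expect_lte(total, qbinom(0.9995, 400L * 200L, 0.5))

  # min rule: one ghm5C half-site does not rescue an uncleavable partner
  mixed <- make_single_site_22mer(
    data.frame(pos = c(0, 21), strand = c("top", "bottom"),
               mod = c("ghm5C", "m5C")))
  expect_identical(nrow(simulate_digest(mixed, rule_default, seed = 1)$cuts),
                   0L)
})

test_that("end repair chews back 3' overhangs and fills in 5' overhangs", {
  g <- make_single_site_22mer(
    data.frame(pos = c(0, 21), strand = c("top", "bottom"), mod = "hm5C"))
  rep3 <- end_repair(simulate_digest(g, rule_default, seed = 1))
  expect_identical(rep3$start, c(0L, 12L))
  expect_identical(rep3$end, c(10L, 22L))

  # mirrored 5' rule (u = 9, v = 11): repaired intervals cover the
  # protrusion, extending 2 bp past the shorter strand on each side
  rule5 <- recognition_rule(u = 9, v = 11)
  res5 <- simulate_digest(g, rule5, seed = 1)
  expect_identical(res5$cuts$top_nick, 10L)
  expect_identical(res5$cuts$bottom_nick, 12L)
  rep5 <- end_repair(res5)
  expect_identical(rep5$start, c(0L, 10L))
  expect_identical(rep5$end, c(12L, 22L))

  # blunt fragments are untouched
  blunt <- end_repair(simulate_digest(g, recognition_rule(u = 10, v = 10),
                                      seed = 1))
  expect_identical(blunt$start, c(0L, 11L))
  expect_identical(blunt$end, c(11L, 22L))
})

test_that("mass conservation: repaired lengths sum to L - k*o by chemistry", {
  cases <- list(c(11L, 9L), c(9L, 11L), c(10L, 10L), c(3L, 0L), c(0L, 6L))
  for (uv in cases) {
    g <- make_rule_genome(uv[1], uv[2], n_sites = 40, seed = 17)
    res <- simulate_digest(g, recognition_rule(u = uv[1], v = uv[2]),
                           seed = 1)
    k <- nrow(res$cuts)
    expect_gt(k, 0)
    o <- uv[1] - uv[2]
    repaired <- end_repair(res)
    expect_identical(sum(repaired$end - repaired$start),
                     nchar(g$seq) - k * o)
  }
})

test_that("read pairs are the outer read-length bases of each interval", {
  g <- modified_genome("ACGTACGTAC")
  reads <- emit_read_pairs(data.frame(start = 0, end = 10), g,
                           read_len = 150)
  expect_identical(as.character(reads$mate1[[1]]), "ACGTACGTAC")
  expect_identical(as.character(reads$mate2[[1]]), "GTACGTACGT")

  # long interval: outermost mapped termini reproduce the interval ends
  gg <- generate_genome(400, gc = 0.5, seed = 8)
  rr <- emit_read_pairs(data.frame(start = 0, end = 300), gg, read_len = 150)
  expect_identical(as.character(rr$mate1[[1]]), substr(gg$seq, 1, 150))
  expect_identical(
    as.character(Biostrings::reverseComplement(rr$mate2[[1]])),
    substr(gg$seq, 151, 300))
  expect_identical(names(rr$mate1), "synthetic:0-300/1")

  # seeded twice: byte-identical FASTQ
  f1a <- withr::local_tempfile(); f2a <- withr::local_tempfile()
  f1b <- withr::local_tempfile(); f2b <- withr::local_tempfile()
  iv <- data.frame(start = c(0, 100), end = c(90, 350))
  emit_read_pairs(iv, gg, read_len = 150, seed = 5, fastq1 = f1a, fastq2 = f2a)
  emit_read_pairs(iv, gg, read_len = 150, seed = 5, fastq1 = f1b, fastq2 = f2b)
  expect_identical(readLines(f1a), readLines(f1b))
  expect_identical(readLines(f2a), readLines(f2b))
  expect_length(readLines(f1a), 8L)
})
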