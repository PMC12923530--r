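single_nick_pileup <- function(top, bottom, count = 1L) {
  call <- structure(list(length = abs(top - bottom),
                         polarity = if (top > bottom) "3prime"
                                    else if (top < bottom) "5prime"
                                    else "blunt",
                         support = 1, modal_gap = top - bottom),
                    class = "OverhangCall")
  structure(list(loci = data.frame(top = as.integer(top),
                                   bottom = as.integer(bottom),
                                   count = as.integer(count)),
                 flagged = 0L, call = call, window = 10L),
            class = "NickPileup")
}

test_that("a single observation yields a one-hot PFM matching the sequence", {
  set.seed(1)
  g <- generate_genome(44, gc = 0.5, seed = 33)
  pfm <- flank_pfm(single_nick_pileup(22, 20), g, W = 20)
  expect_identical(pfm$n_sites, 1L)
  expect_true(all(colSums(pfm$prob) - 1 < 1e-9))
  flank <- substr(g$seq, 3, 42)  # 20 bases either side of boundary 22
  chars <- strsplit(flank, "")[[1]]
  for (j in 1:40) expect_equal(unname(pfm$prob[chars[j], j]), 1.0)

  # nicks too close to an edge are dropped and counted
  pile2 <- single_nick_pileup(5, 3)
  expect_error(flank_pfm(pile2, g, W = 20), "genome end")
})

test_that("PFM columns always normalise to 1", {
  g <- apply_modification_scheme(
    generate_genome(30000, gc = 0.35, seed = 3),
    modification_scheme("all"))
  res <- simulate_digest(g, recognition_rule(), seed = 3)
  repaired <- end_repair(res)
  pile <- reconstruct_nicks(repaired, infer_overhang(gap_distribution(repaired)))
  pfm <- flank_pfm(pile, g, W = 20)
  expect_true(all(abs(colSums(pfm$prob) - 1) < 1e-9))
  # ground truth anchors: modified C 11 intervening bases left of the
  # nick, conserved G 9 intervening bases right
  expect_equal(unname(pfm$prob["C", "-12"]), 1.0)
  expect_equal(unname(pfm$prob["G", "10"]), 1.0)
})

test_that("column information matches closed-form relative entropy", {
  g <- generate_genome(44, gc = 0.5, seed = 33)
  pfm <- flank_pfm(single_nick_pileup(22, 20), g, W = 20)
  bits <- column_information(pfm)
  expect_equal(unname(bits), rep(2.0, 40))  # one-hot, uniform background

  # hand-built columns: uniform -> 0 bits; (0.5, 0.5, 0, 0) -> 1 bit
  pfm$prob[, 1] <- rep(0.25, 4)
  pfm$prob[, 2] <- c(0.5, 0.5, 0, 0)
  bits <- column_information(pfm)
  expect_equal(unname(bits[1]), 0.0)
  expect_equal(unname(bits[2]), 1.0)

  # bounded by log2(1/min q) and maximised by one-hot columns
  q <- c(0.1, 0.2, 0.3, 0.4)
  bits_q <- column_information(pfm, background = q)
  expect_true(all(bits_q >= -1e-12))
  expect_true(all(bits_q <= log2(1 / min(q)) + 1e-12))

  expect_error(column_information(pfm, background = c(0, 1, 1, 1) / 3),
               "positive")
})

test_that("consensus collapses to run-length notation with recovered offsets", {
  g <- apply_modification_scheme(
    generate_genome(50000, gc = 0.35, seed = 23),
    modification_scheme("all"))
  res <- simulate_digest(g, recognition_rule(), seed = 23)
  repaired <- end_repair(res)
  pile <- reconstruct_nicks(repaired, infer_overhang(gap_distribution(repaired)))
  cons <- consensus_call(flank_pfm(pile, g, W = 20), threshold = 0.9)
  expect_identical(cons$consensus, "CN11/N9G")
  expect_identical(cons$u_hat, 11L)
  expect_identical(cons$v_hat, 9L)
  expect_identical(cons$s_hat, 21L)
  expect_identical(cons$overhang_hat, 2L)
  expect_false(cons$flagged)

  # blunt cutter renders symmetric consensus
  gb <- make_rule_genome(5, 5, n_sites = 60, seed = 6)
  resb <- simulate_digest(gb, recognition_rule(u = 5, v = 5), seed = 1)
  repb <- end_repair(resb)
  pileb <- reconstruct_nicks(repb, infer_overhang(gap_distribution(repb)))
  consb <- consensus_call(flank_pfm(pileb, gb, W = 20), threshold = 0.9)
  expect_identical(consb$consensus, "CN5/N5G")
  expect_identical(consb$s_hat, 11L)

  # a uniform PFM has no conserved anchors and is flagged
  pfm_flat <- flank_pfm(pileb, gb, W = 10)
  pfm_flat$prob[] <- 0.25
  flat <- consensus_call(pfm_flat, threshold = 0.9)
  expect_true(flat$flagged)
  expect_true(is.na(flat$u_hat))

  expect_error(consensus_call(pfm_flat, threshold = 0.4), "threshold")
})

test_that("rule parameters are recovered from the ground-truth track", {
  g <- make_rule_genome(7, 3, n_sites = 60, seed = 11)
  rule <- recognition_rule(u = 7, v = 3)
  res <- simulate_digest(g, rule, seed = 2)
  repaired <- end_repair(res)
  pile <- reconstruct_nicks(repaired, infer_overhang(gap_distribution(repaired)))
  est <- infer_rule_parameters(pile, g)
  expect_identical(est$u, 7L)
  expect_identical(est$v, 3L)
  expect_identical(est$s, 11L)
  expect_identical(est$n_excluded, 0L)

  # a locus with no tracked modification nearby is excluded with a count
  pile$loci <- rbind(pile$loci,
                     data.frame(top = nchar(g$seq) - 25L,
                                bottom = nchar(g$seq) - 27L, count = 1L))
  est2 <- infer_rule_parameters(pile, g)
  expect_identical(est2$n_excluded, 1L)
  expect_identical(est2$u, 7L)

  expect_error(infer_rule_parameters(pile, generate_genome(100, seed = 1)),
               "track")
})

test_that("consensus is invariant to duplicate-fragment inflation", {
  g <- make_rule_genome(11, 9, n_sites = 60, seed = 19)
  res <- simulate_digest(g, recognition_rule(), seed = 1)
  repaired <- end_repair(res)
  inflated <- repaired[rep(seq_len(nrow(repaired)), times = 3), ]
  pile <- reconstruct_nicks(inflated,
                            infer_overhang(gap_distribution(inflated)))
  cons <- consensus_call(flank_pfm(pile, g, W = 20), threshold = 0.9)
  expect_identical(cons$u_hat, 11L)
  expect_identical(cons$v_hat, 9L)
})
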