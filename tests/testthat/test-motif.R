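# PWM parsing, similarity scoring, scanning and enrichment scores.

test_that("TRANSFAC parsing normalizes counts with the requested pseudocount", {
  block <- c("ID TEST_01", "P0 A C G T", "01 10 0 0 0", "XX", "//")
  p0 <- parse_motifs(block, pseudocount = 0)[[1]]
  expect_equal(p0$length, 1L)
  expect_equal(unname(p0$freqs[1, ]), c(1, 0, 0, 0))
  p1 <- parse_motifs(block, pseudocount = 1)[[1]]
  expect_equal(unname(p1$freqs[1, ]), c(11, 1, 1, 1) / 14)
  expect_equal(parse_motifs(character(0)), list())
  expect_error(parse_motifs(c("ID X", "01 1 2 x 4", "//")), "non-numeric")
  expect_error(parse_motifs(c("ID X", "01 1 2", "//")), "4 base")
})

test_that("JASPAR records parse with labelled or bare rows", {
  txt <- c(">MA0001.1 test",
           "A [ 4 19  0 ]",
           "C [16  0 20 ]",
           "G [ 0  1  0 ]",
           "T [ 0  0  0 ]")
  p <- parse_motifs(txt, format = "jaspar", pseudocount = 0)[[1]]
  expect_equal(p$id, "MA0001.1")
  expect_equal(p$length, 3L)
  expect_equal(unname(p$freqs[1, ]), c(4, 16, 0, 0) / 20)
  # shuffled base labels are honoured
  txt2 <- c(">M2", "T [ 0 0 ]", "A [ 10 0 ]", "G [ 0 10 ]", "C [ 0 0 ]")
  p2 <- parse_motifs(txt2, pseudocount = 0)[[1]]
  expect_equal(pwm_consensus(p2), "AG")
})

test_that("write_motifs / parse_motifs round-trips matrices and cutoffs", {
  pws <- lapply(1:3, function(k) random_pwm(paste0("M", k), 5 + k, seed = k))
  pws[[2]]$cutoff <- 0.8123456789
  path <- withr::local_tempfile(fileext = ".txt")
  write_motifs(pws, path)
  back <- parse_motifs(path)
  expect_length(back, 3)
  for (k in 1:3) {
    expect_equal(back[[k]]$id, pws[[k]]$id)
    expect_equal(back[[k]]$freqs, pws[[k]]$freqs, tolerance = 1e-12)
    expect_equal(back[[k]]$info, pws[[k]]$info, tolerance = 1e-12)
    expect_equal(back[[k]]$cutoff, pws[[k]]$cutoff)
  }
})

test_that("match_score spans [0, 1] with consensus at 1 and anti-consensus at 0", {
  p <- pwm("AC", rbind(c(8, 1, 1, 0), c(1, 7, 1, 1)), pseudocount = 0)
  expect_equal(match_score(p, "AC"), 1.0)
  # anti-consensus: per-position minimum-weight bases
  worst <- paste(BASES[apply(t(p$freqs) * rep(p$info, each = 4), 2, which.min)],
                 collapse = "")
  expect_equal(match_score(p, worst), 0.0)
  expect_error(match_score(p, "ACG"), "length")
})

test_that("match_score agrees with the hand-computed weighted formula", {
  p <- pwm("MIX", rbind(c(.5, .2, .2, .1),
                        c(.1, .6, .2, .1),
                        c(.25, .3, .25, .2)))
  for (w in c("ACG", "TTT", "GCA", "CAC"))
    expect_equal(match_score(p, w), oracle_match(p, w), tolerance = 1e-12)
})

test_that("match_score is invariant to rescaling the information weights", {
  p <- random_pwm("M", 6, seed = 11)
  p2 <- p
  p2$info <- p$info * 7.5
  for (w in vapply(1:5, function(i) random_dna(6, i + 100), character(1)))
    expect_equal(match_score(p, w), match_score(p2, w), tolerance = 1e-12)
})

test_that("ambiguous bases contribute the position's mean frequency", {
  p <- pwm("AMB", rbind(c(.4, .3, .2, .1), c(.7, .1, .1, .1)))
  sN <- match_score(p, "NA")
  w <- t(p$freqs) * rep(p$info, each = 4)
  expected <- (mean(w[, 1]) + unname(w["A", 2]) - sum(apply(w, 2, min))) /
    (sum(apply(w, 2, max)) - sum(apply(w, 2, min)))
  expect_equal(sN, expected, tolerance = 1e-12)
})

test_that("scan reports planted consensus and reverse-complement hits", {
  p <- pwm("AC", rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)))
  h <- scan_hits(p, "ACGGACGGAC", cutoff = 0.9)
  expect_equal(h$start[h$strand == "+"], c(0L, 4L, 8L))
  expect_equal(h$end, h$start + 2L)
  rc <- scan_hits(p, "GT", cutoff = 0.9)
  expect_equal(nrow(rc), 1L)
  expect_equal(rc$start, 0L)
  expect_equal(rc$strand, "-")
  none <- scan_hits(p, "GGGGGG", cutoff = 0.9)
  expect_equal(nrow(none), 0L)
  # sequence shorter than the motif: empty, not an error
  expect_equal(nrow(scan_hits(p, "A", cutoff = 0.5)), 0L)
})

test_that("scan equals the brute-force window enumeration oracle", {
  for (k in 1:6) {
    p <- random_pwm(paste0("M", k), 4 + (k %% 4), seed = 20 + k)
    seqs <- vapply(1:3, function(i) random_dna(50 + 30 * i, 300 + 10 * k + i),
                   character(1))
    for (s in seqs) {
      for (cutoff in c(0.6, 0.85)) {
        got <- scan_hits(p, s, cutoff = cutoff)
        want <- oracle_scan(p, s, cutoff)
        expect_equal(nrow(got), nrow(want))
        expect_equal(got$start, want$start)
        expect_equal(got$strand, want$strand)
        expect_equal(got$score, want$score, tolerance = 1e-9)
      }
    }
  }
})

test_that("enrichment is additive over non-matching spacers and strand-symmetric", {
  p <- pwm("ACGT", rbind(c(1, 0, 0, 0), c(0, 1, 0, 0),
                         c(0, 0, 1, 0), c(0, 0, 0, 1)))
  p$cutoff <- 0.95
  s1 <- "TTACGTTT"
  s2 <- "GACGTG"
  spacer <- "CCCCCCCC"
  e <- enrichment_score
  expect_equal(e(p, paste0(s1, spacer, s2)), e(p, s1) + e(p, s2),
               tolerance = 1e-9)
  for (i in 1:5) {
    s <- random_dna(80, 500 + i)
    expect_equal(e(p, s), e(p, oracle_revcomp(s)), tolerance = 1e-9)
  }
})

test_that("enrichment sums above-cutoff hit scores and requires a cutoff", {
  p <- pwm("SITE", rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0)))
  expect_error(enrichment_score(p, "ACGACG"), "cutoff")
  p$cutoff <- 0.9
  expect_equal(enrichment_score(p, "TTTTTTTT"), 0)
  # 4 planted consensus sites, each scoring exactly 1 (the reverse
  # complement CGT never occurs in this sequence)
  p2 <- pwm("SITE2", rbind(c(1, 0, 0, 0), c(1, 0, 0, 0), c(0, 1, 0, 0)))
  p2$cutoff <- 0.9
  expect_equal(enrichment_score(p2, "AACGGAACGGAACGGAACGG"), 4.0)
})

test_that("minFN cutoff calibration is seeded and matches exact enumeration", {
  # deterministic matrix: every true site is consensus
  pd <- pwm("DET", rbind(c(1, 0, 0, 0), c(0, 0, 0, 1)))
  expect_equal(calibrate_minfn_cutoff(pd, seed = 1), 1 - 1e-9)
  p <- random_pwm("CAL", 5, seed = 31)
  c1 <- calibrate_minfn_cutoff(p, target_fnr = 0.1, seed = 7)
  c2 <- calibrate_minfn_cutoff(p, target_fnr = 0.1, seed = 7)
  expect_identical(c1, c2)
  expect_gte(c1, 0); expect_lt(c1, 1)
  # exact oracle: enumerate all 4^L windows with their model probabilities
  L <- p$length
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  probs <- apply(grid, 1, function(g) prod(p$freqs[cbind(seq_len(L), g)]))
  scores <- apply(grid, 1, function(g)
    oracle_match(p, paste(BASES[g], collapse = "")))
  o <- order(scores)
  exact_q <- scores[o][which(cumsum(probs[o]) >= 0.1)[1]]
  expect_equal(c1, exact_q, tolerance = 0.03)
})
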