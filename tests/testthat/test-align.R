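# Gapless alignment scores, exact null distributions, p-values.

test_that("alignment scores: uniform windows score zero, single-letter
           closed form holds, and random windows match a per-position
           oracle", {
  params <- alignment_params(probability_floor = 1e-12)
  unif <- matrix(1 / 20, 8, 20, dimnames = list(NULL, aa1))
  s <- target_sequence("s", "ACDEFGHIKLMN")
  for (o in c(0, 2, 4))
    expect_lt(abs(alignment_score(unif, s, o, params)), 1e-9)

  w <- matrix(c(0.5, rep(0.5 / 19, 19)), 1, 20, byrow = TRUE,
              dimnames = list(NULL, aa1))
  got <- alignment_score(w, target_sequence("s", "A"), 0, params)
  expect_equal(got, log(10), tolerance = 1e-6)

  # term-by-term summation oracle on seeded random windows
  params2 <- alignment_params()
  for (seed in 1:5) {
    w3 <- random_window(3, seed)
    tgt <- gen_sequence(30, seed = seed + 100)
    for (o in c(0, 7, 27)) {
      letters <- strsplit(tgt$residues, "")[[1]][o + 1:3]
      wf <- seqregister:::floor_rows(w3, params2$probability_floor)
      want <- sum(log(wf[cbind(1:3, match(letters, aa1))] / (1 / 20)))
      expect_equal(alignment_score(w3, tgt, o, params2), want,
                   tolerance = 1e-12)
    }
  }

  expect_error(alignment_score(w, target_sequence("s", "A"), 1, params),
               "out of range")
})

test_that("an X in the target contributes zero score", {
  params <- alignment_params()
  w <- random_window(3, 7)
  s_x <- target_sequence("sx", "AXC")
  s_a <- target_sequence("sa", "AAC")
  d <- alignment_score(w, s_x, 0, params) - alignment_score(w, s_a, 0, params)
  wf <- seqregister:::floor_rows(w, params$probability_floor)
  expect_equal(d, -log(unname(wf[2, "A"]) / (1 / 20)), tolerance = 1e-12)
})

test_that("best gapless alignment finds planted offsets and honours
           tie-breaking", {
  params <- alignment_params()
  tgt <- gen_sequence(60, seed = 5)
  letters <- strsplit(tgt$residues, "")[[1]]
  w <- degenerate_window(letters[8:19])  # subsequence at offset 7
  best <- best_gapless_alignment(w, list(tgt), params)
  expect_equal(best$offset, 7)
  expect_equal(best$n_offsets, 60 - 12 + 1)

  # degenerate 'A' rows against "AAAA": tie broken to offset 0
  wa <- degenerate_window(c("A", "A"))
  best_a <- best_gapless_alignment(wa, list(target_sequence("t", "AAAA")),
                                   params)
  expect_equal(best_a$offset, 0)

  expect_error(best_gapless_alignment(random_window(9, 1),
                                      list(target_sequence("t", "ACDEF")),
                                      params),
               "long enough")
})

test_that("best gapless alignment equals the exhaustive-scan oracle over
           sequence sets", {
  params <- alignment_params()
  seqs <- list(gen_sequence(40, seed = 11, id = "a"),
               gen_sequence(25, seed = 12, id = "b"),
               gen_sequence(33, seed = 13, id = "c"))
  for (seed in 1:100) {
    w <- random_window(5, seed)
    got <- best_gapless_alignment(w, seqs, params)
    want <- exhaustive_best(w, seqs, params)
    expect_identical(got$seq_id, want$seq_id)
    expect_identical(got$offset, want$offset)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("the null distribution reproduces closed forms and the L=2
           enumeration oracle", {
  params <- alignment_params(probability_floor = 1e-12)
  w1 <- matrix(c(0.5, rep(0.5 / 19, 19)), 1, 20, byrow = TRUE,
               dimnames = list(NULL, aa1))
  null1 <- null_score_distribution(w1, params)
  expect_equal(sum(null1$mass), 1, tolerance = 1e-9)
  # atom near log(10) with mass 0.05; remaining mass below zero
  vals <- (null1$offset + seq_along(null1$mass) - 1) * null1$step
  expect_equal(sum(null1$mass[vals > 2.29 & vals < 2.31]), 0.05,
               tolerance = 1e-12)
  expect_equal(sum(null1$mass[vals < 0]), 0.95, tolerance = 1e-9)

  # L = 2: exact enumeration over all 400 ordered residue pairs
  params2 <- alignment_params()
  w2 <- random_window(2, 21)
  null2 <- null_score_distribution(w2, params2)
  expect_equal(sum(null2$mass), 1, tolerance = 1e-9)
  lr <- log(seqregister:::floor_rows(w2, params2$probability_floor) / (1 / 20))
  bins <- floor(lr / params2$grid_step + 1e-9)
  enum <- outer(bins[1, ], bins[2, ], `+`)
  enum_mass <- table(as.integer(enum)) / 400
  got_nonzero <- null2$mass[null2$mass > 0]
  keys <- (null2$offset + which(null2$mass > 0) - 1)
  expect_equal(as.integer(names(enum_mass)), keys)
  expect_equal(as.numeric(enum_mass), got_nonzero, tolerance = 1e-12)

  # arbitrary seeded windows: total mass 1
  for (seed in 1:5)
    expect_equal(sum(null_score_distribution(random_window(6, seed),
                                             params2)$mass), 1,
                 tolerance = 1e-9)
})

test_that("binned tails are conservative: at least the exact tail (L = 2
           enumeration)", {
  params <- alignment_params()
  for (seed in c(3, 17)) {
    w2 <- random_window(2, seed)
    null2 <- null_score_distribution(w2, params)
    lr <- log(seqregister:::floor_rows(w2, params$probability_floor) /
                (1 / 20))
    exact <- as.numeric(outer(lr[1, ], lr[2, ], `+`))
    for (s in stats::quantile(exact, c(0.05, 0.25, 0.5, 0.75, 0.95, 0.999))) {
      exact_tail <- sum(exact >= s) / 400
      expect_gte(null_tail(null2, s) + 1e-12, exact_tail)
    }
  }
})

test_that("p-values follow the offset correction and its monotonicity", {
  # closed forms via a synthetic null with a known tail
  w1 <- matrix(c(0.5, rep(0.5 / 19, 19)), 1, 20, byrow = TRUE,
               dimnames = list(NULL, aa1))
  params <- alignment_params(probability_floor = 1e-12)
  null1 <- null_score_distribution(w1, params)
  expect_equal(alignment_pvalue(log(10), null1, 1), 0.05, tolerance = 1e-9)

  tail <- null_tail(null1, log(10))
  expect_equal(tail, 0.05, tolerance = 1e-12)
  # a two-letter peak of mass 0.3 each: tail 0.10 at score log(6)
  w01 <- matrix(c(0.3, 0.3, rep(0.4 / 18, 18)), 1, 20, byrow = TRUE,
                dimnames = list(NULL, aa1))
  null01 <- null_score_distribution(w01, params)
  expect_equal(null_tail(null01, log(6)), 0.10, tolerance = 1e-9)

  p_an <- 1 - (1 - 0.01)^100
  expect_equal(p_an, 0.63397, tolerance = 1e-4)

  # monotone in score and in M
  w <- random_window(6, 9)
  params2 <- alignment_params()
  null <- null_score_distribution(w, params2)
  ss <- seq(-6, 6, length.out = 25)
  pv <- vapply(ss, function(s) alignment_pvalue(s, null, 10), numeric(1))
  expect_true(all(diff(pv) <= 1e-12))
  pm <- vapply(c(1, 2, 10, 100, 1000),
               function(m) alignment_pvalue(1.5, null, m), numeric(1))
  expect_true(all(diff(pm) >= -1e-12))
  expect_true(all(pv > 0 & pv <= 1))
})

test_that("convolution tails agree with Monte-Carlo best-score frequencies",
{
  # The convolution is exact on the score lattice, so the Monte-Carlo draws
  # are binned identically (per-position floor); the comparison then
  # isolates the convolution and the offset correction.
  params <- alignment_params()
  set.seed(202)
  nmc <- 20000
  for (l in c(5, 10)) {
    w <- random_window(l, 50 + l)
    null <- null_score_distribution(w, params)
    tail_at <- function(k)
      sum(null$mass[(null$offset + seq_along(null$mass) - 1) >= k])

    lr <- log(seqregister:::floor_rows(w, params$probability_floor) /
                (1 / 20))
    bins <- matrix(floor(lr / params$grid_step + 1e-9), nrow = l)
    m <- 120 - l + 1
    a <- matrix(sample.int(20, nmc * 120, replace = TRUE), nrow = 120)
    sc <- matrix(0, m, nmc)
    for (i in seq_len(l))
      sc <- sc + matrix(bins[i, ][a[i:(i + m - 1), ]], m, nmc)
    bests <- apply(sc, 2, max)

    for (q in c(0.5, 0.9, 0.995)) {
      k <- stats::quantile(bests, q, type = 1)
      p_emp <- mean(bests >= k)
      p_conv <- 1 - (1 - tail_at(k))^m
      se <- sqrt(max(p_emp * (1 - p_emp), 1e-12) / nmc)
      expect_lt(abs(p_conv - p_emp), 3 * se + 0.02 * p_emp + 1e-9)
    }
  }
})
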