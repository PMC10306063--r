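# Synthetic benchmark generator and scorer.

test_that("gen_sequence is seeded, validated and composition-faithful", {
  expect_error(gen_sequence(0), "positive")
  expect_identical(gen_sequence(50, seed = 7)$residues,
                   gen_sequence(50, seed = 7)$residues)
  expect_false(identical(gen_sequence(50, seed = 7)$residues,
                         gen_sequence(50, seed = 8)$residues))
  s <- gen_sequence(100000, seed = 3)
  freq <- table(strsplit(s$residues, "")[[1]]) / 100000
  expect_true(all(abs(freq - 0.05) < 0.005))
})

test_that("gen_profile rows are valid and hit the truth at rate alpha", {
  tgt <- gen_sequence(10000, seed = 2)
  truth <- plain_truth(10000)
  prof <- gen_profile(tgt, truth, alpha = 0.8, seed = 4)
  expect_equal(rowSums(prof$probs), rep(1, 10000))
  pred <- aa1[max.col(prof$probs)]
  tl <- strsplit(tgt$residues, "")[[1]]
  expect_lt(abs(mean(pred == tl) - 0.8), 0.01)

  # alpha = 1 is degenerate at the true types
  prof1 <- gen_profile(tgt, truth, alpha = 1, seed = 5)
  expect_true(all(prof1$probs[cbind(1:10000, match(tl, aa1))] == 1))
})

test_that("injected errors follow the stated conventions", {
  tgt <- gen_sequence(310, seed = 6)
  spec <- synthetic_spec(chain_length = 300, accuracy = 0.9,
                         shifts = list(c(121, 180, 2)), seed = 1)
  inj <- inject_errors(spec, tgt)
  # truth at model residue 130 is target position 132 (1-based)
  expect_equal(inj$truth$true_pos[130], 132)
  expect_equal(inj$truth$true_pos[120], 120)
  expect_equal(inj$truth$true_pos[181], 181)
  # the claimed types still follow the claimed positions
  tl <- strsplit(tgt$residues, "")[[1]]
  expect_identical(inj$chain$residues[[130]]$type1, tl[130])

  # numbering gap: numbers jump, identities unchanged
  spec_gap <- synthetic_spec(chain_length = 120,
                             numbering_gaps = list(c(92, 16)), seed = 1)
  inj_gap <- inject_errors(spec_gap, tgt)
  nums <- vapply(inj_gap$chain$residues, `[[`, integer(1), "number")
  expect_equal(nums[92], 92)
  expect_equal(nums[93], 109)
  expect_identical(inj_gap$chain$residues[[93]]$type1, tl[93])

  # empty spec: claimed equals truth everywhere
  inj0 <- inject_errors(synthetic_spec(chain_length = 50, seed = 1), tgt)
  expect_equal(inj0$truth$true_pos, 1:50)
  expect_identical(model_sequence(inj0$chain)$sequence,
                   substr(tgt$residues, 1, 50))

  expect_error(synthetic_spec(chain_length = 100,
                              shifts = list(c(10, 50, 1), c(40, 80, 2))),
               "overlap")
})

test_that("fragment sampling enforces both rejection rules", {
  clean <- toy_two_chain_model()
  # chain A: 100 clean residues for this test
  model <- toy_two_chain_model()
  big <- gen_structure(100, seed = 31)
  frags <- sample_fragments(big, lengths = c(10, 20), n_per_length = 3,
                            seed = 17)
  expect_length(frags, 6)
  expect_equal(sort(unique(vapply(frags, `[[`, integer(1), "length"))),
               c(10L, 20L))

  # UNK rejection: no fragment covers the unknown residue
  unk <- toy_two_chain_model(unk_at = 15)
  for (seed in 1:20) {
    fr <- sample_fragments(unk, lengths = 10, n_per_length = 3, seed = seed)
    for (f in fr)
      if (f$chain_id == "A") expect_false(15 %in% (f$start:(f$start + 9)))
  }

  # numbering jump: no fragment spans the discontinuity
  gap <- toy_two_chain_model(gap_after = 20)
  for (seed in 1:20) {
    fr <- sample_fragments(gap, lengths = 10, n_per_length = 3, seed = seed)
    for (f in fr)
      if (f$chain_id == "A")
        expect_equal(f$numbers[10] - f$numbers[1] + 1L, 10L)
  }

  # insertion codes reject the fragment
  ico <- toy_two_chain_model(icode_at = 15)
  for (seed in 1:20) {
    fr <- sample_fragments(ico, lengths = 10, n_per_length = 3, seed = seed)
    for (f in fr)
      if (f$chain_id == "A")
        expect_false(any((f$start:(f$start + 9)) == 15))
  }

  # short chains yield fewer or no fragments, silently
  expect_length(sample_fragments(toy_two_chain_model(), lengths = 20,
                                 n_per_length = 3, seed = 1)[
    vapply(sample_fragments(toy_two_chain_model(), lengths = 20,
                            n_per_length = 3, seed = 1), `[[`, character(1),
           "chain_id") == "B"], 0)
})

test_that("region evaluation matches an independent scorer", {
  truth <- data.frame(chain = "A", category = "register_shift",
                      start = 121L, end = 180L, offset = 2L,
                      stringsAsFactors = FALSE)
  exact <- data.frame(chain = "A", category = "register_shift",
                      start = 121L, end = 180L, offset = 2L,
                      best_pvalue = 1e-9, n_windows = 41L,
                      stringsAsFactors = FALSE)
  ev <- evaluate_regions(exact, truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$median_boundary_error, 0)

  shifted3 <- transform(exact, start = 124L, end = 183L)
  expect_equal(evaluate_regions(shifted3, truth)$boundary_errors, 3)

  # independent re-implementation of the matching rule on random outputs
  indep <- function(det, tr) {
    used <- rep(FALSE, nrow(det))
    n_match <- 0L; errs <- numeric(0)
    for (i in seq_len(nrow(tr))) {
      cand <- which(!used & det$category == tr$category[i] &
                      !is.na(det$offset) & det$offset == tr$offset[i])
      ov <- vapply(cand, function(j)
        max(0, min(det$end[j], tr$end[i]) - max(det$start[j], tr$start[i]) +
              1), numeric(1))
      ok <- cand[ov >= (tr$end[i] - tr$start[i] + 1L) / 2]
      if (length(ok)) {
        j <- ok[which.max(ov[match(ok, cand)])]
        used[j] <- TRUE; n_match <- n_match + 1L
        errs <- c(errs, max(abs(det$start[j] - tr$start[i]),
                            abs(det$end[j] - tr$end[i])))
      }
    }
    list(recall = n_match / nrow(tr), precision = sum(used) / nrow(det),
         errs = sort(errs))
  }
  set.seed(12)
  for (rep in 1:50) {
    nt <- sample(1:3, 1)
    tr <- data.frame(chain = "A", category = "register_shift",
                     start = sort(sample(as.integer(seq(1, 400, 40)), nt)),
                     offset = sample(c(-2L, 1L, 2L), nt, replace = TRUE),
                     stringsAsFactors = FALSE)
    tr$end <- tr$start + 30L
    nd <- sample(1:4, 1)
    det <- data.frame(chain = "A",
                      category = sample(c("register_shift",
                                          "indexing_issue"), nd,
                                        replace = TRUE),
                      start = sample(1:400, nd),
                      offset = sample(c(-2L, 1L, 2L), nd, replace = TRUE),
                      best_pvalue = 1e-6, n_windows = 5L,
                      stringsAsFactors = FALSE)
    det$end <- det$start + sample(10:40, max(nd, 1))[seq_len(nd)]
    ev1 <- evaluate_regions(det, tr)
    ev2 <- indep(det, tr)
    expect_equal(ev1$recall, ev2$recall)
    expect_equal(ev1$precision, ev2$precision)
    expect_equal(sort(ev1$boundary_errors), ev2$errs)
  }
})

test_that("the generator composes: accuracy-1 benchmarks recover every
           injected wide region exactly", {
  spec <- synthetic_spec(chain_length = 260, accuracy = 1,
                         shifts = list(c(41, 90, 1), c(141, 200, -3)),
                         seed = 14)
  b <- make_benchmark(spec)
  res <- scan_benchmark(b)
  rs <- res$regions[res$regions$category == "register_shift", ]
  expect_equal(nrow(rs), 2)
  expect_equal(sort(rs$offset), c(-3, 1))
  ev <- evaluate_regions(res$regions, b$truth)
  expect_equal(ev$recall, 1)
})

test_that("benchmarks are fully deterministic under a fixed seed and
           round-trip on disk", {
  spec <- synthetic_spec(chain_length = 80, accuracy = 0.9,
                         shifts = list(c(21, 60, 2)), seed = 9)
  b1 <- make_benchmark(spec)
  b2 <- make_benchmark(spec)
  expect_identical(b1$target$residues, b2$target$residues)
  expect_identical(b1$profile$probs, b2$profile$probs)
  expect_identical(b1$truth$true_pos, b2$truth$true_pos)

  dir <- withr::local_tempdir()
  write_benchmark(b1, dir)
  back <- read_benchmark(dir)
  expect_identical(back$target$residues, b1$target$residues)
  expect_equal(back$profile$probs, b1$profile$probs, tolerance = 1e-12)
  expect_identical(back$truth$true_pos, b1$truth$true_pos)
  expect_identical(model_sequence(back$chain)$sequence,
                   model_sequence(b1$chain)$sequence)
})
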