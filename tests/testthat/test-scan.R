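# Chain assignment, window scanning and issue categorization.

test_that("chains below the ten-residue floor are skipped, not failed", {
  tgt <- gen_sequence(50, seed = 1)
  prof <- residue_profile("A", number = 1:8,
                          probs = matrix(1 / 20, 8, 20))
  asn <- assign_chain(prof, list(tgt), scan_config())
  expect_true(asn$skipped)
  expect_false(asn$assigned)
  expect_match(asn$reason, "below minimum length")
})

test_that("a synthetic chain is assigned to its source among decoys", {
  cfg <- scan_config()
  s2 <- gen_sequence(120, seed = 21, id = "s2")
  decoys <- list(gen_sequence(120, seed = 22, id = "s1"), s2,
                 gen_sequence(120, seed = 23, id = "s3"))
  truth <- plain_truth(120)
  prof <- gen_profile(s2, truth, alpha = 0.9, seed = 31)
  asn <- assign_chain(prof, decoys, cfg)
  expect_true(asn$assigned)
  expect_identical(asn$seq_id, "s2")
  expect_lt(asn$pvalue, 0.14)
})

test_that("uniform-noise profiles are rarely assigned to unrelated
           sequences", {
  cfg <- scan_config()
  decoys <- lapply(1:3, function(i)
    gen_sequence(120, seed = 500 + i, id = paste0("d", i)))
  assigned <- 0L
  for (k in 1:200) {
    probs <- seqregister:::with_seed(2000 + k, {
      m <- matrix(exp(stats::rnorm(60 * 20, sd = 0.05)), 60, 20)
      sweep(m, 1, rowSums(m), `/`)
    })
    prof <- residue_profile("A", 1:60, probs = probs)
    asn <- assign_chain(prof, decoys, cfg)
    if (isTRUE(asn$assigned)) assigned <- assigned + 1L
  }
  expect_lte(assigned / 200, 0.05)
})

test_that("error-free chains scan fully consistent and yield no regions", {
  spec <- synthetic_spec(chain_length = 120, accuracy = 1, seed = 3)
  b <- make_benchmark(spec)
  res <- scan_benchmark(b)
  expect_true(all(res$calls$status == "consistent"))
  expect_equal(nrow(res$regions), 0)
})

test_that("an injected +2 register shift is recovered window by window and
           as one merged region", {
  spec <- synthetic_spec(chain_length = 300, accuracy = 0.9,
                         shifts = list(c(121, 180, 2)), seed = 42)
  b <- make_benchmark(spec)
  res <- scan_benchmark(b)

  inside <- res$calls$start >= 121 & res$calls$end <= 180
  expect_true(all(res$calls$delta[inside] == 2))
  expect_true(all(res$calls$status[inside] == "shifted"))

  rs <- res$regions[res$regions$category == "register_shift", ]
  expect_equal(nrow(rs), 1)
  expect_equal(rs$offset, 2)
  expect_lt(rs$best_pvalue, 0.14)
  ev <- evaluate_regions(res$regions, b$truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  expect_lte(ev$median_boundary_error, 5)
})

test_that("chains shorter than the window scan as one truncated window", {
  cfg <- scan_config()
  tgt <- gen_sequence(80, seed = 9)
  truth <- plain_truth(14)
  prof <- gen_profile(tgt, truth, alpha = 1, seed = 10)
  chain <- inject_errors(synthetic_spec(chain_length = 14, accuracy = 1,
                                        seed = 1), tgt)$chain
  asn <- assign_chain(prof, list(tgt), cfg)
  calls <- scan_chain(prof, chain, list(tgt), asn, cfg)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$window_length, 14)
  expect_equal(calls$status, "consistent")
})

test_that("scanning an unassigned chain is an explicit error", {
  tgt <- gen_sequence(50, seed = 2)
  prof <- gen_profile(tgt, plain_truth(20), alpha = 1, seed = 3)
  chain <- inject_errors(synthetic_spec(chain_length = 20, accuracy = 1,
                                        seed = 1), tgt)$chain
  asn <- list(assigned = FALSE)
  expect_error(scan_chain(prof, chain, list(tgt), asn, scan_config()),
               "unassigned_chain")
})

test_that("region bounds follow the midpoint rule", {
  expect_equal(unname(region_bounds(100, 119, 20)), c(110, 110))
  expect_equal(unname(region_bounds(100, 160, 20)), c(110, 150))
  expect_equal(unname(region_bounds(50, 59, 10)), c(55, 55))
})

test_that("correct identities with wrong numbering are categorized as an
           indexing issue, not a register shift", {
  cfg <- scan_config()
  tgt <- gen_sequence(160, seed = 77)
  tl <- strsplit(tgt$residues, "")[[1]]
  # claimed letters follow the TRUE positions (identities right), but the
  # numbering ignores a 4-residue unmodelled stretch after position 80
  true_pos <- c(1:80, 85:124)
  letters <- tl[true_pos]
  residues <- lapply(seq_along(letters), function(i)
    seqregister:::new_residue(i, "", aa_one_to_three(letters[i]),
                              matrix(numeric(0), ncol = 3)))
  chain <- seqregister:::new_chain("A", residues)
  truth <- structure(list(true_pos = true_pos, numbers = seq_along(true_pos),
                          target_id = tgt$id,
                          regions = NULL), class = "ground_truth")
  prof <- gen_profile(tgt, truth, alpha = 0.9, seed = 78)
  asn <- assign_chain(prof, list(tgt), cfg)
  calls <- scan_chain(prof, chain, list(tgt), asn, cfg)
  reg <- categorize_calls(calls, chain, tgt, cfg)

  idx <- reg[reg$category == "indexing_issue", ]
  expect_equal(nrow(idx), 1)
  expect_equal(idx$offset, 4)
  expect_equal(nrow(reg[reg$category == "register_shift", ]), 0)
})

test_that("an isolated UNK inside a consistent chain becomes a one-residue
           sequence mismatch", {
  spec <- synthetic_spec(chain_length = 120, accuracy = 0.9,
                         mismatches = list(c(57, "X")), seed = 5)
  b <- make_benchmark(spec)
  res <- scan_benchmark(b)
  mm <- res$regions[res$regions$category == "sequence_mismatch", ]
  expect_equal(nrow(mm), 1)
  expect_equal(c(mm$start, mm$end), c(57, 57))
  expect_equal(nrow(res$regions[res$regions$category == "register_shift", ]),
               0)
})

test_that("injected point mutations are reported as sequence mismatches", {
  tgt0 <- gen_sequence(140, seed = 81)
  tl <- strsplit(tgt0$residues, "")[[1]]
  wrong <- setdiff(aa1, tl[70])[1]
  spec <- synthetic_spec(chain_length = 140, accuracy = 0.9,
                         mismatches = list(c(70, wrong)), seed = 82)
  b <- make_benchmark(spec, target = tgt0)
  res <- scan_benchmark(b)
  mm <- res$regions[res$regions$category == "sequence_mismatch", ]
  expect_equal(nrow(mm), 1)
  expect_equal(c(mm$start, mm$end), c(70, 70))
})

test_that("single injected shifts of either sign are recovered with the
           exact offset", {
  cfg <- scan_config()
  for (off in c(-5, 1, 10)) {
    spec <- synthetic_spec(chain_length = 300, accuracy = 0.9,
                           shifts = list(c(121, 180, off)), seed = 400 + off)
    b <- make_benchmark(spec)
    res <- scan_benchmark(b, cfg)
    rs <- res$regions[res$regions$category == "register_shift", ]
    expect_gte(nrow(rs), 1)
    expect_true(all(rs$offset == off))
  }
})

test_that("opposite-sign shifts in adjacent runs stay separate regions", {
  spec <- synthetic_spec(chain_length = 300, accuracy = 0.95,
                         shifts = list(c(100, 150, 2), c(151, 200, -1)),
                         seed = 88)
  b <- make_benchmark(spec)
  res <- scan_benchmark(b)
  rs <- res$regions[res$regions$category == "register_shift", ]
  expect_equal(sort(rs$offset), c(-1, 2))
  expect_equal(nrow(rs), 2)
})

test_that("every reported register-shift region contains a confident
           window", {
  for (seed in 1:5) {
    spec <- synthetic_spec(chain_length = 200, accuracy = 0.85,
                           shifts = list(c(61, 140, 3)), seed = seed)
    b <- make_benchmark(spec)
    res <- scan_benchmark(b)
    rs <- res$regions[res$regions$category == "register_shift", ]
    expect_true(all(rs$best_pvalue < 0.14))
  }
})
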