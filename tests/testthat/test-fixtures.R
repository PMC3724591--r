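test_that("the RET-like fixture reproduces the four annotated domains", {
  fx <- make_ret_like_fixture()
  expect_equal(fx$domains$name, c("Signal Peptide", "Cadherin",
                                  "Transmembrane", "Tyrosine Kinase"))
  expect_equal(fx$domains$start, c(1L, 191L, 636L, 724L))
  expect_equal(fx$domains$end, c(24L, 270L, 653L, 1005L))
  expect_equal(fx$context$length, 1114L)
})

test_that("the clustered set sits just N-terminal of the transmembrane start, in cysteines", {
  fx <- make_ret_like_fixture()
  expect_true(all(fx$mutations_secondary$position < 636L))
  expect_true(all(fx$mutations_secondary$position >= 600L))
  expect_true(all(fx$mutations_secondary$ref == "C"))
  expect_error(make_ret_like_fixture(length = 900), ">= 1005")
})

test_that("fixture generation is seed-deterministic and leaves global RNG alone", {
  f1 <- make_ret_like_fixture(seed = 11)
  f2 <- make_ret_like_fixture(seed = 11)
  expect_identical(f1, f2)
  expect_false(identical(f1$mutations, make_ret_like_fixture(seed = 12)$mutations))

  set.seed(99)
  before <- .Random.seed
  invisible(simulate_mutations(fixture_config(100, 10, seed = 4)))
  invisible(simulate_alignment(fixture_config(50, n_alignment_sequences = 4,
                                              seed = 4)))
  expect_identical(.Random.seed, before)
})

test_that("simulated mutations honor count, cluster bounds and the alphabet", {
  cfg <- fixture_config(protein_length = 1000, n_mutations = 24,
                        cluster = list(center = 620, half_width = 10,
                                       fraction = 1.0), seed = 7)
  m <- simulate_mutations(cfg)
  expect_equal(nrow(m), 24L)
  expect_true(all(m$position >= 610L & m$position <= 630L))
  expect_true(all(m$ref != m$alt))
  expect_equal(nrow(simulate_mutations(fixture_config(100, 0))), 0L)
  expect_identical(simulate_mutations(cfg), simulate_mutations(cfg))
  # half clustered, half anywhere
  cfg2 <- fixture_config(1000, 100, cluster = list(center = 500,
                                                   half_width = 5,
                                                   fraction = 0.5), seed = 8)
  m2 <- simulate_mutations(cfg2)
  expect_gte(sum(m2$position >= 495 & m2$position <= 505), 50L)
  expect_error(fixture_config(100, 5, cluster = list(center = 99,
                                                     half_width = 5,
                                                     fraction = 1)),
               "outside")
})

test_that("simulated alignments realize the identity profile at its endpoints", {
  all1 <- fixture_config(30, n_alignment_sequences = 6,
                         identity_profile = rep(1, 30), seed = 9)
  expect_equal(conservation_scores(simulate_alignment(all1))$score, rep(1, 30))
  all0 <- fixture_config(30, n_alignment_sequences = 6,
                         identity_profile = rep(0, 30), seed = 9)
  expect_equal(conservation_scores(simulate_alignment(all0))$score, rep(0, 30))
  expect_error(simulate_alignment(fixture_config(10,
                                                 n_alignment_sequences = 1)),
               ">= 2")
})

test_that("simulated alignments recover intermediate identity within binomial error", {
  cfg <- fixture_config(50, n_alignment_sequences = 201,
                        identity_profile = rep(0.5, 50), seed = 10)
  s <- conservation_scores(simulate_alignment(cfg))$score
  se <- sqrt(0.25 / 200)
  expect_gte(mean(abs(s - 0.5) <= 3 * se), 0.99)
  expect_lt(abs(mean(s) - 0.5), 3 * se)
})

test_that("gap-rate alignments still parse and score within bounds", {
  cfg <- fixture_config(40, n_alignment_sequences = 8, seed = 12)
  aln <- simulate_alignment(cfg, gap_rate = 0.2)
  expect_true(any(grepl("-", aln$seqs[-1], fixed = TRUE)))
  s <- conservation_scores(aln)$score
  expect_true(all(s >= 0 & s <= 1))
})

test_that("generated fixtures round-trip through the file writers", {
  fx <- make_ret_like_fixture(seed = 13)
  d <- tempfile(); dir.create(d)
  write_mutation_file(fx$mutations, file.path(d, "m.tsv"))
  expect_identical(read_mutation_file(file.path(d, "m.tsv")), fx$mutations)
  write_architecture_file(fx$domains, file.path(d, "a.tsv"))
  expect_identical(read_architecture_file(file.path(d, "a.tsv")), fx$domains)
  write_ptm_file(fx$ptms, file.path(d, "p.tsv"))
  expect_identical(read_ptm_file(file.path(d, "p.tsv")), fx$ptms)
  expect_equal(nrow(validate_inputs(fx$mutations, fx$domains, fx$ptms,
                                    fx$context)), 0L)
})
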