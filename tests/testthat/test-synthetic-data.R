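test_that("generate_ancestor hits length, GC target, and is seed-reproducible", {
  g <- generate_ancestor(100000, gc_fraction = 0.37, seed = 1)
  expect_equal(nchar(g$seq), 100000L)
  gc <- lengths(regmatches(g$seq, gregexpr("[GC]", g$seq))) / 100000
  # 99% binomial interval around 0.37 at n = 1e5 is well inside +/- 0.01
  expect_lt(abs(gc - 0.37), 0.01)
  g2 <- generate_ancestor(100000, gc_fraction = 0.37, seed = 1)
  expect_identical(g$seq, g2$seq)
  expect_error(generate_ancestor(0), ">= 1")
  expect_error(generate_ancestor(100, gc_fraction = 1), "gc_fraction")
})

test_that("derive_strain: identity case, SNV counts, and replay oracle", {
  g <- generate_ancestor(100000, seed = 2)
  same <- derive_strain(g, 0, 0, seed = 3)
  expect_identical(same$genome$seq, g$seq)
  expect_equal(nrow(same$log), 0L)
  expect_equal(same$genome$lineage, g$label)

  mut <- derive_strain(g, 0.01, 0, seed = 4)
  # Binomial(1e5, 0.01): 99% interval approx 1000 +/- 2.58*sqrt(990)
  expect_lt(abs(nrow(mut$log) - 1000), 2.6 * sqrt(990))
  expect_true(all(mut$log$type == "SNV"))
  expect_true(all(mut$log$ref != mut$log$alt))

  expect_error(derive_strain(g, 0.5, 0), "0.1")
})

test_that("mutation logs replay exactly, including indels (brute-force oracle)", {
  # independent replay: apply events right-to-left on the raw string
  oracle_replay <- function(parent_seq, log) {
    s <- parent_seq
    for (i in rev(seq_len(nrow(log)))) {
      p <- log$position[i] + 1  # 1-based
      s <- switch(log$type[i],
        SNV = paste0(substring(s, 1, p - 1), log$alt[i],
                     substring(s, p + 1, nchar(s))),
        insertion = paste0(substring(s, 1, p), log$alt[i],
                           substring(s, p + 1, nchar(s))),
        deletion = paste0(substring(s, 1, p - 1),
                          substring(s, p + nchar(log$ref[i]), nchar(s)))
      )
    }
    s
  }
  for (i in 1:25) {
    g <- generate_ancestor(3000, seed = 100 + i)
    d <- derive_strain(g, 0.01, 0.002, seed = 200 + i)
    expect_identical(d$genome$seq, oracle_replay(g$seq, d$log))
    expect_identical(replay_mutations(g, d$log)$seq, d$genome$seq)
    expect_false(is.unsorted(d$log$position, strictly = TRUE))
  }
})

test_that("simulate_reads: error-free mates are genome substrings, counts exact", {
  g <- generate_ancestor(20000, seed = 5)
  rd <- simulate_reads(g, 200, error_rate = 0, seed = 6)
  expect_equal(n_pairs(rd), 200L)
  expect_true(all(nchar(rd$seq1) == 150))
  hits1 <- vapply(rd$seq1, function(s) grepl(s, g$seq, fixed = TRUE), TRUE)
  expect_true(all(hits1))
  # mate 2 is the reverse-complement strand of the fragment end
  hits2 <- vapply(oracle_revcomp(rd$seq2),
                  function(s) grepl(s, g$seq, fixed = TRUE), TRUE)
  expect_true(all(hits2))
  expect_error(simulate_reads(g, 10, insert_mean = 30000), "insert")
})

test_that("simulate_reads injects errors at the requested per-base rate", {
  g <- generate_ancestor(20000, seed = 7)
  rate <- 0.01
  rd0 <- simulate_reads(g, 4000, error_rate = 0, seed = 8)
  rd1 <- simulate_reads(g, 4000, error_rate = rate, seed = 8)
  # same seed -> same fragments, so mismatches against rd0 are the errors
  mism <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, c(rd0$seq1, rd0$seq2), c(rd1$seq1, rd1$seq2)))
  n_bases <- 2 * 4000 * 150
  se <- sqrt(rate * (1 - rate) / n_bases)
  expect_lt(abs(mism / n_bases - rate), 3 * se)
})

test_that("consensus error probability decays with depth (parity-aware)", {
  e <- 0.05
  p <- consensus_error_prob(c(2, 3, 5, 7, 10, 20), e)
  # the spec'd comparison: deep consensus beats shallow
  expect_lt(p[6], p[3])   # depth 20 < depth 5
  # monotone along equal parity (majority threshold moves at odd depths)
  expect_lt(consensus_error_prob(7, e), consensus_error_prob(5, e))
  expect_lt(consensus_error_prob(6, e), consensus_error_prob(4, e))
  # exact binomial value at depth 2: both reads wrong with the same base
  expect_equal(consensus_error_prob(2, e), 3 * (e / 3)^2, tolerance = 1e-12)
  expect_equal(consensus_error_prob(0, e), 1)
})

test_that("emulate_assembly: noise-free contigs cover the genome exactly", {
  g <- generate_ancestor(60000, seed = 9)
  mod <- assembly_model(mean_depth = 100, base_error_rate = 0)
  asm <- emulate_assembly(g, mod, seed = 10)
  # at depth 100 no window drops: single contig equal to the genome
  expect_true(all(vapply(asm$seq, function(s) {
    grepl(s, g$seq, fixed = TRUE)
  }, TRUE)))
  expect_equal(total_length(asm), 60000L)
  # in-order concatenation is a subsequence cover
  expect_identical(paste(asm$seq, collapse = ""), g$seq)
  # determinism
  asm2 <- emulate_assembly(g, mod, seed = 10)
  expect_identical(tibble::as_tibble(asm), tibble::as_tibble(asm2))
})

test_that("emulate_assembly drops short contigs and empties gracefully", {
  g <- generate_ancestor(30000, seed = 11)
  asm <- emulate_assembly(g, assembly_model(), seed = 12)
  expect_true(all(nchar(asm$seq) >= 1000))
  expect_warning(empty <- emulate_assembly(g, assembly_model(mean_depth = 0)),
                 "mean_depth")
  expect_equal(nrow(empty), 0L)
})

test_that("same-strain emulated assemblies have ANI slightly below 100 with spread", {
  g <- generate_ancestor(50000, seed = 13)
  anis <- vapply(1:8, function(i) {
    a <- emulate_assembly(g, seed = 20 + 2 * i)
    b <- emulate_assembly(g, seed = 21 + 2 * i)
    symmetric_ani(a, b)
  }, 0)
  expect_true(all(anis < 100))
  expect_true(all(anis > 99.5))
  expect_gt(sd(anis), 0)
  # error-free emulation against its own genome is exactly 100
  a0 <- emulate_assembly(g, assembly_model(base_error_rate = 0), seed = 30)
  expect_identical(fragment_ani(a0, as_assembly(g))$ani, 100)
})
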