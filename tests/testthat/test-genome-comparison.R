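aln_tbl <- function(labels, rows) tibble::tibble(label = labels, seq = rows)

test_that("aligned FASTA loads into an equal-width alignment", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "aln.fa")
  set.seed(1)
  rows <- replicate(3, paste(sample(c("A", "C", "G", "T", "-"), 500, TRUE,
                                    prob = c(.24, .24, .24, .24, .04)),
                             collapse = ""))
  writeLines(c(">g1", rows[1], ">g2", rows[2], ">g3", rows[3]), path)
  aln <- read_alignment(path, "fasta")
  expect_equal(nrow(aln), 3L)
  expect_equal(unique(nchar(aln$seq)), 500L)
  expect_equal(aln$label, c("g1", "g2", "g3"))
  # ragged rows error
  bad <- file.path(dir, "bad.fa")
  writeLines(c(">g1", "ACGT", ">g2", "ACGTT"), bad)
  expect_error(read_alignment(bad, "fasta"), "ragged")
})

test_that("XMFA blocks concatenate per genome in block order", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "aln.xmfa")
  set.seed(2)
  mk <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  b1 <- list(g1 = mk(300), g2 = mk(300))
  b2 <- list(g1 = mk(200), g2 = mk(200))
  writeLines(c(
    "#FormatVersion Mauve1",
    "> g1:1-300 + f1", substring(b1$g1, 1, 150), substring(b1$g1, 151, 300),
    "> g2:1-300 + f2", b1$g2, "=",
    "> g1:301-500 + f1", b2$g1,
    "> g2:301-500 + f2", b2$g2, "="
  ), path)
  aln <- read_alignment(path, "xmfa")
  expect_equal(sort(aln$label), c("g1", "g2"))
  expect_equal(unique(nchar(aln$seq)), 500L)
  expect_equal(aln$seq[aln$label == "g1"], paste0(b1$g1, b2$g1))
  # a genome absent from a block gets gap fill
  path2 <- file.path(dir, "aln2.xmfa")
  writeLines(c("> g1:1-10 + f", strrep("A", 10),
               "> g2:1-10 + f", strrep("A", 10), "=",
               "> g1:11-14 + f", "CCCC", "="), path2)
  aln2 <- read_alignment(path2, "xmfa")
  expect_equal(aln2$seq[aln2$label == "g2"], paste0(strrep("A", 10), "----"))
})

test_that("count_snps follows the gap-free-column convention (hand count)", {
  # identical rows: zero SNPs
  same <- count_snps(aln_tbl(c("a", "b"), rep("ACGTACGTAC", 2)))
  expect_equal(same$snp_count, 0L)
  expect_equal(same$snp_percent, 0)

  # 2 rows, length 10: mismatches at 2 gap-free columns, 1 gapped column
  r1 <- "ACGTACGTAC"
  r2 <- "ACCTAC-TAT"   # mismatch at 3 and 10; gap at 7
  rep2 <- count_snps(aln_tbl(c("a", "b"), c(r1, r2)))
  expect_equal(rep2$columns_considered, 9L)
  expect_equal(rep2$snp_count, 2L)
  expect_equal(rep2$snp_percent, 100 * 2 / 9, tolerance = 1e-10)

  # N excludes the column entirely
  rep3 <- count_snps(aln_tbl(c("a", "b"), c("ACGT", "ANGA")))
  expect_equal(rep3$columns_considered, 3L)
  expect_equal(rep3$snp_count, 1L)

  # no considered columns: NA percent with a warning
  expect_warning(rep4 <- count_snps(aln_tbl(c("a", "b"), c("A-", "-A"))),
                 "undefined")
  expect_true(is.na(rep4$snp_percent))
})

test_that("count_snps matches a column-scanning oracle on random alignments", {
  set.seed(3)
  for (i in 1:100) {
    n_rows <- sample(2:4, 1)
    width <- sample(20:60, 1)
    rows <- replicate(n_rows, paste(
      sample(c("A", "C", "G", "T", "N", "-"), width, TRUE,
             prob = c(rep(0.23, 4), 0.04, 0.04)), collapse = ""))
    # ensure at least one unambiguous character per row
    rows <- paste0(rows, "A")
    got <- count_snps(aln_tbl(paste0("g", seq_len(n_rows)), rows))
    want <- oracle_count_snps(rows)
    expect_equal(got$snp_count, want$snp_count)
    expect_equal(got$columns_considered, want$columns_considered)
  }
})

test_that("count_snps is invariant to row order and all-gap columns", {
  set.seed(4)
  rows <- replicate(3, paste(sample(c("A", "C", "G", "T", "-"), 50, TRUE),
                             collapse = ""))
  rows <- paste0(rows, "ACGT")
  base <- count_snps(aln_tbl(c("a", "b", "c"), rows))
  shuffled <- count_snps(aln_tbl(c("c", "a", "b"), rows[c(3, 1, 2)]))
  expect_equal(shuffled$snp_count, base$snp_count)
  expect_equal(shuffled$columns_considered, base$columns_considered)
  padded <- count_snps(aln_tbl(c("a", "b", "c"), paste0(rows, "-")))
  expect_equal(padded$snp_count, base$snp_count)
  expect_equal(padded$columns_considered, base$columns_considered)
})

test_that("snp_percent tracks true divergence on simulated no-indel pairs", {
  g <- generate_ancestor(50000, seed = 5)
  d <- 0.01
  der <- derive_strain(g, d, 0, seed = 6)
  rep <- count_snps(aln_tbl(c("parent", "child"), c(g$seq, der$genome$seq)))
  expect_equal(rep$snp_count, nrow(der$log))
  se <- sqrt(d * (1 - d) / 50000)
  expect_lt(abs(rep$snp_percent / 100 - d), 4 * se)
})

test_that("pairwise_identity: hand-built case, symmetry, SNP relation", {
  # 2 x 8 alignment with 6 comparable columns, 3 matching -> 50%
  r1 <- "ACGTAC-G"
  r2 <- "ANCTAAGC"   # col 2 N, col 7 gap; comparable 1,3,4,5,6,8; matches 1,4,5
  m <- pairwise_identity(aln_tbl(c("a", "b"), c(r1, r2)))
  expect_equal(m["a", "b"], 50)
  expect_equal(diag(m), c(a = 100, b = 100))
  expect_equal(m, t(m))

  expect_equal(unname(pairwise_identity(
    aln_tbl(c("a", "b"), rep("ACGT", 2)))["a", "b"]), 100)

  # for 2-row alignments: snp_count = (100 - identity)/100 * considered
  set.seed(7)
  for (i in 1:10) {
    rows <- replicate(2, paste(sample(c("A", "C", "G", "T", "-"), 40, TRUE),
                               collapse = ""))
    rows <- paste0(rows, "AC")
    snp <- count_snps(aln_tbl(c("x", "y"), rows))
    pid <- pairwise_identity(aln_tbl(c("x", "y"), rows))["x", "y"]
    expect_equal(snp$snp_count,
                 round((100 - pid) / 100 * snp$columns_considered))
  }
})
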