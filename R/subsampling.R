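#' Subsample whole read pairs without replacement
#'
#' Draws a uniform sample of `n_pairs` whole pairs (mates are never
#' separated) from a read set, preserving input order. Deterministic under a
#' fixed seed. Requesting more pairs than available is an error, never a
#' silent truncation.
#'
#' @param reads A [paired_reads()] tibble.
#' @param n_pairs Number of pairs to draw (default 150000, the replicate
#'   size used when building same-strain null distributions).
#' @param seed Optional integer seed.
#' @return A [paired_reads()] tibble with `n_pairs` rows.
#' @export
subsample_read_pairs <- function(reads, n_pairs = 150000L, seed = NULL) {
  stopifnot(inherits(reads, "paired_reads"))
  n <- nrow(reads)
  if (n_pairs > n) {
    rlang::abort(sprintf(
      "cannot subsample %d pairs from a read set of %d pairs", n_pairs, n
    ))
  }
  idx <- with_seed_opt(seed, sort(sample.int(n, n_pairs)))
  paired_reads(tibble::as_tibble(reads)[idx, ],
               source_label = attr(reads, "source_label"))
}

#' Derive distinct replicate seeds from a master seed
#'
#' Replicate seeds are drawn without replacement from the 31-bit integer
#' range under the master seed, so they are pairwise distinct and the whole
#' replicate scheme is reproducible from one number.
#'
#' @param master_seed Integer master seed.
#' @param n Number of seeds.
#' @return Integer vector of `n` distinct seeds.
#' @export
derive_replicate_seeds <- function(master_seed, n) {
  withr::with_seed(as.integer(master_seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

#' Build seeded subsample replicates of a read set
#'
#' Produces `n_replicates` independent subsamples of `n_pairs` whole pairs,
#' one per derived seed (the standard scheme uses 50 replicates of 150000
#' pairs each, later paired off into 25 disjoint ANI comparisons).
#' `n_replicates` must be even because replicates are consumed in disjoint
#' pairs downstream.
#'
#' @param reads A [paired_reads()] tibble.
#' @param n_replicates Even number of replicates (default 50).
#' @param n_pairs Pairs per replicate (default 150000).
#' @param master_seed Integer master seed.
#' @return A `replicate_set`: tibble with columns `replicate`, `seed`, and
#'   list-column `reads`; attribute `strain_label` carries the source label.
#' @export
make_replicates <- function(reads, n_replicates = 50L, n_pairs = 150000L,
                            master_seed = 1L) {
  stopifnot(inherits(reads, "paired_reads"))
  if (n_replicates %% 2 != 0) {
    rlang::abort(paste0(
      "n_replicates must be even: replicates are consumed in disjoint pairs, ",
      "one ANI comparison per pair"
    ))
  }
  seeds <- derive_replicate_seeds(master_seed, n_replicates)
  out <- tibble::tibble(
    replicate = seq_len(n_replicates),
    seed = seeds,
    reads = purrr::map(seeds, function(s) {
      subsample_read_pairs(reads, n_pairs, seed = s)
    })
  )
  structure(out, strain_label = attr(reads, "source_label"),
            class = c("replicate_set", class(tibble::tibble())))
}

#' Pair items disjointly in order
#'
#' Consecutive pairing (1,2), (3,4), ...: every item enters exactly one
#' pair, so no replicate assembly is reused across ANI comparisons
#' (avoiding pseudo-replication in the null distribution).
#'
#' @param items A list or vector of even length.
#' @return A tibble with columns `pair`, `a`, `b` (`a`/`b` are list-columns
#'   when `items` is a list).
#' @export
disjoint_pairs <- function(items) {
  n <- length(items)
  if (n %% 2 != 0) {
    rlang::abort("disjoint pairing requires an even number of items")
  }
  odd <- if (n == 0L) integer() else seq(1L, n, by = 2L)
  tibble::tibble(
    pair = seq_len(n / 2L),
    a = items[odd],
    b = items[odd + 1L]
  )
}
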