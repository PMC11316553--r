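#' Fragment-based average nucleotide identity
#'
#' Built-in FastANI-style estimator: the query assembly is cut into
#' non-overlapping fragments of `fragment_len` bp (terminal remainders are
#' discarded), each fragment is anchored to the reference by shared k-mers
#' on both strands, placed on its best-supported diagonal, and scored as
#' ungapped percent identity over the portion of the fragment that projects
#' into a single reference contig (at least `min_overlap` bp). Fragments
#' whose best identity falls below `min_identity_seed` are unmapped. ANI is
#' the mean identity over mapped fragments, reported as `NA` (undefined,
#' not 0) when fewer than `min_mapped` fragments map.
#'
#' Defaults follow the common fragment-mapping convention: 3000 bp
#' fragments, k = 16.
#'
#' @param query,reference [assembly()] objects (or anything
#'   [as_assembly()] accepts).
#' @param fragment_len Fragment length in bp.
#' @param k K-mer size for anchoring (4..32).
#' @param min_identity_seed Minimum percent identity for a fragment to count
#'   as mapped (default 80).
#' @param min_overlap Minimum compared overlap in bp for a candidate
#'   placement (default 300).
#' @param min_mapped Minimum mapped fragments for a defined ANI (default
#'   10).
#' @return A one-row tibble: `query`, `reference`, `ani`,
#'   `fragments_mapped`, `fragments_total`.
#' @examples
#' g <- generate_ancestor(30000, seed = 1)
#' fragment_ani(as_assembly(g), as_assembly(g))
#' @export
fragment_ani <- function(query, reference, fragment_len = 3000L, k = 16L,
                         min_identity_seed = 80, min_overlap = 300L,
                         min_mapped = 10L) {
  query <- as_assembly(query)
  reference <- as_assembly(reference)
  if (nrow(query) == 0 || nrow(reference) == 0) {
    rlang::abort("both assemblies must be non-empty")
  }
  res <- cpp_fragment_ani(query$seq, reference$seq, as.integer(fragment_len),
                          as.integer(k), min_identity_seed,
                          as.integer(min_overlap))
  ani <- if (res$fragments_mapped >= min_mapped) res$ani else NA_real_
  tibble::tibble(
    query = assembly_label(query),
    reference = assembly_label(reference),
    ani = ani,
    fragments_mapped = res$fragments_mapped,
    fragments_total = res$fragments_total
  )
}

#' Symmetric ANI of an assembly pair
#'
#' The fragment estimator is directional; the single ANI reported for a
#' pair is the arithmetic mean of the two directions. `NA` in either
#' direction propagates.
#'
#' @inheritParams fragment_ani
#' @param a,b [assembly()] objects.
#' @return A single numeric ANI percent (possibly `NA`).
#' @export
symmetric_ani <- function(a, b, fragment_len = 3000L, k = 16L,
                          min_identity_seed = 80, min_overlap = 300L,
                          min_mapped = 10L) {
  ab <- fragment_ani(a, b, fragment_len, k, min_identity_seed, min_overlap,
                     min_mapped)
  ba <- fragment_ani(b, a, fragment_len, k, min_identity_seed, min_overlap,
                     min_mapped)
  (ab$ani + ba$ani) / 2
}
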