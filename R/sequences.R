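#' Sequence containers
#'
#' Light containers for the objects the pipeline moves around: a `genome` is
#' a single nucleotide sequence with a label and an optional parent lineage;
#' an `assembly` is a tibble of contigs (columns `contig_id`, `seq`) with a
#' strain/sample label; a `paired_reads` object is a tibble of read pairs
#' (columns `read_id`, `seq1`, `qual1`, `seq2`, `qual2`) with a source label.
#'
#' Sequences are stored uppercase over the alphabet `{A,C,G,T,N}`; IUPAC
#' ambiguity codes are mapped to `N` (with a message giving the count), since
#' downstream k-mer anchoring only uses unambiguous bases.
#'
#' @param seq Nucleotide string.
#' @param label Genome / strain / sample label.
#' @param lineage Optional label of the parent genome this one was derived
#'   from.
#' @return `genome()` returns a `genome` object; `assembly()` an `assembly`;
#'   `paired_reads()` a `paired_reads` tibble.
#' @examples
#' g <- genome("ACGTACGTAC", label = "anc")
#' a <- assembly(tibble::tibble(contig_id = "c1", seq = "ACGTACGT"), "s1")
#' total_length(a)
#' @name sequence-containers
NULL

# uppercase and collapse non-{A,C,G,T,N} characters to N
clean_seq <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- vapply(
    gregexpr("[^ACGTN]", x),
    function(m) if (m[1] == -1L) 0L else length(m),
    integer(1)
  )
  if (any(bad > 0)) {
    rlang::inform(sprintf(
      "%d character(s) outside {A,C,G,T,N} in %s mapped to N", sum(bad), what
    ))
    x <- gsub("[^ACGTN]", "N", x)
  }
  x
}

#' @rdname sequence-containers
#' @export
genome <- function(seq, label = "genome", lineage = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  structure(
    list(seq = clean_seq(seq, label), label = label, lineage = lineage),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf(
    "<genome> %s: %s bp%s\n", x$label, format(nchar(x$seq), big.mark = ","),
    if (is.null(x$lineage)) "" else paste0(" (derived from ", x$lineage, ")")
  ))
  invisible(x)
}

#' @param contigs Tibble with columns `contig_id` and `seq`.
#' @rdname sequence-containers
#' @export
assembly <- function(contigs, label = "assembly") {
  stopifnot(is.data.frame(contigs), all(c("contig_id", "seq") %in% names(contigs)))
  contigs <- tibble::as_tibble(contigs)[, c("contig_id", "seq")]
  if (anyDuplicated(contigs$contig_id)) {
    rlang::abort("duplicate contig ids in assembly")
  }
  if (nrow(contigs) > 0 && any(!nzchar(contigs$seq))) {
    rlang::abort("empty contig sequence in assembly")
  }
  contigs$seq <- clean_seq(contigs$seq, label)
  structure(contigs, label = label,
            class = c("assembly", class(tibble::tibble())))
}

#' @param x An object.
#' @rdname sequence-containers
#' @export
total_length <- function(x) UseMethod("total_length")

#' @export
total_length.assembly <- function(x) sum(nchar(x$seq))

#' @export
total_length.genome <- function(x) nchar(x$seq)

#' @rdname sequence-containers
#' @export
assembly_label <- function(x) attr(x, "label")

#' Coerce to an assembly
#'
#' A `genome` becomes a single-contig assembly; a character vector becomes
#' one contig per element.
#'
#' @param x Object to coerce.
#' @param label Assembly label (defaults to the genome's own label).
#' @return An [assembly()].
#' @export
as_assembly <- function(x, label = NULL) UseMethod("as_assembly")

#' @export
as_assembly.assembly <- function(x, label = NULL) {
  if (!is.null(label)) attr(x, "label") <- label
  x
}

#' @export
as_assembly.genome <- function(x, label = NULL) {
  assembly(tibble::tibble(contig_id = paste0(x$label, "_1"), seq = x$seq),
           label = label %||% x$label)
}

#' @export
as_assembly.character <- function(x, label = "assembly") {
  ids <- names(x) %||% paste0("contig_", seq_along(x))
  assembly(tibble::tibble(contig_id = ids, seq = unname(x)), label = label)
}

#' @param pairs Tibble with columns `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`.
#' @param source_label Label of the read set's source.
#' @rdname sequence-containers
#' @export
paired_reads <- function(pairs, source_label = "reads") {
  need <- c("read_id", "seq1", "qual1", "seq2", "qual2")
  stopifnot(is.data.frame(pairs), all(need %in% names(pairs)))
  pairs <- tibble::as_tibble(pairs)[, need]
  structure(pairs, source_label = source_label,
            class = c("paired_reads", class(tibble::tibble())))
}

#' @rdname sequence-containers
#' @export
n_pairs <- function(x) {
  stopifnot(inherits(x, "paired_reads"))
  nrow(x)
}

#' Reverse complement
#'
#' @param x Character vector of nucleotide sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}
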