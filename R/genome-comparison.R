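#' Read a whole-genome multiple alignment
#'
#' Supports aligned FASTA (equal-length gapped records) and XMFA (aligned
#' blocks separated by `=` lines, concatenated per genome in block order; a
#' genome absent from a block contributes gaps for that block). Rows are
#' uppercased; characters outside `{A,C,G,T,N,-}` are mapped to `N`.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"xmfa"`.
#' @return A `multiple_alignment`: tibble with columns `label`, `seq`, all
#'   rows of equal length.
#' @export
read_alignment <- function(path, format = c("fasta", "xmfa")) {
  format <- match.arg(format)
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  rows <- switch(format,
    fasta = {
      set <- Biostrings::readBStringSet(path, format = "fasta")
      tibble::tibble(label = sub("\\s.*$", "", names(set)),
                     seq = as.character(set))
    },
    xmfa = read_xmfa(path)
  )
  new_multiple_alignment(rows)
}

new_multiple_alignment <- function(rows) {
  stopifnot(all(c("label", "seq") %in% names(rows)))
  if (nrow(rows) < 2) rlang::abort("an alignment needs >= 2 rows")
  rows$seq <- toupper(rows$seq)
  rows$seq <- gsub("[^ACGTN-]", "N", rows$seq)
  w <- nchar(rows$seq)
  if (length(unique(w)) != 1) {
    rlang::abort(sprintf(
      "ragged alignment: row lengths %s", paste(unique(w), collapse = ", ")
    ))
  }
  if (any(vapply(rows$seq, function(s) !grepl("[ACGTN]", s), TRUE))) {
    rlang::abort("alignment row with no non-gap characters")
  }
  structure(tibble::as_tibble(rows[, c("label", "seq")]), width = w[1],
            class = c("multiple_alignment", class(tibble::tibble())))
}

# XMFA: '>' headers of the form "> id:start-end strand comment", block
# sequences possibly wrapped, blocks terminated by lines starting with '='
read_xmfa <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  blocks <- list()
  cur_labels <- character()
  cur_seqs <- character()
  cur_open <- FALSE
  flush_block <- function() {
    if (length(cur_labels) > 0) {
      blocks[[length(blocks) + 1]] <<- tibble::tibble(label = cur_labels,
                                                      seq = cur_seqs)
    }
    cur_labels <<- character(); cur_seqs <<- character(); cur_open <<- FALSE
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^=", ln)) {
      flush_block()
    } else if (grepl("^>", ln)) {
      hdr <- sub("^>\\s*", "", ln)
      lab <- sub(":.*$", "", strsplit(hdr, "\\s+")[[1]][1])
      cur_labels <- c(cur_labels, lab)
      cur_seqs <- c(cur_seqs, "")
      cur_open <- TRUE
    } else if (nzchar(trimws(ln))) {
      if (!cur_open) {
        rlang::abort(sprintf("XMFA parse error: sequence before header at line %d", i))
      }
      cur_seqs[length(cur_seqs)] <- paste0(cur_seqs[length(cur_seqs)], trimws(ln))
    }
  }
  flush_block()
  if (length(blocks) == 0) rlang::abort("empty XMFA file")
  labels <- unique(unlist(lapply(blocks, function(b) b$label)))
  pieces <- lapply(blocks, function(b) {
    w <- unique(nchar(b$seq))
    if (length(w) != 1) rlang::abort("ragged XMFA block")
    out <- stats::setNames(rep(strrep("-", w), length(labels)), labels)
    out[b$label] <- b$seq
    out
  })
  tibble::tibble(
    label = labels,
    seq = vapply(labels, function(l) {
      paste(vapply(pieces, `[[`, "", l), collapse = "")
    }, "", USE.NAMES = FALSE)
  )
}

# character matrix view of an alignment: rows = genomes, cols = columns
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  rownames(m) <- aln$label
  m
}

#' Count SNPs in a multiple alignment
#'
#' A column is *considered* iff every row carries an unambiguous base
#' (`A/C/G/T`: no gap, no `N`); a considered column is a SNP iff at least
#' two distinct bases occur in it. The SNP percentage uses considered
#' columns as its denominator — the only convention under which a
#' substitution is well defined for every row — and the convention is
#' recorded in the output.
#'
#' @param aln A `multiple_alignment` (see [read_alignment()]), or a data
#'   frame with columns `label` and `seq` of equal-length rows.
#' @return A one-row tibble: `snp_count`, `columns_considered`,
#'   `snp_percent` (`NA` with a warning when no column is considered), and
#'   `convention`.
#' @export
count_snps <- function(aln) {
  if (!inherits(aln, "multiple_alignment")) aln <- new_multiple_alignment(aln)
  m <- aln_matrix(aln)
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  considered <- colSums(!ok) == 0
  differs <- colSums(m != matrix(m[1, ], nrow(m), ncol(m), byrow = TRUE)) > 0
  snp <- considered & differs
  n_cons <- sum(considered)
  if (n_cons == 0) {
    rlang::warn("no gap-free unambiguous columns: SNP percent undefined")
  }
  tibble::tibble(
    snp_count = sum(snp),
    columns_considered = n_cons,
    snp_percent = if (n_cons == 0) NA_real_ else 100 * sum(snp) / n_cons,
    convention = "gap-free unambiguous columns"
  )
}

#' Pairwise percent identity matrix of an alignment
#'
#' For each row pair, identity = matches / compared over the columns where
#' both rows carry an unambiguous base; `N` never matches anything. The
#' matrix is symmetric with 100 on the diagonal; a pair with no comparable
#' columns gets `NA`.
#'
#' @inheritParams count_snps
#' @return A symmetric numeric matrix of percent identities with row/column
#'   names from the alignment labels.
#' @export
pairwise_identity <- function(aln) {
  if (!inherits(aln, "multiple_alignment")) aln <- new_multiple_alignment(aln)
  m <- aln_matrix(aln)
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  n <- nrow(m)
  out <- matrix(100, n, n, dimnames = list(aln$label, aln$label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      out[i, j] <- out[j, i] <-
        if (nc == 0) NA_real_ else 100 * sum(m[i, comp] == m[j, comp]) / nc
    }
  }
  out
}
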