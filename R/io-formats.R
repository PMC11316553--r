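#' Read and write FASTA assemblies
#'
#' `read_fasta()` loads a (possibly multi-line) FASTA file into an
#' [assembly()], one contig per record, in file order; lowercase bases are
#' folded to uppercase and ambiguity codes are mapped to `N`. `write_fasta()`
#' is its inverse; round trips preserve ids and sequences.
#'
#' @param path Path to a FASTA file (may be gzipped).
#' @param label Assembly label; defaults to the file name without extension.
#' @return `read_fasta()` returns an [assembly()]; `write_fasta()` returns
#'   `path` invisibly.
#' @export
read_fasta <- function(path, label = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  if (file.size(path) == 0) rlang::abort(paste0("empty FASTA file: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) {
      rlang::abort(paste0("FASTA parse error in ", path, ": ",
                          conditionMessage(e)))
    }
  )
  if (length(set) == 0) {
    rlang::abort(paste0("empty FASTA file: ", path))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    rlang::abort(paste0("FASTA record with empty id in ", path))
  }
  assembly(tibble::tibble(contig_id = ids, seq = unname(as.character(set))),
           label = label %||% sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                                  basename(path)))
}

#' @param x An [assembly()] (or object coercible with [as_assembly()]).
#' @param width Line width for wrapping sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(x, path, width = 70L) {
  x <- as_assembly(x)
  set <- Biostrings::DNAStringSet(x$seq)
  names(set) <- x$contig_id
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

#' Read and write paired FASTQ files
#'
#' Reads an R1/R2 FASTQ file pair (4-line records, Phred+33) into a
#' [paired_reads()] tibble, zipping mates in file order and retaining
#' quality strings verbatim. The two files must contain the same number of
#' records.
#'
#' @param path_r1,path_r2 Paths to the mate-1 and mate-2 FASTQ files.
#' @param source_label Label for the read set; defaults to the R1 file name.
#' @return A [paired_reads()] tibble.
#' @export
read_fastq_pair <- function(path_r1, path_r2, source_label = NULL) {
  # strict 4-line-per-record reader: truncated or malformed blocks must be
  # a parse error, never silently mis-paired
  read_one <- function(p) {
    if (!file.exists(p)) rlang::abort(paste0("file not found: ", p))
    lines <- readLines(p)
    if (length(lines) %% 4 != 0) {
      rlang::abort(sprintf(
        "FASTQ parse error in %s: %d lines is not a whole number of 4-line records",
        p, length(lines)
      ))
    }
    n <- length(lines) %/% 4
    hdr <- lines[seq(1, by = 4, length.out = n)]
    seq <- lines[seq(2, by = 4, length.out = n)]
    plus <- lines[seq(3, by = 4, length.out = n)]
    qual <- lines[seq(4, by = 4, length.out = n)]
    bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                   nchar(seq) != nchar(qual))
    if (length(bad) > 0) {
      rlang::abort(sprintf("FASTQ parse error in %s: malformed record %d (line %d)",
                           p, bad[1], (bad[1] - 1) * 4 + 1))
    }
    list(id = sub("\\s.*$", "", substring(hdr, 2)), seq = seq, qual = qual)
  }
  r1 <- read_one(path_r1)
  r2 <- read_one(path_r2)
  if (length(r1$seq) != length(r2$seq)) {
    rlang::abort(sprintf(
      "R1/R2 record counts differ (%d vs %d); cannot pair %s and %s",
      length(r1$seq), length(r2$seq), path_r1, path_r2
    ))
  }
  paired_reads(
    tibble::tibble(read_id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
                   seq2 = r2$seq, qual2 = r2$qual),
    source_label = source_label %||% sub("\\.(fq|fastq)(\\.gz)?$", "",
                                         basename(path_r1))
  )
}

#' @param reads A [paired_reads()] tibble.
#' @rdname read_fastq_pair
#' @export
write_fastq_pair <- function(reads, path_r1, path_r2) {
  stopifnot(inherits(reads, "paired_reads"))
  write_one <- function(seqs, quals, ids, p) {
    set <- Biostrings::DNAStringSet(seqs)
    names(set) <- ids
    Biostrings::writeXStringSet(set, p, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  write_one(reads$seq1, reads$qual1, reads$read_id, path_r1)
  write_one(reads$seq2, reads$qual2, reads$read_id, path_r2)
  invisible(c(path_r1, path_r2))
}

#' Drop short contigs from an assembly
#'
#' Removes contigs strictly shorter than `min_len` (the conventional
#' post-assembly trim; the boundary length is kept), preserving contig
#' order. Idempotent; warns if nothing survives.
#'
#' @param x An [assembly()].
#' @param min_len Minimum contig length to keep (default 1000 bp).
#' @return The filtered [assembly()].
#' @export
filter_contigs <- function(x, min_len = 1000L) {
  stopifnot(inherits(x, "assembly"), min_len >= 1)
  keep <- nchar(x$seq) >= min_len
  out <- assembly(tibble::as_tibble(x)[keep, ], label = assembly_label(x))
  if (nrow(out) == 0 && nrow(x) > 0) {
    rlang::warn(sprintf("all %d contigs of '%s' are shorter than %d bp",
                        nrow(x), assembly_label(x), as.integer(min_len)))
  }
  out
}

ani_table_cols <- c("query", "reference", "ani",
                    "fragments_mapped", "fragments_total")

#' Read and write five-column ANI tables
#'
#' Parses the headerless tab-separated dialect used by fragment-mapping ANI
#' tools: query path/label, reference path/label, ANI percent, mapped
#' fragment count, total fragment count. Values are validated (ANI in
#' \[0, 100\], non-negative integer counts, mapped <= total).
#'
#' @param path Path to the tab-separated table.
#' @return A tibble with columns `query`, `reference`, `ani`,
#'   `fragments_mapped`, `fragments_total`.
#' @export
parse_ani_table <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(query = character(), reference = character(),
                          ani = numeric(), fragments_mapped = integer(),
                          fragments_total = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 5L)) {
    rlang::abort(sprintf(
      "ANI table dialect error: expected 5 tab-separated columns, got %d on line %d",
      nf[which(nf != 5L)[1]], which(nf != 5L)[1]
    ))
  }
  m <- do.call(rbind, fields)
  ani <- suppressWarnings(as.numeric(m[, 3]))
  mapped <- suppressWarnings(as.integer(m[, 4]))
  total <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(ani)) {
    rlang::abort(sprintf("non-numeric ANI value on line %d", which(is.na(ani))[1]))
  }
  if (any(ani < 0 | ani > 100)) {
    rlang::abort(sprintf("ANI value out of [0, 100] on line %d",
                         which(ani < 0 | ani > 100)[1]))
  }
  if (anyNA(mapped) || anyNA(total) || any(mapped < 0) || any(total < 0)) {
    rlang::abort("fragment counts must be non-negative integers")
  }
  if (any(mapped > total)) {
    rlang::abort(sprintf("fragments_mapped > fragments_total on line %d",
                         which(mapped > total)[1]))
  }
  tibble::tibble(query = m[, 1], reference = m[, 2], ani = ani,
                 fragments_mapped = mapped, fragments_total = total)
}

#' @param records A data frame with the five ANI-table columns.
#' @rdname parse_ani_table
#' @export
write_ani_table <- function(records, path) {
  stopifnot(all(ani_table_cols %in% names(records)))
  readr::write_tsv(records[, ani_table_cols], path, col_names = FALSE)
  invisible(path)
}
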