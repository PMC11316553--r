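#' Parse a CRISPR spacer table
#'
#' Reads the three-column tab-separated export of a CRISPR detection tool
#' (contig, start coordinate, spacer sequence; a header line is detected
#' and skipped). Rows are grouped into one spacer array per contig, with
#' spacers in coordinate order. An empty file yields an empty set of
#' arrays — the "no CRISPR–Cas system" case.
#'
#' @param path Path to the TSV file.
#' @param genome_label Label of the genome the spacers belong to.
#' @return A `spacer_arrays` object: tibble with columns `contig_id` and
#'   list-column `spacers`, attribute `genome_label`.
#' @export
parse_spacers <- function(path, genome_label = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  genome_label <- genome_label %||% sub("\\.[^.]*$", "", basename(path))
  if (length(lines) > 0) {
    first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2])))) {
      lines <- lines[-1]  # header
    }
  }
  if (length(lines) == 0) {
    return(spacer_arrays(tibble::tibble(contig_id = character(),
                                        spacers = list()), genome_label))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad) > 0) {
    rlang::abort(sprintf("spacer table parse error: expected 3 columns on line %d",
                         bad[1]))
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.numeric(m[, 2]))
  if (anyNA(start)) {
    rlang::abort(sprintf("non-numeric start coordinate on line %d",
                         which(is.na(start))[1]))
  }
  df <- tibble::tibble(contig_id = m[, 1], start = start,
                       spacer = clean_seq(m[, 3], "spacer table"))
  df <- dplyr::arrange(df, match(.data$contig_id, unique(df$contig_id)),
                       .data$start)
  grouped <- dplyr::summarise(dplyr::group_by(df, .data$contig_id),
                              spacers = list(.data$spacer), .groups = "drop")
  grouped <- grouped[match(unique(df$contig_id), grouped$contig_id), ]
  spacer_arrays(grouped, genome_label)
}

#' @param arrays Tibble with columns `contig_id` and list-column `spacers`.
#' @rdname parse_spacers
#' @export
spacer_arrays <- function(arrays, genome_label = "genome") {
  stopifnot(is.data.frame(arrays),
            all(c("contig_id", "spacers") %in% names(arrays)))
  arrays <- tibble::as_tibble(arrays)[, c("contig_id", "spacers")]
  structure(arrays, genome_label = genome_label,
            class = c("spacer_arrays", class(tibble::tibble())))
}

# flip an array to the other strand: reverse order, reverse-complement each
flip_array <- function(spacers) rev(revcomp(spacers))

array_key <- function(spacers) paste(spacers, collapse = "|")

#' Canonical form of spacer arrays
#'
#' Maps each array to the lexicographically smaller of its two strand
#' readings (the spacer list as given, and the reverse-complemented
#' reversed list), so the same array detected on opposite strands gets the
#' same form. Idempotent.
#'
#' @param arrays A `spacer_arrays` object, or a list of character vectors.
#' @return A list of canonical spacer vectors (one per array).
#' @export
canonicalize <- function(arrays) {
  lst <- if (inherits(arrays, "spacer_arrays")) arrays$spacers else arrays
  lapply(lst, function(sp) {
    sp <- toupper(sp)
    fl <- flip_array(sp)
    if (array_key(fl) < array_key(sp)) fl else sp
  })
}

# all permutations of seq_len(n), n small
perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1]] <- append(sub, n, after = pos)
    }
  }
  out
}

# every full-array concatenation reachable by reordering the arrays and,
# when allow_flips, reading any subset on the other strand
concat_keys <- function(lst, allow_flips = TRUE) {
  n <- length(lst)
  keys <- character()
  flips <- lapply(lst, flip_array)
  combos <- if (allow_flips) {
    expand.grid(rep(list(c(FALSE, TRUE)), n))
  } else {
    as.data.frame(matrix(FALSE, 1, n))
  }
  for (perm in perms(n)) {
    for (r in seq_len(nrow(combos))) {
      use_flip <- as.logical(combos[r, ])
      full <- unlist(lapply(seq_len(n), function(i) {
        if (use_flip[i]) flips[[perm[i]]] else lst[[perm[i]]]
      }))
      keys <- c(keys, array_key(full))
    }
  }
  unique(keys)
}

#' Test two genomes' CRISPR spacer arrays for equivalence
#'
#' Two genomes carry the same CRISPR array when some concatenation order of
#' one genome's arrays (each readable on either strand) equals some
#' concatenation order of the other's, spacer by spacer — so the verdict is
#' invariant under strand flips and under arrays split across contigs.
#' Spacer matching is exact and case-insensitive. Shared/unique spacer
#' counts are computed over strand-canonicalized spacer multisets whatever
#' the verdict. With more than `max_exhaustive` arrays on a side the
#' order search is skipped and the verdict falls back to the multiset
#' comparison, with a warning.
#'
#' Two genomes with no spacers at all compare as `identical` with
#' `no_crispr_system = TRUE` (reported distinctly rather than as evidence
#' of shared strain history).
#'
#' @param a,b `spacer_arrays` objects (or lists of character vectors).
#' @param max_exhaustive Largest per-genome array count for the exhaustive
#'   order/strand search (default 6).
#' @return A one-row tibble: `verdict` (identical/different),
#'   `shared_spacers`, `only_a`, `only_b`, `orientation_used`,
#'   `split_resolved`, `no_crispr_system`.
#' @export
arrays_equivalent <- function(a, b, max_exhaustive = 6L) {
  la <- if (inherits(a, "spacer_arrays")) a$spacers else a
  lb <- if (inherits(b, "spacer_arrays")) b$spacers else b
  la <- lapply(la, toupper)
  lb <- lapply(lb, toupper)
  # spacer multiset counts, each spacer canonicalized to its smaller strand
  canon_spacer <- function(s) pmin(s, revcomp(s))
  ms_a <- unlist(lapply(la, canon_spacer)) %||% character()
  ms_b <- unlist(lapply(lb, canon_spacer)) %||% character()
  ta <- table(ms_a)
  tb <- table(ms_b)
  common <- intersect(names(ta), names(tb))
  shared <- sum(pmin(ta[common], tb[common]))
  only_a <- length(ms_a) - shared
  only_b <- length(ms_b) - shared
  if (length(la) == 0 && length(lb) == 0) {
    return(tibble::tibble(verdict = "identical", shared_spacers = 0L,
                          only_a = 0L, only_b = 0L,
                          orientation_used = NA_character_,
                          split_resolved = FALSE, no_crispr_system = TRUE))
  }
  if (length(la) > max_exhaustive || length(lb) > max_exhaustive) {
    rlang::warn(paste0(
      "more than ", max_exhaustive, " arrays on one side: order search ",
      "skipped, verdict from spacer multisets only"
    ))
    identical_arrays <- only_a == 0 && only_b == 0
    orientation <- NA_character_
  } else if (length(la) == 0 || length(lb) == 0) {
    identical_arrays <- FALSE
    orientation <- NA_character_
  } else {
    keys_a <- concat_keys(la)
    keys_b <- concat_keys(lb)
    identical_arrays <- any(keys_b %in% keys_a)
    orientation <- if (!identical_arrays) NA_character_ else {
      # forward = the two genomes' arrays already match without any strand
      # flip on either side
      fwd <- any(concat_keys(lb, allow_flips = FALSE) %in%
                   concat_keys(la, allow_flips = FALSE))
      if (fwd) "forward" else "reverse-complement"
    }
  }
  profile <- function(l) paste(sort(lengths(l)), collapse = ",")
  tibble::tibble(
    verdict = if (identical_arrays) "identical" else "different",
    shared_spacers = as.integer(shared),
    only_a = as.integer(only_a),
    only_b = as.integer(only_b),
    orientation_used = orientation,
    split_resolved = identical_arrays && profile(la) != profile(lb),
    no_crispr_system = FALSE
  )
}
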