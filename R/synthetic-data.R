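#' Generate a random ancestral genome
#'
#' Draws an i.i.d. nucleotide sequence with a target GC fraction, the root
#' from which synthetic strains are derived. Reproducible under a fixed
#' seed.
#'
#' @param length Genome length in bp (>= 1).
#' @param gc_fraction Probability that a base is G or C, in (0, 1). The
#'   default 0.37 is typical of the vaginal/urinary *Lactobacillus* species
#'   whose strain structure the simulator emulates.
#' @param seed Optional integer seed.
#' @param label Genome label.
#' @return A [genome()].
#' @examples
#' g <- generate_ancestor(1e4, seed = 1)
#' @export
generate_ancestor <- function(length, gc_fraction = 0.37, seed = NULL,
                              label = "ancestor") {
  if (length < 1) rlang::abort("genome length must be >= 1")
  if (!(gc_fraction > 0 && gc_fraction < 1)) {
    rlang::abort("gc_fraction must be strictly inside (0, 1)")
  }
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq <- with_seed_opt(seed, {
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  })
  genome(seq, label = label)
}

#' Derive a mutated strain from a parent genome
#'
#' Applies independent per-base substitutions (SNVs) at `snv_rate` and short
#' indels at `indel_rate` (lengths 1 + Geometric, mean 3), returning the
#' child genome together with a mutation log whose replay on the parent
#' reproduces the child exactly. The log is the ground truth used by the
#' Hamming-identity oracle for the ANI estimator.
#'
#' Events are placed one per parent position; positions swallowed by a
#' deletion carry no further events. Log positions are 0-based on the
#' parent; insertion payloads attach after their position.
#'
#' @param parent A [genome()].
#' @param snv_rate,indel_rate Per-base event probabilities, each in
#'   \[0, 0.1\].
#' @param seed Optional integer seed.
#' @param label Child label (default: parent label + "_mut").
#' @return A list with elements `genome` (the child, `lineage` set to the
#'   parent label) and `log` (tibble: `position`, `type`, `ref`, `alt`).
#' @export
derive_strain <- function(parent, snv_rate, indel_rate = 0, seed = NULL,
                          label = NULL) {
  stopifnot(inherits(parent, "genome"))
  if (snv_rate < 0 || snv_rate > 0.1 || indel_rate < 0 || indel_rate > 0.1) {
    rlang::abort("snv_rate and indel_rate must lie in [0, 0.1]")
  }
  label <- label %||% paste0(parent$label, "_mut")
  L <- nchar(parent$seq)
  log <- with_seed_opt(seed, {
    snv_pos <- which(runif(L) < snv_rate)
    ind_pos <- setdiff(which(runif(L) < indel_rate), snv_pos)
    ev <- list()
    if (length(snv_pos) > 0) {
      ref <- substring(parent$seq, snv_pos, snv_pos)
      others <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                     G = c("A", "C", "T"), T = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))
      alt <- vapply(ref, function(b) sample(others[[b]], 1), "",
                    USE.NAMES = FALSE)
      ev$snv <- tibble::tibble(position = snv_pos, type = "SNV",
                               ref = ref, alt = alt)
    }
    if (length(ind_pos) > 0) {
      len <- 1L + rgeom(length(ind_pos), 1 / 3)
      is_ins <- runif(length(ind_pos)) < 0.5
      payload <- vapply(len, function(l) {
        paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
      }, "")
      del_end <- pmin(ind_pos + len - 1L, L)
      ev$indel <- tibble::tibble(
        position = ind_pos,
        type = ifelse(is_ins, "insertion", "deletion"),
        ref = ifelse(is_ins, "",
                     substring(parent$seq, ind_pos, del_end)),
        alt = ifelse(is_ins, payload, "")
      )
    }
    events <- if (length(ev) == 0) NULL else {
      dplyr::arrange(dplyr::bind_rows(ev), .data$position)
    }
    # drop events inside an earlier deletion's span
    if (!is.null(events) && nrow(events) > 1) {
      covered_until <- 0L
      keep <- logical(nrow(events))
      for (i in seq_len(nrow(events))) {
        if (events$position[i] <= covered_until) next
        keep[i] <- TRUE
        if (events$type[i] == "deletion") {
          covered_until <- events$position[i] + nchar(events$ref[i]) - 1L
        }
      }
      events <- events[keep, ]
    }
    events
  })
  if (is.null(log) || nrow(log) == 0) {
    log <- tibble::tibble(position = integer(), type = character(),
                          ref = character(), alt = character())
  }
  log$position <- as.integer(log$position - 1L)  # 0-based on parent
  child <- replay_mutations(parent, log)
  child$label <- label
  child$lineage <- parent$label
  list(genome = child, log = log)
}

#' Replay a mutation log on a parent genome
#'
#' @param parent A [genome()].
#' @param log A mutation log as produced by [derive_strain()] (0-based
#'   `position`, `type` in SNV/insertion/deletion, `ref`, `alt`).
#' @return The reconstructed child [genome()].
#' @export
replay_mutations <- function(parent, log) {
  stopifnot(inherits(parent, "genome"))
  ch <- strsplit(parent$seq, "", fixed = TRUE)[[1]]
  keep <- rep(TRUE, length(ch))
  if (nrow(log) > 0) {
    if (is.unsorted(log$position, strictly = TRUE)) {
      rlang::abort("mutation log positions must be strictly increasing")
    }
    pos <- log$position + 1L  # back to 1-based
    for (i in seq_len(nrow(log))) {
      p <- pos[i]
      switch(log$type[i],
        SNV = { ch[p] <- log$alt[i] },
        insertion = { ch[p] <- paste0(ch[p], log$alt[i]) },
        deletion = { keep[p:(p + nchar(log$ref[i]) - 1L)] <- FALSE },
        rlang::abort(paste0("unknown mutation type: ", log$type[i]))
      )
    }
  }
  genome(paste(ch[keep], collapse = ""), label = paste0(parent$label, "_replay"),
         lineage = parent$label)
}

#' Write a mutation log to a tab-separated file
#'
#' @param log Mutation log tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_log <- function(log, path) {
  readr::write_tsv(log, path)
  invisible(path)
}

#' Simulate paired-end reads
#'
#' Draws uniform fragment start positions, normal insert sizes, and emits
#' 2 x `read_len` bp pairs: mate 1 is the forward fragment start, mate 2 the
#' reverse complement of the fragment end. Per-base substitution errors are
#' injected at `error_rate`. Quality strings are constant (quality modelling
#' is out of scope).
#'
#' @param genome A [genome()].
#' @param n_pairs Number of read pairs.
#' @param read_len Read length (default 150, as for 300-cycle paired-end
#'   Illumina kits).
#' @param insert_mean,insert_sd Insert size distribution; clipped to
#'   \[`read_len`, genome length\].
#' @param error_rate Per-base substitution error probability, in \[0, 0.1\].
#' @param seed Optional integer seed.
#' @return A [paired_reads()] tibble with `n_pairs` rows.
#' @export
simulate_reads <- function(genome, n_pairs, read_len = 150L,
                           insert_mean = 300L, insert_sd = 25,
                           error_rate = 0.001, seed = NULL) {
  stopifnot(inherits(genome, "genome"), n_pairs >= 0)
  L <- nchar(genome$seq)
  if (!(read_len <= insert_mean && insert_mean <= L)) {
    rlang::abort("need read_len <= insert_mean <= genome length")
  }
  if (error_rate < 0 || error_rate > 0.1) {
    rlang::abort("error_rate must lie in [0, 0.1]")
  }
  with_seed_opt(seed, {
    ins <- pmin(L, pmax(read_len, round(rnorm(n_pairs, insert_mean, insert_sd))))
    start <- floor(runif(n_pairs) * (L - ins + 1)) + 1L
    m1 <- substring(genome$seq, start, start + read_len - 1L)
    m2 <- if (n_pairs > 0) {
      revcomp(substring(genome$seq, start + ins - read_len, start + ins - 1L))
    } else character()
    m1 <- cpp_inject_errors(m1, error_rate)
    m2 <- cpp_inject_errors(m2, error_rate)
    qual <- strrep("I", read_len)
    paired_reads(
      tibble::tibble(
        read_id = sprintf("%s_read%07d", genome$label, seq_len(n_pairs)),
        seq1 = m1, qual1 = rep(qual, n_pairs),
        seq2 = m2, qual2 = rep(qual, n_pairs)
      ),
      source_label = genome$label
    )
  })
}

#' Assembly emulation model
#'
#' Parameters of the desk-scale assembly emulator. Depth is drawn per
#' `window` bp as Poisson(`mean_depth`); windows below `min_contig_depth`
#' are treated as coverage gaps that break (and drop) contigs. Within kept
#' windows, each base is replaced by a wrong consensus base with the exact
#' binomial probability that a strict majority of the window's `d` reads
#' carry the same wrong base when each read errs with probability
#' `base_error_rate` (see [consensus_error_prob()]).
#'
#' @param mean_depth Mean effective consensus depth per window (>= 0).
#' @param base_error_rate Per-read, per-base error probability in \[0, 1).
#' @param min_contig_depth Minimum window depth retained in a contig (>= 1).
#' @param window Window size in bp for the Poisson coverage model.
#' @return An `assembly_model` object.
#' @export
assembly_model <- function(mean_depth = 5, base_error_rate = 0.05,
                           min_contig_depth = 2L, window = 1000L) {
  stopifnot(is.finite(mean_depth), mean_depth >= 0,
            base_error_rate >= 0, base_error_rate < 1,
            min_contig_depth >= 1, window >= 1)
  structure(list(mean_depth = mean_depth, base_error_rate = base_error_rate,
                 min_contig_depth = as.integer(min_contig_depth),
                 window = as.integer(window)),
            class = "assembly_model")
}

#' Consensus error probability under majority vote
#'
#' Exact probability that a strict majority of `depth` overlapping reads
#' carry the same wrong base at a site, when each read independently errs
#' with probability `base_error_rate` (errors uniform over the three
#' alternatives): `3 * P(Binom(d, e/3) > d/2)`. This decays rapidly with
#' depth (compare any depth `d` with `d + 2`; consecutive depths alternate
#' slightly because the majority threshold moves only at odd depths).
#'
#' @param depth Integer vector of read depths.
#' @param base_error_rate Per-read error probability.
#' @return Numeric vector of consensus error probabilities (depth 0 gives 1:
#'   no evidence).
#' @export
consensus_error_prob <- function(depth, base_error_rate) {
  p <- ifelse(depth <= 0, 1,
              pmin(1, 3 * pbinom(floor(depth / 2), depth,
                                 base_error_rate / 3, lower.tail = FALSE)))
  as.numeric(p)
}

#' Emulate a draft assembly of a genome
#'
#' Desk-scale surrogate for read assembly: splits the genome into contigs at
#' simulated coverage gaps and applies per-base consensus errors, so that
#' replicate emulations of the same genome yield ANI values slightly below
#' 100 with replicate-to-replicate spread — the statistical structure the
#' same-strain null distribution is built from. With
#' `base_error_rate = 0` the contigs are exact subsequences of the genome.
#'
#' @param genome A [genome()].
#' @param model An [assembly_model()].
#' @param seed Optional integer seed.
#' @param min_contig_len Contigs shorter than this are dropped via
#'   [filter_contigs()] (default 1000 bp).
#' @param label Assembly label (default: genome label + "_asm").
#' @return An [assembly()].
#' @export
emulate_assembly <- function(genome, model = assembly_model(), seed = NULL,
                             min_contig_len = 1000L, label = NULL) {
  stopifnot(inherits(genome, "genome"), inherits(model, "assembly_model"))
  label <- label %||% paste0(genome$label, "_asm")
  L <- nchar(genome$seq)
  if (model$mean_depth == 0) {
    rlang::warn("mean_depth = 0: no coverage, empty assembly")
    return(assembly(tibble::tibble(contig_id = character(), seq = character()),
                    label = label))
  }
  with_seed_opt(seed, {
    w <- model$window
    nw <- ceiling(L / w)
    depth <- rpois(nw, model$mean_depth)
    keep <- depth >= model$min_contig_depth
    perr <- consensus_error_prob(depth, model$base_error_rate)
    runs <- rle(keep)
    ends_w <- cumsum(runs$lengths)
    starts_w <- ends_w - runs$lengths + 1L
    contigs <- list()
    ci <- 0L
    for (r in seq_along(runs$values)) {
      if (!runs$values[r]) next
      from <- (starts_w[r] - 1L) * w + 1L
      to <- min(ends_w[r] * w, L)
      seq <- substring(genome$seq, from, to)
      if (model$base_error_rate > 0) {
        # per-base error probability follows the window it falls in
        p <- rep(perr[starts_w[r]:ends_w[r]], each = w)[seq_len(to - from + 1L)]
        idx <- which(runif(to - from + 1L) < p)
        if (length(idx) > 0) {
          ch <- strsplit(seq, "", fixed = TRUE)[[1]]
          others <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                         G = c("A", "C", "T"), T = c("A", "C", "G"),
                         N = c("A", "C", "G", "T"))
          ch[idx] <- vapply(ch[idx], function(b) sample(others[[b]], 1), "",
                            USE.NAMES = FALSE)
          seq <- paste(ch, collapse = "")
        }
      }
      ci <- ci + 1L
      contigs[[ci]] <- tibble::tibble(
        contig_id = sprintf("%s_ctg%03d", label, ci), seq = seq
      )
    }
    out <- assembly(
      if (ci == 0L) tibble::tibble(contig_id = character(), seq = character())
      else dplyr::bind_rows(contigs),
      label = label
    )
    if (nrow(out) == 0) {
      rlang::warn(paste0("no window reached min_contig_depth; empty assembly for ",
                         label))
      return(out)
    }
    suppressWarnings(filter_contigs(out, min_contig_len))
  })
}
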