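# shared in-code fixtures; everything is generated, nothing is stored

`%||%` <- function(a, b) if (is.null(a)) b else a

fix_assembly <- function(seqs, label = "fix") {
  ids <- if (length(seqs)) paste0("c", seq_along(seqs)) else character()
  as_assembly(stats::setNames(seqs, ids), label = label)
}

# write a small FASTA file and return its path
write_tmp_fasta <- function(records, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "fix.fa")
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

# minimal independent FASTQ writer (4-line records)
write_tmp_fastq <- function(seqs, path, quals = NULL) {
  quals <- quals %||% strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(paste0("@r", seq_along(seqs)), seqs, "+", quals)),
             path)
  path
}

# independent reverse complement (no package code)
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# brute-force left-tail ECDF
oracle_ecdf_p <- function(null, obs) {
  vapply(obs, function(o) sum(null <= o) / length(null), 0)
}

# naive per-column SNP scan over a list of equal-length row strings
oracle_count_snps <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  considered <- 0L
  snps <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (all(col %in% c("A", "C", "G", "T"))) {
      considered <- considered + 1L
      if (length(unique(col)) > 1) snps <- snps + 1L
    }
  }
  list(snp_count = snps, columns_considered = considered)
}

# small standard simulation: ancestor + strains at given divergence
make_strain_family <- function(n_strains = 2, length = 50000, divergence = 0.0025,
                               seed = 1100, label = "anc") {
  anc <- generate_ancestor(length, seed = seed, label = label)
  strains <- lapply(seq_len(n_strains), function(i) {
    derive_strain(anc, divergence, 0, seed = seed + i,
                  label = paste0(label, "_s", i))
  })
  list(ancestor = anc, strains = strains)
}
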