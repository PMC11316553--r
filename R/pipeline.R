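#' Pipeline configuration
#'
#' Collects every numeric parameter of the strain-identity pipeline with
#' the standard defaults: 150000 read pairs per replicate, 50 replicates
#' (paired off into 25 disjoint ANI comparisons per strain), 10000
#' bootstrap draws, k = 16 with 3000 bp fragments for ANI, a 1000 bp
#' minimum contig length, and classification thresholds 0.05 / 0.95.
#'
#' @param n_pairs Read pairs per subsample replicate.
#' @param n_replicates Replicates per strain (even).
#' @param bootstrap_B Bootstrap draws for the null distribution.
#' @param k K-mer size for ANI anchoring.
#' @param fragment_len ANI fragment length in bp.
#' @param min_contig_len Minimum contig length kept in assemblies.
#' @param p_low,p_high Classification thresholds (`p < p_low` different,
#'   `p >= p_high` identical).
#' @param master_seed Master seed; every random stage derives its seed from
#'   it.
#' @param assembly_model An [assembly_model()] for the emulator backend.
#' @param assembly_backend `"emulator"`, or a function
#'   `function(reads, genome, seed, label)` returning an [assembly()] (an
#'   external-assembler hook; the emulator ignores read bases and is driven
#'   by the genome and the replicate seed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_pairs = 150000L, n_replicates = 50L,
                            bootstrap_B = 10000L, k = 16L,
                            fragment_len = 3000L, min_contig_len = 1000L,
                            p_low = 0.05, p_high = 0.95, master_seed = 1L,
                            assembly_model = strainani::assembly_model(),
                            assembly_backend = "emulator") {
  if (n_replicates %% 2 != 0) {
    rlang::abort("n_replicates must be even (disjoint pairing)")
  }
  if (!(p_low >= 0 && p_low < p_high && p_high <= 1)) {
    rlang::abort("need 0 <= p_low < p_high <= 1")
  }
  structure(
    list(n_pairs = as.integer(n_pairs),
         n_replicates = as.integer(n_replicates),
         bootstrap_B = as.integer(bootstrap_B), k = as.integer(k),
         fragment_len = as.integer(fragment_len),
         min_contig_len = as.integer(min_contig_len),
         p_low = p_low, p_high = p_high,
         master_seed = as.integer(master_seed),
         assembly_model = assembly_model,
         assembly_backend = assembly_backend),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    paste0("<pipeline_config> %d pairs x %d replicates (%d disjoint ANI pairs/strain), ",
           "B = %d, k = %d, fragments %d bp, min contig %d bp, thresholds %.2f/%.2f, ",
           "master seed %d\n"),
    x$n_pairs, x$n_replicates, x$n_replicates / 2, x$bootstrap_B, x$k,
    x$fragment_len, x$min_contig_len, x$p_low, x$p_high, x$master_seed
  ))
  invisible(x)
}

# assemble one replicate through the configured backend
replicate_assembly <- function(config, reads, genome, seed, label) {
  if (is.function(config$assembly_backend)) {
    config$assembly_backend(reads, genome, seed, label)
  } else {
    emulate_assembly(genome, config$assembly_model, seed = seed,
                     min_contig_len = config$min_contig_len, label = label)
  }
}

#' Build per-species same-strain null distributions
#'
#' The null-simulation design: for each strain, the read set is subsampled
#' into `n_replicates` seeded replicates of `n_pairs` whole pairs, each
#' replicate is assembled (emulator backend by default), replicate
#' assemblies are paired disjointly, and one symmetric ANI is computed per
#' pair. Per species, the same-strain ANI values of all strains are pooled,
#' bootstrapped, KDE-fitted, and tested by strain-level ANOVA. Each species
#' is considered independently. Everything is deterministic under
#' `master_seed`.
#'
#' @param strains A tibble with columns `strain`, `species`, `genome`
#'   (list of [genome()]), `reads` (list of [paired_reads()]). A strain
#'   whose read set is smaller than `n_pairs` is skipped with a message and
#'   recorded in the output's `skipped` attribute.
#' @param config A [pipeline_config()].
#' @return A `null_set`: tibble with columns `species` and list-column
#'   `null` (`pooled_null` objects); attributes `values` (all same-strain
#'   ANI values with strain labels and replicate seeds) and `config`.
#' @export
run_null_construction <- function(strains, config = pipeline_config()) {
  stopifnot(is.data.frame(strains),
            all(c("strain", "species", "genome", "reads") %in% names(strains)))
  strain_seeds <- derive_replicate_seeds(config$master_seed, nrow(strains) + 1L)
  skipped <- character()
  vals <- purrr::pmap(
    list(strains$strain, strains$species, strains$genome, strains$reads,
         strain_seeds[seq_len(nrow(strains))]),
    function(strain, species, genome, reads, sseed) {
      if (nrow(reads) < config$n_pairs) {
        rlang::inform(sprintf(
          "skipping strain %s: %d read pairs < n_pairs = %d",
          strain, nrow(reads), config$n_pairs
        ))
        skipped <<- c(skipped, strain)
        return(NULL)
      }
      reps <- make_replicates(reads, config$n_replicates, config$n_pairs,
                              master_seed = sseed)
      asm <- purrr::pmap(list(reps$reads, reps$seed, reps$replicate),
                         function(r, s, i) {
        replicate_assembly(config, r, genome, s,
                           label = sprintf("%s_rep%02d", strain, i))
      })
      pairs <- disjoint_pairs(asm)
      tibble::tibble(
        species = species, strain = strain, pair = pairs$pair,
        seed_a = reps$seed[seq(1, nrow(reps), 2)],
        seed_b = reps$seed[seq(2, nrow(reps), 2)],
        ani = purrr::map2_dbl(pairs$a, pairs$b, function(x, y) {
          symmetric_ani(x, y, config$fragment_len, config$k)
        })
      )
    }
  )
  values <- dplyr::bind_rows(vals)
  if (nrow(values) == 0) rlang::abort("no strain produced null ANI values")
  null_seed <- strain_seeds[length(strain_seeds)]
  by_species <- dplyr::group_split(dplyr::group_by(values, .data$species))
  nulls <- tibble::tibble(
    species = vapply(by_species, function(d) d$species[1], ""),
    null = lapply(by_species, function(d) {
      build_null(d[, c("strain", "ani")], species = d$species[1],
                 B = config$bootstrap_B, seed = null_seed)
    })
  )
  structure(nulls, values = values, config = config, skipped = skipped,
            class = c("null_set", class(tibble::tibble())))
}

#' Classify observed genome pairs against species nulls
#'
#' Projects each observed pair's ANI onto its species' null distribution
#' (the bootstrap-enlarged pooled sample), computes the left-tail empirical
#' P-value, and makes the three-way identical/related/different call.
#'
#' @param nulls A `null_set` from [run_null_construction()], or a named
#'   list of `pooled_null` objects keyed by species.
#' @param observed_pairs Tibble with columns `genome_a`, `genome_b`,
#'   `species`, and either `ani` (numeric) or list-columns `assembly_a`,
#'   `assembly_b` from which symmetric ANI is computed.
#' @param config A [pipeline_config()].
#' @return A `study_report`: list with `calls` (tibble: `genome_a`,
#'   `genome_b`, `species`, `observed_ani`, `empirical_p`, `category`),
#'   `summary` (call counts), `nulls`, and `config`.
#' @export
run_classification <- function(nulls, observed_pairs,
                               config = pipeline_config()) {
  null_list <- if (inherits(nulls, "null_set")) {
    stats::setNames(nulls$null, nulls$species)
  } else {
    nulls
  }
  op <- tibble::as_tibble(observed_pairs)
  if (nrow(op) > 0) {
    stopifnot(all(c("genome_a", "genome_b", "species") %in% names(op)))
    missing_sp <- setdiff(unique(op$species), names(null_list))
    if (length(missing_sp) > 0) {
      rlang::abort(paste0("no null distribution for species: ",
                          paste(missing_sp, collapse = ", ")))
    }
    if (!("ani" %in% names(op))) {
      stopifnot(all(c("assembly_a", "assembly_b") %in% names(op)))
      op$ani <- purrr::map2_dbl(op$assembly_a, op$assembly_b, function(x, y) {
        symmetric_ani(x, y, config$fragment_len, config$k)
      })
    }
    p <- purrr::map2_dbl(op$species, op$ani, function(sp, ani) {
      empirical_p(null_list[[sp]], ani)
    })
    calls <- tibble::tibble(
      genome_a = op$genome_a, genome_b = op$genome_b, species = op$species,
      observed_ani = op$ani, empirical_p = p,
      category = classify_pair(p, config$p_low, config$p_high)
    )
  } else {
    calls <- tibble::tibble(genome_a = character(), genome_b = character(),
                            species = character(), observed_ani = numeric(),
                            empirical_p = numeric(), category = character())
  }
  summary <- c(identical = sum(calls$category == "identical"),
               related = sum(calls$category == "related"),
               different = sum(calls$category == "different"))
  structure(list(calls = calls, summary = summary, nulls = null_list,
                 config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d pair(s): %d identical, %d related, %d different\n",
              nrow(x$calls), x$summary[["identical"]], x$summary[["related"]],
              x$summary[["different"]]))
  invisible(x)
}

#' Run the full strain-identity study
#'
#' Convenience wrapper: [run_null_construction()] then
#' [run_classification()].
#'
#' @inheritParams run_null_construction
#' @inheritParams run_classification
#' @return A `study_report` (see [run_classification()]).
#' @export
run_strain_study <- function(strains, observed_pairs,
                             config = pipeline_config()) {
  nulls <- run_null_construction(strains, config)
  run_classification(nulls, observed_pairs, config)
}
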