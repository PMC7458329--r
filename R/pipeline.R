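#' Build a resolved pipeline configuration
#'
#' Collects every stage's settings, validates key names strictly (unknown
#' keys are rejected) and records the global seed. The defaults describe a
#' small but complete demonstration run on simulated data.
#'
#' @param out_dir output directory for stage CSVs and the resolved-config
#'   copy.
#' @param seed global seed from which all stage seeds are derived.
#' @param discovery a [discovery_sim_config()].
#' @param population a [pop_sim_config()].
#' @param array list: `missing_rate`, `n_duplicates`, `mono_fraction`.
#' @param ascertainment an [ascertainment_config()].
#' @param qc an [array_qc_config()].
#' @param probes list: `k`, `max_hits`, `n_target`.
#' @param popgen list: `n_boot`, `n_perm`, `set_size`, `n_sets`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1,
                            discovery = discovery_sim_config(seed = seed),
                            population = pop_sim_config(
                              n_loci = 400, seed = seed),
                            array = list(missing_rate = 0.02,
                                         n_duplicates = 7,
                                         mono_fraction = 0.05),
                            ascertainment = ascertainment_config(),
                            qc = array_qc_config(),
                            probes = list(k = 16, max_hits = 100,
                                          n_target = 50),
                            popgen = list(n_boot = 200, n_perm = 99,
                                          set_size = 80, n_sets = 20)) {
  check_keys <- function(x, allowed, what) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop("unknown ", what, " keys: ", paste(extra, collapse = ", "),
           call. = FALSE)
  }
  check_keys(array, c("missing_rate", "n_duplicates", "mono_fraction"),
             "array")
  check_keys(probes, c("k", "max_hits", "n_target"), "probes")
  check_keys(popgen, c("n_boot", "n_perm", "set_size", "n_sets"),
             "popgen")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 discovery = discovery, population = population,
                 array = array, ascertainment = ascertainment, qc = qc,
                 probes = probes, popgen = popgen),
            class = "pipeline_config")
}

#' Run the full pipeline on simulated data
#'
#' Executes the whole chain — discovery simulation, ascertainment
#' filtering, probe design and k-mer screening, array-experiment
#' simulation, genotyping QC and the population-genetic suite — writing
#' every stage output as CSV (plus FASTA/VCF/BED for the simulated
#' discovery data) under `cfg$out_dir`, together with a resolved-config
#' JSON and a run log with all derived seeds. Reruns with the same config
#' produce byte-identical CSVs.
#'
#' @param cfg a [pipeline_config()].
#' @return invisible list with every stage result.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(cfg$seed, 4)
  log_lines <- c(sprintf("snpforge pipeline, global seed %d", cfg$seed),
                 sprintf("stage seeds: %s", paste(seeds, collapse = " ")),
                 sprintf("R %s", getRversion()))

  ## stage 1: discovery simulation + ascertainment
  disc_cfg <- cfg$discovery
  disc_cfg$seed <- seeds[1]
  disc <- simulate_discovery_dataset(disc_cfg,
                                     dir = file.path(cfg$out_dir, "sim"))
  asc <- ascertain_variants(disc$variants, disc$reference,
                            cfg$ascertainment, mask = disc$mask,
                            excluded = disc$excluded)
  summary_tbl <- summarize_filter_ledger(asc)
  write.csv(summary_tbl, file.path(cfg$out_dir, "filter_summary.csv"),
            row.names = FALSE)
  catalog <- select_catalog(asc)
  write.csv(catalog, file.path(cfg$out_dir, "catalog.csv"),
            row.names = FALSE)
  log_lines <- c(log_lines, sprintf("ascertainment: %d raw, %d retained",
                                    summary_tbl$count[1], nrow(catalog)))

  ## stage 2: probe design + screening + array content sampling
  idx <- build_kmer_index(disc$reference, cfg$probes$k)
  probes <- do.call(rbind, lapply(seq_len(nrow(catalog)), function(i)
    extract_probe_context(disc$reference, catalog$contig[i],
                          catalog$pos[i], catalog$ref[i], catalog$alt[i],
                          snp_id = catalog$snp_id[i])))
  probes <- screen_probes(probes, idx, cfg$probes$max_hits)
  write.csv(probes, file.path(cfg$out_dir, "probes.csv"),
            row.names = FALSE)
  n_target <- min(cfg$probes$n_target, length(unique(catalog$contig)))
  content <- sample_array_content(catalog, n_target,
                                  contig_lengths = nchar(disc$reference),
                                  seed = seeds[2])
  write.csv(content, file.path(cfg$out_dir, "array_content.csv"),
            row.names = FALSE)

  ## stage 3: population simulation + array experiment + QC
  pop_cfg <- cfg$population
  pop_cfg$seed <- seeds[3]
  hier <- simulate_hierarchical_genotypes(pop_cfg)
  gm <- simulate_array_experiment(hier$truth,
                                  missing_rate = cfg$array$missing_rate,
                                  n_duplicates = cfg$array$n_duplicates,
                                  mono_fraction = cfg$array$mono_fraction,
                                  seed = seeds[4])
  write_calls(gm, file.path(cfg$out_dir, "calls.csv"),
              file.path(cfg$out_dir, "samples.csv"))
  perf <- performance_summary(gm, cfg$qc)
  write.csv(perf$table, file.path(cfg$out_dir, "performance.csv"),
            row.names = FALSE)
  dup <- duplicate_concordance(gm)
  log_lines <- c(log_lines,
                 sprintf("mean duplicate concordance: %.4f", dup$mean))

  ## stage 4: population genetics on converted SNPs from unique samples
  keep_snps <- which(perf$conventional$converted)
  uniq <- is.na(gm$samples$duplicate_of)
  gmu <- subset_samples(subset_loci(gm, keep_snps), uniq)
  div <- diversity_summary(gmu, n_boot = cfg$popgen$n_boot, seed = seeds[3])
  write.csv(div$populations, file.path(cfg$out_dir, "diversity.csv"),
            row.names = FALSE)
  am <- hierarchical_amova(gmu, n_perm = cfg$popgen$n_perm,
                           seed = seeds[3])
  write.csv(data.frame(index = names(am$indices),
                       value = unname(am$indices),
                       p_value = unname(am$p_values)),
            file.path(cfg$out_dir, "amova.csv"), row.names = FALSE)
  pw <- pairwise_fst(gmu, n_perm = 0)
  write.csv(pw$fst, file.path(cfg$out_dir, "pairwise_fst.csv"))
  pc <- pcoa(genetic_distance_matrix(gmu))
  write.csv(data.frame(sample_id = rownames(pc$coordinates),
                       pc$coordinates),
            file.path(cfg$out_dir, "pcoa.csv"), row.names = FALSE)
  sfs <- site_frequency_spectrum(snp_call_metrics(gmu)$maf)
  write.csv(sfs, file.path(cfg$out_dir, "sfs.csv"), row.names = FALSE)
  rs <- subset_resampling(gmu,
                          set_size = min(cfg$popgen$set_size,
                                         ncol(gmu$calls)),
                          n_sets = cfg$popgen$n_sets, seed = seeds[4])
  write.csv(rs, file.path(cfg$out_dir, "resampling.csv"),
            row.names = FALSE)
  lk <- simulate_structure_likelihoods(k_true = 2, seed = seeds[4])
  ev <- evanno_delta_k(lk)
  write.csv(ev, file.path(cfg$out_dir, "evanno.csv"), row.names = FALSE)
  log_lines <- c(log_lines,
                 sprintf("AMOVA: FstR=%.3f FstP/R=%.3f FstT=%.3f",
                         am$indices[1], am$indices[2], am$indices[3]),
                 sprintf("Evanno best K: %d", attr(ev, "best_k")))

  cfg_out <- cfg
  cfg_out$ascertainment <- unclass(cfg_out$ascertainment)
  cfg_out$qc <- unclass(cfg_out$qc)
  cfg_out$discovery <- unclass(cfg_out$discovery)
  cfg_out$population <- unclass(cfg_out$population)
  jsonlite::write_json(unclass(cfg_out),
                       file.path(cfg$out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  invisible(list(discovery = disc, ascertainment = asc,
                 catalog = catalog, probes = probes, content = content,
                 matrix = gm, performance = perf, duplicates = dup,
                 diversity = div, amova = am, pairwise = pw, pcoa = pc,
                 sfs = sfs, resampling = rs, evanno = ev))
}
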