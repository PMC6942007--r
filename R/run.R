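#' Execute a configured experiment
#'
#' The orchestration entry point behind the command-line driver. Creates
#' the output directory, runs the named experiment, writes every result
#' table as TSV plus the resolved configuration and a manifest of output
#' files with MD5 checksums, and logs stage timings to standard error.
#' Runs are fully deterministic given the config (including VCF bytes).
#'
#' Experiments:
#' * `simulate` — one cohort; writes the per-individual table, the
#'   frequency model, the trait architecture, and (optionally) a VCF.
#' * `scenario` — [run_scenario()]; options `case_id` (default 1),
#'   `k_pcs` (default 20); writes the result table and its summary.
#' * `mr` — [two_sample_experiment()]; options `n_exposure`, `n_outcome`
#'   (default 500 each), `gamma` (default 0.5), `delta` (default 0),
#'   `pc_rule`, `k_pcs`; writes the bias table and per-arm summary.
#' * `detect` — empirical FST between the admixture-split halves of one
#'   cohort and the detectability statistic over a sample-size grid.
#' * `project` — synthesizes reference and cohort sharing matrices, fits
#'   the reference SVD, projects the cohort, and reports variance in a
#'   group-linked synthetic phenotype explained by the scores.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `status` (0 on success) and `manifest`
#'   (data frame of files and MD5 checksums).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  log_msg <- function(...) {
    if (config$log_level != "quiet")
      message(sprintf("[stratsim %+8.2fs] ",
                      proc.time()[["elapsed"]] - t0), sprintf(...))
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  files <- character(0)
  emit <- function(df, name) {
    write_tsv(df, out(name))
    files <<- c(files, name)
    log_msg("wrote %s (%d rows)", name, nrow(as.data.frame(df)))
  }
  p <- config$params
  opt <- config$options
  getopt <- function(name, default) opt[[name]] %||% default
  log_msg("experiment '%s' (seed %d)", config$experiment, p$seed)

  switch(config$experiment,
    simulate = {
      co <- make_cohort(p)
      emit(cohort_table(co), "cohort.tsv")
      emit(data.frame(snp = seq_len(p$n_snps),
                      ancestral = co$freqs$ancestral,
                      pop1 = co$freqs$pop1, pop2 = co$freqs$pop2),
           "frequencies.tsv")
      emit(data.frame(snp = seq_len(p$n_snps),
                      causal = co$arch$causal_indicator,
                      beta = co$arch$effect_sizes),
           "architecture.tsv")
      if (config$export_vcf) {
        write_vcf(co, out("genotypes.vcf"))
        files <- c(files, "genotypes.vcf")
        log_msg("wrote genotypes.vcf")
      }
    },
    scenario = {
      res <- run_scenario(p, case_id = getopt("case_id", 1),
                          n_replicates = config$n_replicates,
                          k_pcs = getopt("k_pcs", 20))
      emit(res, "scenario_results.tsv")
      s <- summarize_scenario(res)
      emit(s$by_arm, "scenario_summary.tsv")
      emit(s$paired, "scenario_paired.tsv")
    },
    mr = {
      res <- two_sample_experiment(
        p, n_exposure = getopt("n_exposure", 500),
        n_outcome = getopt("n_outcome", 500),
        gamma = getopt("gamma", 0.5), delta = getopt("delta", 0),
        pc_rule = getopt("pc_rule", "detect"),
        k_pcs = getopt("k_pcs", 20),
        n_replicates = config$n_replicates)
      emit(res, "mr_bias.tsv")
      summ <- do.call(rbind, lapply(split(res, res$arm), function(d)
        data.frame(arm = d$arm[1], mean_bias = mean(d$bias),
                   se_bias = stats::sd(d$bias) / sqrt(nrow(d)),
                   n = nrow(d))))
      emit(summ, "mr_summary.tsv")
    },
    detect = {
      co <- make_cohort(p)
      grp <- co$admixture > stats::median(co$admixture)
      fst <- empirical_fst(co$genotypes, grp)
      grid <- getopt("n_grid", c(100, 500, 1000, 5000, 10000, 100000))
      det <- do.call(rbind, lapply(grid, function(n) {
        d <- detectability(n, p$n_snps, fst)
        data.frame(n = n, L = p$n_snps, fst = fst,
                   statistic = d$statistic, detectable = d$detectable,
                   n_required = d$n_required)
      }))
      emit(det, "detectability.tsv")
    },
    project = {
      K <- getopt("K", 8)
      ref <- synth_sharing_matrix(getopt("n_ref", 400), K,
                                  concentration = getopt("concentration", 50),
                                  seed = p$seed)
      coh <- synth_sharing_matrix(p$n_individuals, K,
                                  concentration = getopt("concentration", 50),
                                  seed = p$seed + 1L)
      basis <- fit_reference_basis(ref)
      scores <- project_cohort(basis, coh)
      # group-linked synthetic phenotype: group mean + unit noise
      pheno <- with_substream(p$seed, "noise", 0L,
                              coh$group + stats::rnorm(nrow(scores)))
      ve <- variance_explained(scores, pheno)
      emit(data.frame(individual = seq_len(nrow(scores)),
                      group = coh$group, scores), "projection_scores.tsv")
      emit(data.frame(component = names(ve$per_component),
                      marginal_r2 = ve$per_component,
                      total_r2 = ve$r2), "variance_explained.tsv")
    })

  write_run_config(config, out("config.json"))
  files <- c(files, "config.json")
  writeLines(as.character(p$seed), out("seed.txt"))
  files <- c(files, "seed.txt")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(
                           config$output_dir, files))))
  write_tsv(manifest, out("manifest.tsv"))
  log_msg("done: %d output file(s)", length(files))
  invisible(list(status = 0L, manifest = manifest))
}
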