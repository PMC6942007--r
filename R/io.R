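#' Export simulated genotypes to VCF
#'
#' Writes a minimal VCF v4.2 with haploid GT calls: SNPs become records at
#' positions `1..L` on a dummy contig, `REF = A`, `ALT = G`, and each
#' individual's 0/1 dosage is its haploid genotype. Deterministic given
#' the cohort, so exports are byte-identical under a fixed seed.
#'
#' @param cohort A `cohort` (or a plain 0/1 genotype matrix).
#' @param path Output file path.
#' @param contig Contig name (default `"sim1"`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cohort, path, contig = "sim1") {
  X <- if (inherits(cohort, "cohort")) cohort$genotypes else as.matrix(cohort)
  if (!all(X %in% c(0L, 1L)))
    stop("VCF export supports haploid 0/1 dosages only", call. = FALSE)
  n <- nrow(X); L <- ncol(X)
  samples <- sprintf("ind%0*d", nchar(n), seq_len(n))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=stratsim",
    sprintf("##contig=<ID=%s,length=%d>", contig, L),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt <- apply(X, 2, function(col) paste(col, collapse = "\t"))
  body <- sprintf("%s\t%d\tsnp%d\tA\tG\t.\tPASS\t.\tGT\t%s",
                  contig, seq_len(L), seq_len(L), gt)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a tidy table as TSV
#'
#' All package outputs use the same convention: tab separation, a header
#' row, no quoting or row names, floating values at 10 significant
#' digits.
#'
#' @param df Data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Cohort tables as a tidy data frame
#'
#' Per-individual table of the cohort's phenotype decomposition:
#' admixture fraction, genetic component, environment, noise, phenotype.
#'
#' @param cohort A `cohort`.
#' @return A data frame with one row per individual.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  data.frame(individual = seq_along(cohort$admixture),
             admixture = cohort$admixture,
             genetic_component = cohort$genetic_component,
             environment = cohort$environment,
             noise = cohort$noise,
             phenotype = cohort$phenotype)
}

#' Run configuration
#'
#' A validated bundle of simulation parameters plus orchestration options
#' that round-trips losslessly through JSON, so a run can be reproduced
#' from the config file it writes beside its outputs.
#'
#' @param params A [sim_params()] object.
#' @param experiment One of `"simulate"`, `"scenario"`, `"mr"`,
#'   `"detect"`, `"project"`.
#' @param output_dir Output directory (created if needed at run time).
#' @param n_replicates Replicates for replicate-based experiments.
#' @param export_vcf Write a VCF of simulated genotypes (simulate runs)?
#' @param log_level `"info"` or `"quiet"`.
#' @param options Named list of experiment-specific options (e.g.,
#'   `case_id`, `k_pcs` for `scenario`; `n_exposure`, `n_outcome`,
#'   `gamma`, `delta` for `mr`).
#' @return A `run_config` list.
#' @export
run_config <- function(params = sim_params(), experiment, output_dir,
                       n_replicates = 20, export_vcf = FALSE,
                       log_level = c("info", "quiet"), options = list()) {
  experiment <- match.arg(experiment,
                          c("simulate", "scenario", "mr", "detect",
                            "project"))
  log_level <- match.arg(log_level)
  validate_sim_params(params)
  stopifnot(is.character(output_dir), length(output_dir) == 1,
            n_replicates >= 1, is.logical(export_vcf), is.list(options))
  structure(list(params = params, experiment = experiment,
                 output_dir = output_dir,
                 n_replicates = as.integer(n_replicates),
                 export_vcf = export_vcf, log_level = log_level,
                 options = options),
            class = "run_config")
}

#' Write / read a run configuration
#'
#' JSON serialization of a [run_config()]. `read_run_config()` re-validates
#' everything, so editing the file by hand cannot smuggle in an invalid
#' parameter; the round trip is lossless.
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- unclass(config)
  obj$params <- unclass(obj$params)
  obj$params$sigma_a2 <- NULL  # derived; recomputed on read
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(sim_params, obj$params)
  run_config(params = params, experiment = obj$experiment,
             output_dir = obj$output_dir,
             n_replicates = obj$n_replicates,
             export_vcf = obj$export_vcf, log_level = obj$log_level,
             options = as.list(obj$options))
}
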