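# End-to-end orchestration: read the five input tables plus the protein,
# run design -> responder calling -> association -> MAPPs -> integration,
# and write all result tables with a parameter-echo log.

default_pipeline_params <- list(
  window = 15L, stagger = 5L, pool_size = 10L, min_terminal = 7L,
  alpha = 0.05, family = "donor", ev_threshold = 0.05, min_length = 9L,
  mode = "partial", distinct = "region", min_overlap = 1L
)

#' Validate and normalise a pipeline configuration
#'
#' @param config Named list or path to a YAML file. Required entries:
#'   `fasta`, `counts`, `genotypes_tcell`, `genotypes_mapps`,
#'   `allele_freqs`, `mapps`, `out_dir`. Optional analysis parameters
#'   (with defaults): `window` 15, `stagger` 5, `pool_size` 10,
#'   `min_terminal` 7, `alpha` 0.05, `family` "donor", `ev_threshold`
#'   0.05, `min_length` 9, `mode` "partial", `distinct` "region",
#'   `min_overlap` 1.
#' @return Normalised config list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  required <- c("fasta", "counts", "genotypes_tcell", "genotypes_mapps",
                "allele_freqs", "mapps", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0L) {
    stop("pipeline config is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (p in setdiff(required, "out_dir")) {
    if (!file.exists(config[[p]])) {
      stop("input file for '", p, "' does not exist: ", config[[p]],
           call. = FALSE)
    }
  }
  params <- utils::modifyList(default_pipeline_params,
                              config[intersect(names(config),
                                               names(default_pipeline_params))])
  c(config[required], params)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full three-part analysis pipeline
#'
#' Executes library design, responder calling, allele association and
#' promiscuity scoring (both rules), MAPPs filtering/mapping/merging, and
#' the final integration, writing every result table as TSV under
#' `out_dir` plus a `run_log.yaml` echoing parameters and package version
#' (no timestamps, so identical inputs give byte-identical output).
#'
#' @param config See [pipeline_config()].
#' @return Named character vector of output paths (the manifest),
#'   invisibly; the in-memory results are attached as the `"results"`
#'   attribute.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  protein <- stage("peptide_library", read_protein_fasta(config$fasta))
  library <- stage("peptide_library",
                   peptide_library(protein, config$window, config$stagger,
                                   config$pool_size, config$min_terminal))
  pools <- attr(library, "pools")

  counts <- stage("responder_calling",
                  read_stimulation_counts(config$counts))
  calls <- stage("responder_calling",
                 call_responders(counts, alpha = config$alpha,
                                 family = config$family))
  pct <- stage("responder_calling", percent_responders(calls))
  per_donor <- stage("responder_calling", pools_per_donor(calls))
  lfc <- stage("responder_calling", log_fold_change_table(counts))

  genotypes_tcell <- stage("hla_association",
                           read_genotype_table(config$genotypes_tcell))
  genotypes_mapps <- stage("hla_association",
                           read_genotype_table(config$genotypes_mapps))
  freqs <- stage("hla_association",
                 read_allele_frequencies(config$allele_freqs))
  map_any <- stage("hla_association",
                   build_association_map(calls, genotypes_tcell, "any"))
  map_all <- stage("hla_association",
                   build_association_map(calls, genotypes_tcell, "all"))
  prom_any <- stage("hla_association", promiscuity_scores(map_any, freqs))
  prom_all <- stage("hla_association", promiscuity_scores(map_all, freqs))

  mapps_raw <- stage("mapps_processing", read_mapps_table(config$mapps))
  mapps_sig <- stage("mapps_processing",
                     filter_by_expect_value(mapps_raw,
                                            config$ev_threshold))
  mapps_mapped <- stage("mapps_processing",
                        map_mapps_peptides(mapps_sig, protein))
  regions <- stage("mapps_processing",
                   merge_regions(mapps_mapped, scope = "cohort",
                                 min_overlap = config$min_overlap))
  mapps_summary <- stage("mapps_processing",
                         summarize_mapps(mapps_mapped, regions))
  per_donor_regions <- stage("mapps_processing",
                             per_donor_unique_counts(mapps_mapped,
                                                     config$min_overlap))

  integration <- stage(
    "integration",
    integrate_epitopes(calls, mapps_mapped, genotypes_tcell,
                       genotypes_mapps, pools, protein,
                       min_length = config$min_length,
                       mode = config$mode, distinct = config$distinct))
  coverage <- stage("integration",
                    epitope_population_coverage(integration, freqs))

  manifest <- c(
    library = out("library.tsv"),
    pools = out("pools.tsv"),
    calls = out("responder_calls.tsv"),
    percent_responders = out("percent_responders.tsv"),
    pools_per_donor = out("pools_per_donor.tsv"),
    lfc = out("log_fold_change.tsv"),
    association_any = out("association_any.tsv"),
    association_all = out("association_all.tsv"),
    promiscuity_any = out("promiscuity_any.tsv"),
    promiscuity_all = out("promiscuity_all.tsv"),
    mapps_mapped = out("mapps_mapped.tsv"),
    mapps_regions = out("mapps_regions.tsv"),
    mapps_summary = out("mapps_summary.tsv"),
    per_donor_regions = out("per_donor_regions.tsv"),
    candidates = out("epitope_candidates.tsv"),
    run_log = out("run_log.yaml")
  )
  write_peptide_library(library, manifest["library"])
  readr::write_tsv(pools[, c("pool_id", "n_peptides", "span_start",
                             "span_end")], manifest["pools"])
  readr::write_tsv(calls, manifest["calls"])
  readr::write_tsv(pct, manifest["percent_responders"])
  readr::write_tsv(per_donor, manifest["pools_per_donor"])
  readr::write_tsv(lfc, manifest["lfc"])
  write_association_matrix(map_any, manifest["association_any"])
  write_association_matrix(map_all, manifest["association_all"])
  readr::write_tsv(prom_any, manifest["promiscuity_any"])
  readr::write_tsv(prom_all, manifest["promiscuity_all"])
  readr::write_tsv(mapps_mapped[, c("donor_id", "sequence",
                                    "expect_value", "start", "end")],
                   manifest["mapps_mapped"])
  readr::write_tsv(regions %>%
                     dplyr::mutate(donors = vapply(.data$donors, paste,
                                                   character(1),
                                                   collapse = ",")) %>%
                     dplyr::select("start", "end", "n_peptides",
                                   "n_donors", "donors"),
                   manifest["mapps_regions"])
  readr::write_tsv(mapps_summary, manifest["mapps_summary"])
  readr::write_tsv(per_donor_regions, manifest["per_donor_regions"])
  write_epitope_candidates(integration, manifest["candidates"])
  yaml::write_yaml(
    list(package = "epimapr",
         version = as.character(utils::packageVersion("epimapr")),
         parameters = config[names(default_pipeline_params)],
         inputs = config[c("fasta", "counts", "genotypes_tcell",
                           "genotypes_mapps", "allele_freqs", "mapps")],
         n_candidates = nrow(integration$candidates),
         cumulative_allele_frequency_pct = coverage),
    manifest["run_log"])

  results <- list(library = library, pools = pools, calls = calls,
                  percent_responders = pct, pools_per_donor = per_donor,
                  association = list(any = map_any, all = map_all),
                  promiscuity = list(any = prom_any, all = prom_all),
                  mapps = mapps_mapped, regions = regions,
                  mapps_summary = mapps_summary,
                  per_donor_regions = per_donor_regions,
                  integration = integration, coverage = coverage)
  attr(manifest, "results") <- results
  invisible(manifest)
}
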