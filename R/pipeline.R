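#' Pipeline configuration
#'
#' A single validated configuration object for the whole fingerprinting
#' pipeline.  Every threshold carries its reference default: marker
#' filter 5% heterozygosity / 10% missing / 0.05 MAF; purity levels at
#' 1% and 5% with the 3% re-genotyping trigger; identity classes at 95%
#' and 99% similarity with the 85% mislabel-diagnosis cut; 0.05
#' relatedness guard on new-line release.  Unknown keys are rejected.
#'
#' @param out_dir output directory for stage artifacts.
#' @param genotype_file wide-calls CSV input (ignored when the
#'   `simulate` stage generates the panel).
#' @param marker_file optional marker metadata CSV.
#' @param simulation a [simulation_config()] for the `simulate` stage
#'   (default: [paper_like_preset()] with `seed`).
#' @param filter a [filter_thresholds()] object.
#' @param pure_max,basic_max,regenotype_min purity thresholds, percent.
#' @param identical_min,drift_min,mislabel_sim_max,het_issue_min
#'   identity/diagnosis thresholds, percent.
#' @param consensus_het_max replicate heterozygosity bound (percent)
#'   for preferred inclusion in the consensus.
#' @param missing_policy replicate-merge missing policy
#'   (`"observed"`/`"strict"`).
#' @param nj_mode mislabel NJ cross-check mode
#'   (`"advisory"`/`"strict"`/`"off"`).
#' @param distance_breaks distance-distribution bin breaks.
#' @param relatedness_guard minimum release distance.
#' @param pca_components number of principal components.
#' @param conversion_max flag threshold for parent-conversion pairs.
#' @param seed integer seed (drives the `simulate` stage).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            genotype_file = NULL,
                            marker_file = NULL,
                            simulation = NULL,
                            filter = filter_thresholds(),
                            pure_max = 1, basic_max = 5, regenotype_min = 3,
                            identical_min = 99, drift_min = 95,
                            mislabel_sim_max = 85, het_issue_min = 5,
                            consensus_het_max = 3,
                            missing_policy = c("observed", "strict"),
                            nj_mode = c("advisory", "strict", "off"),
                            distance_breaks = c(0.05, 0.10, 0.30, 0.50),
                            relatedness_guard = 0.05,
                            pca_components = 3,
                            conversion_max = 0.2,
                            seed = 1) {
  missing_policy <- match.arg(missing_policy)
  nj_mode <- match.arg(nj_mode)
  if (is.null(simulation)) simulation <- paper_like_preset(seed = seed)
  cfg <- as.list(environment())
  stopifnot(inherits(cfg$filter, "filter_thresholds"),
            inherits(cfg$simulation, "simulation_config"),
            pure_max > 0, basic_max > pure_max, regenotype_min > 0,
            drift_min < identical_min, mislabel_sim_max <= drift_min,
            relatedness_guard >= 0, pca_components >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Validate a raw configuration list against `pipeline_config()`
#'
#' Rejects unknown keys with a schema error listing the offending
#' fields, then builds the validated configuration.  This is what the
#' command-line wrapper uses for `--config` files.
#'
#' @param x named list of configuration fields.
#' @return a validated `pipeline_config`.
#' @export
as_pipeline_config <- function(x) {
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, x)
}

stage_artifacts <- list(
  simulate = c("genotypes.csv", "markers.csv", "truth_samples.csv"),
  markerqc = c("marker_stats.csv", "exclusions.csv", "retained_markers.txt",
               "chromosome_summary.csv"),
  sampleqc = c("purity.csv", "identity.csv", "flags.csv"),
  reference = c("reference.csv", "provenance.csv", "reference_summary.json"),
  diversity = c("distances.csv", "bins.csv", "subgroups.csv",
                "pca_coords.csv", "pca_variance.csv", "tree.nwk"))

#' Run one pipeline stage
#'
#' Runs a single stage against the artifacts already present in
#' `config$out_dir`, and writes that stage's artifacts there.  Stages
#' and their outputs:
#' \describe{
#'   \item{simulate}{`genotypes.csv`, `markers.csv`, `truth_samples.csv`}
#'   \item{markerqc}{`marker_stats.csv`, `exclusions.csv`,
#'     `retained_markers.txt`, `chromosome_summary.csv`}
#'   \item{sampleqc}{`purity.csv`, `identity.csv`, `flags.csv`}
#'   \item{reference}{`reference.csv` (wide dialect), `provenance.csv`,
#'     `reference_summary.json`}
#'   \item{diversity}{`distances.csv`, `bins.csv`, `subgroups.csv`,
#'     `pca_coords.csv`, `pca_variance.csv`, `tree.nwk`}
#' }
#' A stage whose inputs are missing stops with the name of the missing
#' artifact.  Stages never mutate their inputs; reruns with identical
#' inputs and configuration are byte-identical.
#'
#' @param name stage name (see above), or `"all"` for the full chain.
#' @param config a [pipeline_config()].
#' @return invisibly, the paths of the artifacts written.
#' @export
run_stage <- function(name = c("simulate", "markerqc", "sampleqc",
                               "reference", "diversity", "all"),
                      config) {
  name <- match.arg(name)
  stopifnot(inherits(config, "pipeline_config"))
  if (name == "all") return(run_pipeline(config))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  need <- function(files) {
    p <- file.path(out, files)
    ok <- file.exists(p)
    if (!all(ok)) {
      stop("stage '", name, "' requires missing artifact(s): ",
           paste(files[!ok], collapse = ", "),
           " — run the earlier stages first")
    }
  }
  load_gm <- function() {
    need(c("genotypes.csv", "markers.csv"))
    read_genotype_table(file.path(out, "genotypes.csv"), "wide",
                        markers = read_marker_table(file.path(out, "markers.csv")))
  }
  written <- switch(name,
    simulate = {
      panel <- simulate_panel(config$simulation)
      write_genotype_table(panel$genotypes, file.path(out, "genotypes.csv"),
                           "wide")
      write_marker_table(panel$genotypes$markers, file.path(out, "markers.csv"))
      utils::write.csv(panel$truth$samples,
                       file.path(out, "truth_samples.csv"), row.names = FALSE)
      stage_artifacts$simulate
    },
    markerqc = {
      gm <- if (!is.null(config$genotype_file) &&
                !file.exists(file.path(out, "genotypes.csv"))) {
        ingest_input(config, out)
      } else load_gm()
      stats <- compute_marker_stats(gm)
      flt <- filter_markers(stats, config$filter)
      summ <- summarize_by_chromosome(stats, gm$markers)
      utils::write.csv(stats, file.path(out, "marker_stats.csv"),
                       row.names = FALSE)
      utils::write.csv(flt$exclusions, file.path(out, "exclusions.csv"),
                       row.names = FALSE)
      writeLines(flt$retained, file.path(out, "retained_markers.txt"))
      utils::write.csv(summ$per_chromosome,
                       file.path(out, "chromosome_summary.csv"),
                       row.names = FALSE)
      stage_artifacts$markerqc
    },
    sampleqc = {
      gm <- load_gm()
      purity <- classify_purity(gm, config$pure_max, config$basic_max,
                                config$regenotype_min)
      identity <- classify_identity(gm, purity, config$identical_min,
                                    config$drift_min, config$mislabel_sim_max,
                                    config$het_issue_min)
      screen <- cross_line_similarity_screen(gm)
      utils::write.csv(purity, file.path(out, "purity.csv"), row.names = FALSE)
      utils::write.csv(identity, file.path(out, "identity.csv"),
                       row.names = FALSE)
      utils::write.csv(screen$flags, file.path(out, "flags.csv"),
                       row.names = FALSE)
      stage_artifacts$sampleqc
    },
    reference = {
      need(c("retained_markers.txt", "purity.csv", "flags.csv"))
      gm <- load_gm()
      retained <- readLines(file.path(out, "retained_markers.txt"))
      purity <- utils::read.csv(file.path(out, "purity.csv"),
                                stringsAsFactors = FALSE)
      flags <- utils::read.csv(file.path(out, "flags.csv"),
                               stringsAsFactors = FALSE)
      res <- resolve_mislabels(gm, flags$line_name[flags$flagged],
                               config$drift_min, config$nj_mode)
      ref <- build_reference(gm, retained, purity, res,
                             config$consensus_het_max, config$missing_policy)
      write_genotype_table(ref$genotypes, file.path(out, "reference.csv"),
                           "wide")
      utils::write.csv(ref$provenance, file.path(out, "provenance.csv"),
                       row.names = FALSE)
      jsonlite::write_json(c(ref$summary,
                             list(missing_lines = ref$missing_lines)),
                           file.path(out, "reference_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stage_artifacts$reference
    },
    diversity = {
      need(c("reference.csv", "markers.csv"))
      markers <- read_marker_table(file.path(out, "markers.csv"))
      ref_gm <- read_genotype_table(file.path(out, "reference.csv"), "wide")
      dm <- distance_matrix(ref_gm)
      bins <- bin_distances(dm, config$distance_breaks,
                            config$relatedness_guard)
      grp <- stats::setNames(ref_gm$samples$subgroup,
                             ref_gm$samples$sample_id)
      sg <- if (any(!is.na(grp))) subgroup_distances(dm, grp) else NULL
      pc <- genotype_pca(ref_gm, config$pca_components)
      tree <- nj_tree(dm)
      utils::write.csv(as.data.frame(dm), file.path(out, "distances.csv"))
      utils::write.csv(bins$bins, file.path(out, "bins.csv"),
                       row.names = FALSE)
      if (!is.null(sg)) {
        utils::write.csv(sg, file.path(out, "subgroups.csv"),
                         row.names = FALSE)
      } else {
        utils::write.csv(data.frame(), file.path(out, "subgroups.csv"),
                         row.names = FALSE)
      }
      utils::write.csv(as.data.frame(pc$scores),
                       file.path(out, "pca_coords.csv"))
      utils::write.csv(data.frame(component = seq_along(pc$explained),
                                  explained_fraction = pc$explained),
                       file.path(out, "pca_variance.csv"), row.names = FALSE)
      ape::write.tree(tree, file.path(out, "tree.nwk"))
      stage_artifacts$diversity
    })
  write_run_log(config, out)
  invisible(file.path(out, written))
}

## Copy an external genotype input into the run directory (stages never
## mutate their inputs; all downstream stages read the run-local copy).
ingest_input <- function(config, out) {
  markers <- if (!is.null(config$marker_file))
    read_marker_table(config$marker_file) else NULL
  gm <- read_genotype_table(config$genotype_file, "wide", markers = markers)
  write_genotype_table(gm, file.path(out, "genotypes.csv"), "wide")
  write_marker_table(gm$markers, file.path(out, "markers.csv"))
  gm
}

write_run_log <- function(config, out) {
  cfg_plain <- unclass(config)
  cfg_plain$filter <- unclass(cfg_plain$filter)
  cfg_plain$simulation <- unclass(cfg_plain$simulation)
  tf <- tempfile(); on.exit(unlink(tf))
  jsonlite::write_json(cfg_plain, tf, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  files <- setdiff(list.files(out), "run_log.json")
  sums <- tools::md5sum(file.path(out, files))
  log <- list(package_version = as.character(utils::packageVersion("kaspqc")),
              seed = config$seed,
              config_md5 = unname(tools::md5sum(tf)),
              artifact_md5 = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(log)
}

#' Run the full pipeline
#'
#' Chains the stages in pipeline order:
#' simulate (or ingest an input file) -> markerqc -> sampleqc ->
#' reference -> diversity.
#'
#' @param config a [pipeline_config()].
#' @param stages stages to run, in order.
#' @return invisibly, all artifact paths written.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "markerqc", "sampleqc",
                                    "reference", "diversity")) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$genotype_file)) stages <- setdiff(stages, "simulate")
  paths <- unlist(lapply(stages, run_stage, config = config))
  invisible(paths)
}
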