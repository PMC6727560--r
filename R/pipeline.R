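# Pipeline configuration and orchestration.
#
# A configuration is a strict named list; defaults carry the analysis
# constants: FPKM < 1 means not expressed, Xist/Eif2s3y >= 1.5 calls
# female and < 1 male, FDR alpha 0.05 for single-cell stages and 0.01 for
# the cardiac-precursor bulk comparison, candidate soft-threshold powers
# 1..20 with scale-free R^2 cut 0.8, minimum module size 50, eigengene
# merge cut 0.25, STRING minimum combined score 0.7 with text-mining-only
# edges dropped, and motif p cutoff 1e-5 over the -5000..+1000 promoter
# window. The soft-threshold power itself is data-derived (an output of
# pick_soft_threshold), never a configuration default. All randomness
# flows from the single top-level seed through per-stage derived seeds.

#' Default pipeline configuration
#' @return named list of defaults (see [validate_config()]).
#' @export
default_config <- function() {
  list(
    fpkm_not_expressed = 1.0,
    sex_ratio_female = 1.5,
    sex_ratio_male = 1.0,
    de_alpha = list(single_cell = 0.05, cardiac_precursor = 0.01),
    wgcna = list(powers = 1:20, r2_cut = 0.8, min_module_size = 50,
                 merge_cut = 0.25),
    ppi = list(min_score = 0.7, drop_textmining = TRUE),
    motif = list(p_cutoff = 1e-5, window_upstream = 5000,
                 window_downstream = 1000),
    seed = 1L,
    out_dir = "cardiosex_out"
  )
}

#' Validate a pipeline configuration
#'
#' Injects defaults for missing keys, rejects unknown keys (strict), and
#' range-checks every threshold.
#'
#' @param config named list (e.g. parsed from a JSON file with
#'   [read_config()]); `NULL` yields pure defaults.
#' @return the validated, completed configuration.
#' @export
validate_config <- function(config = NULL) {
  def <- default_config()
  if (is.null(config)) return(def)
  if (!is.list(config)) stop("config must be a named list")
  merge_strict <- function(d, c, path = "") {
    unknown <- setdiff(names(c), names(d))
    if (length(unknown) > 0)
      stop("unknown config key: ", paste0(path, unknown[1L]))
    for (nm in names(c)) {
      d[[nm]] <- if (is.list(d[[nm]]) && is.list(c[[nm]]))
        merge_strict(d[[nm]], c[[nm]], paste0(path, nm, "."))
      else c[[nm]]
    }
    d
  }
  cfg <- merge_strict(def, config)
  .check_number(cfg$fpkm_not_expressed, "fpkm_not_expressed", lower = 0)
  .check_number(cfg$sex_ratio_female, "sex_ratio_female", lower = 0)
  .check_number(cfg$sex_ratio_male, "sex_ratio_male", lower = 0)
  if (cfg$sex_ratio_male > cfg$sex_ratio_female)
    stop("sex_ratio_male must not exceed sex_ratio_female")
  for (nm in names(cfg$de_alpha)) {
    a <- cfg$de_alpha[[nm]]
    if (!is.numeric(a) || a <= 0 || a >= 1)
      stop("de_alpha.", nm, " must lie in (0, 1)")
  }
  .check_number(cfg$wgcna$r2_cut, "wgcna.r2_cut", lower = 0, upper = 1)
  .check_number(cfg$wgcna$min_module_size, "wgcna.min_module_size", lower = 2)
  .check_number(cfg$wgcna$merge_cut, "wgcna.merge_cut", lower = 0, upper = 1)
  .check_number(cfg$ppi$min_score, "ppi.min_score", lower = 0, upper = 1)
  .check_number(cfg$motif$p_cutoff, "motif.p_cutoff", lower = 1e-300, upper = 1)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed) ||
      cfg$seed < 0)
    stop("seed must be a single non-negative integer")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Read a JSON configuration file
#' @param path JSON path.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  validate_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

# derive per-stage seeds from the master seed (kept below 2^31)
.stage_seed <- function(seed, k) (as.integer(seed) * 97L + k * 1009L) %% 2147483629L

#' Run the synthetic end-to-end pipeline
#'
#' Generates a bulk ES panel and per-stage single-cell panels, sexes the
#' cells, runs the per-stage differential tests, assembles the bias table,
#' classifies trajectories, writes all outputs as TSV under
#' `config$out_dir`, and records a JSON manifest (package version, seeds,
#' thresholds, input digests, per-stage summaries). Rerunning with an
#' identical configuration reproduces identical outputs.
#'
#' @param config validated configuration from [validate_config()].
#' @param sc_stages single-cell stages to simulate, default E8.5/E9.5/E10.5.
#' @param n_cells cells per single-cell stage (kept modest by default so
#'   the synthetic run stays interactive).
#' @return the manifest, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = NULL, sc_stages = c("E8.5", "E9.5", "E10.5"),
                         n_cells = 200) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) message(sprintf("[%s] %s", stage,
                                                    sprintf(...)))
  manifest <- list(package = "cardiosex",
                   version = as.character(utils::packageVersion("cardiosex")),
                   seed = cfg$seed, config = cfg, stages = list())

  t0 <- proc.time()[["elapsed"]]
  bulk <- simulate_bulk_panel(seed = .stage_seed(cfg$seed, 1L))
  bulk_path <- file.path(cfg$out_dir, "bulk_es_fpkm.tsv")
  write_expression_tsv(bulk$matrix, bulk_path)
  log_stage("simulate", "bulk panel: %d genes x %d samples",
            nrow(bulk$matrix$values), ncol(bulk$matrix$values))
  manifest$stages$simulate <- list(genes = nrow(bulk$matrix$values),
                                   samples = ncol(bulk$matrix$values))

  stage_results <- list()
  stage_results$ES <- stage_de(bulk$matrix, stage = "ES",
                               alpha = cfg$de_alpha$cardiac_precursor,
                               presence_threshold = cfg$fpkm_not_expressed)
  for (k in seq_along(sc_stages)) {
    st <- sc_stages[k]
    sim <- simulate_cells(stage = st, n_cells = n_cells,
                          seed = .stage_seed(cfg$seed, 10L + k))
    calls <- sex_cells(sim$matrix, female_cut = cfg$sex_ratio_female,
                       male_cut = cfg$sex_ratio_male)
    write_sex_calls_tsv(calls, file.path(cfg$out_dir,
                                         sprintf("sex_calls_%s.tsv", st)))
    acc <- mean(calls$call[calls$usable] ==
                sim$truth$cell_sexes[calls$usable])
    log_stage("sex-cells", "%s: %d/%d usable calls, accuracy %.3f",
              st, sum(calls$usable), nrow(calls), acc)
    stage_results[[st]] <- stage_de(sim$matrix, stage = st,
                                    sex_source = calls,
                                    alpha = cfg$de_alpha$single_cell,
                                    presence_threshold = cfg$fpkm_not_expressed)
    manifest$stages[[st]] <- list(cells = nrow(calls),
                                  usable = sum(calls$usable),
                                  sexing_accuracy = acc,
                                  n_biased = sum(stage_results[[st]]$bias
                                                 %in% c("XX", "XY")))
  }
  for (st in names(stage_results)) {
    utils::write.table(stage_results[[st]],
                       file.path(cfg$out_dir, sprintf("de_%s.tsv", st)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  bt <- build_bias_table(stage_results)
  traj <- classify_trajectories(bt)
  utils::write.table(traj, file.path(cfg$out_dir, "trajectory_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$trajectory <- as.list(table(traj$group))
  log_stage("trajectory", "groups: %s",
            paste(sprintf("%s=%d", names(table(traj$group)),
                          table(traj$group)), collapse = ", "))

  outputs <- list.files(cfg$out_dir, full.names = TRUE, pattern = "\\.tsv$")
  manifest$digests <- as.list(tools::md5sum(outputs))
  manifest$elapsed_s <- proc.time()[["elapsed"]] - t0
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
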