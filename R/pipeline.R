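# One-config orchestration of the full analysis:
# tables_io -> pollution -> diversity -> association -> network,
# with per-stage derived seeds, collected warnings and a JSON report.

.config_defaults <- list(
  otu = NULL, soil = NULL, metals = NULL, backgrounds = NULL,
  out_dir = "paddynet_out",
  min_prevalence = 0.9,
  scan = list(t_min = 0.3, t_max = 0.99, step = 0.01),
  permutations = 999, n_random = 100, seed = 42,
  nmds_k = 2, nmds_restarts = 20,
  stages = c("pollution", "diversity", "association", "network"))

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a list; fills documented defaults
#' (`min_prevalence` 0.9, `n_random` 100, `permutations` 999, scan
#' 0.30-0.99 by 0.01), rejects unknown keys by name, and checks that
#' every input path referenced by a requested stage exists.
#'
#' @param config YAML file path or named list.
#' @return validated config list (class `pipeline_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path", call. = FALSE)
  unknown <- setdiff(names(config), names(.config_defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(.config_defaults, config)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || cfg$seed < 0 ||
      cfg$seed != round(cfg$seed))
    stop("seed must be a non-negative integer", call. = FALSE)
  sc <- cfg$scan
  if (!is.numeric(sc$step) || sc$step <= 0)
    stop("scan step must be > 0", call. = FALSE)
  if (sc$t_min <= 0 || sc$t_max >= 1 || sc$t_min >= sc$t_max)
    stop("scan range must satisfy 0 < t_min < t_max < 1", call. = FALSE)
  if (cfg$min_prevalence <= 0 || cfg$min_prevalence > 1)
    stop("min_prevalence must be in (0, 1]", call. = FALSE)
  if (cfg$permutations < 99) stop("permutations must be >= 99", call. = FALSE)
  if (cfg$n_random < 2) stop("n_random must be >= 2", call. = FALSE)
  bad_stage <- setdiff(cfg$stages, .config_defaults$stages)
  if (length(bad_stage))
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "), call. = FALSE)
  need <- list(pollution = c("metals", "backgrounds"),
               diversity = "otu",
               association = c("otu", "soil"),
               network = "otu")
  for (st in cfg$stages)
    for (inp in need[[st]])
      if (is.null(cfg[[inp]]))
        stop("stage '", st, "' requires input '", inp, "'", call. = FALSE)
  for (inp in c("otu", "soil", "metals", "backgrounds"))
    if (is.character(cfg[[inp]]) && !file.exists(cfg[[inp]]))
      stop("input path does not exist: ", cfg[[inp]], call. = FALSE)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

# aggregate OTU counts to relative phylum abundances (2nd lineage field)
#' Phylum-level relative abundances
#' @param table an [otu_table] with taxonomy.
#' @return samples x phyla matrix of relative abundances.
#' @export
phylum_abundance <- function(table) {
  if (is.null(table$taxonomy)) stop("otu table has no taxonomy", call. = FALSE)
  phylum <- vapply(strsplit(as.character(table$taxonomy), ";"), function(s)
    if (length(s) >= 2) trimws(s[2]) else "Unclassified", character(1))
  rel <- table$counts / rowSums(table$counts)
  t(rowsum(t(rel), group = phylum))
}

#' Run the full pipeline
#'
#' Executes the requested stages in dependency order over one validated
#' configuration. Inputs may be file paths or in-memory tables. Each
#' stage's outputs are written under `out_dir`; a stage failure is
#' recorded in the report and the remaining (independent) stages still
#' run. Stage seeds are derived from the master seed by fixed offsets
#' (diversity +1, association +2, network +3) so stages can be rerun
#' independently. The report is written to `out_dir/report.json`.
#'
#' @param config a [validate_config()]-accepted config (path or list).
#' @return report list: per-stage status and output paths, seeds,
#'   versions, timestamps and collected warnings.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  warn_log <- character(0)
  report <- list(package_version = as.character(utils::packageVersion("paddynet")),
                 r_version = R.version.string,
                 started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 seed = cfg$seed, stages = list())
  grab <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  load_in <- function(x, reader) if (is.character(x)) grab(reader(x)) else x
  otu <- if (!is.null(cfg$otu)) load_in(cfg$otu, read_otu_table)
  soil <- if (!is.null(cfg$soil)) load_in(cfg$soil, read_soil_table)
  metals <- if (!is.null(cfg$metals)) load_in(cfg$metals, read_metal_table)
  backgrounds <- if (!is.null(cfg$backgrounds))
    load_in(cfg$backgrounds, read_background_table)

  out <- function(f) file.path(cfg$out_dir, f)
  run_stage <- function(name, fun) {
    res <- tryCatch(list(status = "ok", outputs = grab(fun())),
                    error = function(e) list(status = "failed",
                                             message = conditionMessage(e)))
    report$stages[[name]] <<- res
  }

  if ("pollution" %in% cfg$stages) run_stage("pollution", function() {
    pol <- assess_pollution(metals, backgrounds, soil)
    .write_table(pol, out("pollution.tsv"))
    "pollution.tsv"
  })

  if ("diversity" %in% cfg$stages) run_stage("diversity", function() {
    alpha <- alpha_diversity(otu)
    .write_table(alpha, out("alpha.tsv"))
    bc <- bray_curtis_matrix(otu)
    .write_table(cbind(sample_id = rownames(bc), as.data.frame(bc)),
                 out("bray.tsv"))
    ord <- nmds(bc, k = cfg$nmds_k, restarts = cfg$nmds_restarts,
                seed = cfg$seed + 1, depth = rowSums(otu$counts))
    .write_table(cbind(sample_id = rownames(ord$coordinates),
                       as.data.frame(ord$coordinates),
                       stress = ord$stress), out("nmds.tsv"))
    c("alpha.tsv", "bray.tsv", "nmds.tsv")
  })

  if ("association" %in% cfg$stages) run_stage("association", function() {
    env <- environment_table(soil, metals)
    env <- env[match(rownames(otu$counts), rownames(env)), , drop = FALSE]
    alpha <- alpha_diversity(otu)
    files <- character(0)
    regs <- do.call(rbind, lapply(names(env), function(v) {
      fit <- fit_polynomial(env[[v]], alpha$shannon, degree = 1)
      data.frame(response = "shannon", predictor = v, degree = 1,
                 slope = fit$coefficients[2], r_squared = fit$r_squared,
                 p_value = fit$p_value)
    }))
    .write_table(regs, out("regressions.tsv")); files <- c(files, "regressions.tsv")
    imp <- forest_importance(env, alpha$shannon, seed = cfg$seed + 2)
    .write_table(imp, out("importance.tsv")); files <- c(files, "importance.tsv")
    bc <- bray_curtis_matrix(otu)
    mt <- do.call(rbind, lapply(names(env), function(v) {
      denv <- as.matrix(stats::dist(scale(env[[v]])))
      dimnames(denv) <- dimnames(bc)
      m <- mantel_test(bc, denv, permutations = cfg$permutations,
                       seed = cfg$seed + 2)
      data.frame(variable = v, r = m$r, p_value = m$p_value)
    }))
    .write_table(mt, out("mantel.tsv")); files <- c(files, "mantel.tsv")
    if (!is.null(metals)) {
      # sand is excluded: the texture closure clay+silt+sand = 100 makes
      # the block exactly collinear
      soil_block <- env[, intersect(c("som", "ph", "cec", "ec", "clay", "silt",
                                      "tn", "an", "ap", "ak"),
                                    names(env)), drop = FALSE]
      metal_block <- env[, grep("^(total|dtpa)_", names(env)), drop = FALSE]
      if (ncol(metal_block)) {
        vp <- variation_partition(otu$counts, soil_block, metal_block)
        .write_table(data.frame(fraction = names(vp$fractions),
                                value = unname(vp$fractions)),
                     out("vpa.tsv"))
        files <- c(files, "vpa.tsv")
      }
    }
    if (!is.null(otu$taxonomy)) {
      grid <- spearman_grid(phylum_abundance(otu), env)
      .write_table(grid, out("spearman_grid.tsv"))
      files <- c(files, "spearman_grid.tsv")
    }
    files
  })

  if ("network" %in% cfg$stages) run_stage("network", function() {
    core <- prevalence_filter(otu, cfg$min_prevalence)
    corr <- correlation_matrix(core)
    scan <- rmt_threshold(corr, cfg$scan$t_min, cfg$scan$t_max, cfg$scan$step)
    .write_table(scan$candidates, out("scan.tsv"))
    net <- build_network(corr, scan$st)
    modules <- detect_modules(net)
    roles <- node_roles(net, modules)
    topo <- network_topology(net)
    topo$st <- scan$st
    nulls <- null_model_ensemble(net, cfg$n_random, seed = cfg$seed + 3)
    jsonlite::write_json(topo, out("topology.json"), auto_unbox = TRUE,
                         digits = NA)
    .write_table(data.frame(node = names(modules$membership),
                            module = unname(modules$membership)),
                 out("modules.tsv"))
    .write_table(roles, out("roles.tsv"))
    .write_table(do.call(rbind, lapply(c("gd", "avg_cc", "modularity"),
      function(m) data.frame(metric = m, null_mean = nulls[[m]]$mean,
                             null_sd = nulls[[m]]$sd,
                             empirical = nulls[[m]]$empirical,
                             z = nulls[[m]]$z))), out("nullstats.tsv"))
    export_network(net, out("network.graphml"), "graphml", modules, roles,
                   otu$taxonomy)
    export_network(net, out("network.gexf"), "gexf", modules, roles,
                   otu$taxonomy)
    files <- c("scan.tsv", "topology.json", "modules.tsv", "roles.tsv",
               "nullstats.tsv", "network.graphml", "network.gexf")
    if (!is.null(soil)) {
      env <- environment_table(soil, metals)
      env <- env[match(rownames(otu$counts), rownames(env)), , drop = FALSE]
      mm <- module_environment_mantel(core, modules, env,
                                      permutations = cfg$permutations,
                                      seed = cfg$seed + 3)
      .write_table(mm, out("module_mantel.tsv"))
      files <- c(files, "module_mantel.tsv")
    }
    files
  })

  report$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  report$warnings <- warn_log
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  report
}
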