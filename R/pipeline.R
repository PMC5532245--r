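#' Read a run configuration
#'
#' Run configurations are YAML files with one top-level section per
#' pipeline stage (`scenario`, `extent`, `mass`, `condition`) plus
#' optional `seed` and `out_dir`. Each `run_*()` function documents the
#' keys it uses; a missing required key is reported by name.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$`.path` <- path
  structure(cfg, class = "run_config")
}

cfg_get <- function(config, key, default = NULL, required = FALSE) {
  val <- config
  for (k in strsplit(key, ".", fixed = TRUE)[[1]]) {
    val <- val[[k]]
    if (is.null(val)) break
  }
  if (is.null(val)) {
    if (required) stop("missing config key: ", key, call. = FALSE)
    return(default)
  }
  val
}

as_run_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.list(config)) stop("`config` must be a list or a file path")
  config
}

provenance_comment <- function(config, seed) {
  hash <- if (!is.null(config$`.path`)) unname(tools::md5sum(config$`.path`))
          else substr(paste(deparse(config), collapse = ""), 1, 0)
  sprintf("soilcapital %s | config %s | seed %s",
          as.character(utils::packageVersion("soilcapital")),
          if (length(hash) && nzchar(hash)) hash else "inline", seed)
}

log_msg <- function(verbose, ...) {
  if (verbose) message("[soilcapital] ", ...)
}

write_manifest <- function(out_dir, files) {
  paths <- file.path(out_dir, files)
  man <- data.frame(file = files, md5 = unname(tools::md5sum(paths)),
                    stringsAsFactors = FALSE)
  utils::write.csv(man, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  man
}

scenario_from_config <- function(config) {
  sc <- cfg_get(config, "scenario", required = TRUE)
  if (isTRUE(sc$eu25_toy))
    return(eu25_toy_scenario(
      nrow = sc$nrow %||% 100, ncol = sc$ncol %||% 100,
      n_samples = sc$n_samples %||% 2000))
  mix <- unlist(cfg_get(config, "scenario.mixture", required = TRUE))
  tm <- diag(14)
  for (tr in sc$transitions %||% list()) {
    tm[tr$from, tr$to] <- tm[tr$from, tr$to] + tr$p
    tm[tr$from, tr$from] <- tm[tr$from, tr$from] - tr$p
  }
  scenario(nrow = cfg_get(config, "scenario.nrow", required = TRUE),
           ncol = cfg_get(config, "scenario.ncol", required = TRUE),
           cell_area_km2 = sc$cell_area_km2 %||% 1,
           epochs = as.character(sc$epochs %||% c("t0", "t1")),
           mixture = mix, patchiness = sc$patchiness %||% 1,
           transition = transition_matrix(tm),
           n_samples = sc$n_samples %||% 500)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a scenario to files
#'
#' Generates the scenario's epoch grids and soil samples and writes them
#' to `out_dir`: one plain-text grid per epoch (`grid_<epoch>.txt`), the
#' sample table (`samples.csv`), a config echo (`config_echo.yaml`) and a
#' `manifest.csv` of output files with MD5 checksums. Deterministic under
#' (config, seed): re-running reproduces identical checksums.
#'
#' Config keys: `scenario.nrow`, `scenario.ncol`, `scenario.mixture`
#' (required unless `scenario.eu25_toy: true`), and optional
#' `cell_area_km2`, `epochs`, `patchiness`, `transitions`
#' (list of `{from, to, p}`), `n_samples`.
#'
#' @param config A `run_config`, plain list, or YAML path.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed (overrides the config's `seed`).
#' @param verbose Log progress to stderr.
#' @return The manifest data frame, invisibly.
#' @export
run_simulate <- function(config, out_dir = cfg_get(config, "out_dir", "."),
                         seed = NULL, verbose = FALSE) {
  config <- as_run_config(config)
  seed <- seed %||% cfg_get(config, "seed", 1L)
  scn <- scenario_from_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg(verbose, "simulating ", scn$nrow, "x", scn$ncol, " grid over ",
          length(scn$epochs), " epochs (seed ", seed, ")")
  sim <- simulate_scenario(scn, seed = seed)
  files <- character(0)
  for (ep in names(sim$grids)) {
    f <- paste0("grid_", ep, ".txt")
    write_grid(sim$grids[[ep]], file.path(out_dir, f))
    files <- c(files, f)
  }
  write_soil_samples(sim$samples, file.path(out_dir, "samples.csv"),
                     comment = provenance_comment(config, seed))
  echo <- config
  echo$`.path` <- NULL
  yaml::write_yaml(echo, file.path(out_dir, "config_echo.yaml"))
  files <- c(files, "samples.csv", "config_echo.yaml")
  man <- write_manifest(out_dir, files)
  log_msg(verbose, "wrote ", length(files), " files to ", out_dir)
  invisible(man)
}

read_epoch_grids <- function(config, out_dir) {
  paths <- cfg_get(config, "extent.grids",
                   cfg_get(config, "condition.grids"))
  if (is.null(paths)) {
    paths <- sort(list.files(out_dir, "^grid_.*\\.txt$", full.names = TRUE))
  }
  if (length(paths) < 2)
    stop("at least two epoch grids are required")
  lapply(paths, function(p) {
    ep <- sub("^grid_(.*)\\.txt$", "\\1", basename(p))
    read_grid(p, epoch = ep)
  })
}

#' Build and write extent accounts for consecutive epoch pairs
#'
#' Reads the epoch grids (config key `extent.grids`, or every
#' `grid_*.txt` in `out_dir`), builds one extent account per consecutive
#' pair plus a combined first-to-last account, and writes each as a
#' published-layout CSV together with a net-change summary.
#'
#' Optional config keys: `extent.mmu_km2` (minimum mapping unit, default
#' 0), `extent.mode` (`net`/`gross`), `extent.managed_classes`.
#'
#' @inheritParams run_simulate
#' @return The manifest data frame, invisibly.
#' @export
run_extent <- function(config, out_dir = cfg_get(config, "out_dir", "."),
                       seed = NULL, verbose = FALSE) {
  config <- as_run_config(config)
  seed <- seed %||% cfg_get(config, "seed", 1L)
  grids <- read_epoch_grids(config, out_dir)
  mmu <- cfg_get(config, "extent.mmu_km2", 0)
  mode <- cfg_get(config, "extent.mode", "net")
  managed <- cfg_get(config, "extent.managed_classes",
                     managed_seea_classes())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pairs <- Map(c, seq_len(length(grids) - 1), seq_len(length(grids) - 1) + 1)
  if (length(grids) > 2) pairs <- c(pairs, list(c(1L, length(grids))))
  files <- character(0)
  total <- sum(area_by_class(grids[[1]]))
  for (pr in pairs) {
    g0 <- grids[[pr[1]]]; g1 <- grids[[pr[2]]]
    log_msg(verbose, "extent account ", g0$epoch, " -> ", g1$epoch)
    acct <- build_extent_account(change_matrix(g0, g1, mmu),
                                 managed_classes = managed, mode = mode)
    stem <- paste0("extent_", g0$epoch, "_", g1$epoch)
    write_extent_account(acct, file.path(out_dir, paste0(stem, ".csv")),
                         comment = provenance_comment(config, seed))
    nets <- net_change_summary(acct, total)
    write_csv_commented(nets,
                        file.path(out_dir, paste0(stem, "_net.csv")),
                        comment = provenance_comment(config, seed))
    files <- c(files, paste0(stem, ".csv"), paste0(stem, "_net.csv"))
  }
  invisible(write_manifest(out_dir, files))
}

#' Build and write the soil mass-balance account
#'
#' Reads per-class areas and gross erosion rates from
#' `mass.inputs_csv` (columns `seea_code`, `area_ha`,
#' `gross_rate_t_per_ha`; defaults to the packaged EU-25 inputs), builds
#' the mass account and writes it in the published layout together with
#' a per-class depletion summary.
#'
#' Optional config keys: `mass.formation_low` (0.4), `mass.formation_high`
#' (1.4), `mass.delivery_fraction` (0.10), `mass.years` (1).
#'
#' @inheritParams run_simulate
#' @return The manifest data frame, invisibly.
#' @export
run_mass <- function(config, out_dir = cfg_get(config, "out_dir", "."),
                     seed = NULL, verbose = FALSE) {
  config <- as_run_config(config)
  seed <- seed %||% cfg_get(config, "seed", 1L)
  path <- cfg_get(config, "mass.inputs_csv",
                  system.file("extdata", "eu25_mass_inputs.csv",
                              package = "soilcapital"))
  d <- utils::read.csv(path, comment.char = "#")
  need <- c("seea_code", "area_ha", "gross_rate_t_per_ha")
  if (!all(need %in% names(d)))
    stop("mass inputs CSV must have columns: ", paste(need, collapse = ", "))
  rates <- formation_rates(cfg_get(config, "mass.formation_low", 0.4),
                           cfg_get(config, "mass.formation_high", 1.4))
  erosion <- erosion_params(
    stats::setNames(d$gross_rate_t_per_ha, d$seea_code),
    cfg_get(config, "mass.delivery_fraction", 0.10))
  acct <- build_mass_account(stats::setNames(d$area_ha, d$seea_code),
                             rates, erosion,
                             years = cfg_get(config, "mass.years", 1))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg(verbose, "mass account over ",
          sum(!is.na(acct$area_ha)), " accounted classes")
  write_mass_account(acct, file.path(out_dir, "mass_account.csv"),
                     comment = provenance_comment(config, seed))
  write_csv_commented(net_balance_summary(acct),
                      file.path(out_dir, "depletion_summary.csv"),
                      comment = provenance_comment(config, seed))
  invisible(write_manifest(out_dir,
                           c("mass_account.csv", "depletion_summary.csv")))
}

#' Build and write soil-condition cross-tabs
#'
#' Reads soil samples (`condition.samples_csv`, or `samples.csv` in
#' `out_dir`) and the epoch grids, and writes SOC and pH state cross-tabs
#' for each epoch plus change cross-tabs for each consecutive epoch pair.
#' Cover areas are taken from each epoch's grid (km2 converted to ha).
#'
#' @inheritParams run_simulate
#' @return The manifest data frame, invisibly.
#' @export
run_condition <- function(config, out_dir = cfg_get(config, "out_dir", "."),
                          seed = NULL, verbose = FALSE) {
  config <- as_run_config(config)
  seed <- seed %||% cfg_get(config, "seed", 1L)
  spath <- cfg_get(config, "condition.samples_csv",
                   file.path(out_dir, "samples.csv"))
  samples <- read_soil_samples(spath)
  grids <- read_epoch_grids(config, out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (g in grids) {
    areas_ha <- area_by_class(g) * 100
    # only covers that actually carry samples enter the state tab
    areas_ha[setdiff(names(areas_ha),
                     as.character(unique(samples$cover)))] <- 0
    for (cl in c("soc", "ph")) {
      tab <- condition_crosstab(samples, areas_ha, cl)
      f <- paste0("condition_", cl, "_", g$epoch, ".csv")
      write_crosstab(tab, file.path(out_dir, f),
                     comment = provenance_comment(config, seed))
      files <- c(files, f)
    }
  }
  for (i in seq_len(length(grids) - 1)) {
    g0 <- grids[[i]]; g1 <- grids[[i + 1]]
    log_msg(verbose, "change cross-tabs ", g0$epoch, " -> ", g1$epoch)
    for (cl in c("soc", "ph")) {
      tab <- change_condition_crosstab(samples, g0, g1, cl)
      f <- paste0("condition_change_", cl, "_", g0$epoch, "_",
                  g1$epoch, ".csv")
      write_crosstab(tab, file.path(out_dir, f),
                     comment = provenance_comment(config, seed))
      files <- c(files, f)
    }
  }
  invisible(write_manifest(out_dir, files))
}
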