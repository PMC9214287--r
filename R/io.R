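#' Load a model configuration from YAML or JSON
#'
#' Reads a configuration document whose keys mirror the field names of
#' [global_params()], [population_config()] and [intervention_config()]
#' (grouped under top-level keys `global`, `population`, `intervention`,
#' any of which may be omitted). Every omitted field takes its documented
#' default, so an empty document yields the full baseline configuration.
#' All invariants are re-validated on load; violations name the offending
#' field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [adoption_config()] object.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("global:\n  b_max: 2.0\npopulation:\n  omega_mean: 0.3", f)
#' load_config(f)$global$b_max
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc)) doc <- list()
  config_from_list(doc)
}

# Build a validated adoption_config from a plain nested list.
config_from_list <- function(doc) {
  known <- c("global", "population", "intervention")
  extra <- setdiff(names(doc), known)
  if (length(extra))
    stop("unknown top-level config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  take <- function(block, ctor) {
    args <- doc[[block]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad))
      stop("unknown fields in '", block, "': ", paste(bad, collapse = ", "),
           call. = FALSE)
    do.call(ctor, args)
  }
  adoption_config(global = take("global", global_params),
                  population = take("population", population_config),
                  intervention = take("intervention", intervention_config))
}

#' Save a model configuration
#'
#' Writes the configuration as YAML or JSON (chosen from the file
#' extension). A saved configuration reloads to an identical object.
#'
#' @param config An [adoption_config()] object.
#' @param path Destination path (`.yaml`, `.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "adoption_config"))
  doc <- lapply(unclass(config), function(block) {
    block <- unclass(block)
    block[!vapply(block, is.null, logical(1))]
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' Write simulation results with a provenance manifest
#'
#' Writes the trajectory (`trajectory.csv`: columns `t, p, y_bar,
#' mean_y_adopters, mean_y_nonadopters, mean_b`), the per-agent final state
#' with parameters (`agents.csv`), and a JSON manifest (`manifest.json`)
#' recording the configuration, variant, seed, package version, timestamp
#' and output file names. Identical seed and configuration produce
#' byte-identical data files.
#'
#' @param sim An `adoption_sim` object.
#' @param dir Existing destination directory; an error (with the path) is
#'   raised before any file is written if it does not exist.
#' @param stem File-name stem prefixed to the three outputs.
#' @return Named character vector of the written paths, invisibly.
#' @examples
#' cfg <- adoption_config(global = global_params(N = 50))
#' sim <- simulate_adoption(cfg, T = 10, seed = 1)
#' out <- file.path(tempdir(), "run1")
#' dir.create(out)
#' write_results(sim, out)
#' @export
write_results <- function(sim, dir, stem = "") {
  stopifnot(inherits(sim, "adoption_sim"))
  if (!dir.exists(dir))
    stop("output directory does not exist: ", dir, call. = FALSE)
  pre <- if (nzchar(stem)) paste0(stem, "_") else ""
  paths <- c(trajectory = file.path(dir, paste0(pre, "trajectory.csv")),
             agents = file.path(dir, paste0(pre, "agents.csv")),
             manifest = file.path(dir, paste0(pre, "manifest.json")))
  utils::write.csv(sim$trajectory, paths[["trajectory"]], row.names = FALSE)
  agents <- cbind(sim$population$params, sim$population$state)
  utils::write.csv(agents, paths[["agents"]], row.names = FALSE)
  manifest <- list(
    config = lapply(unclass(sim$config), function(b) {
      b <- unclass(b); b[!vapply(b, is.null, logical(1))]
    }),
    variant = sim$variant,
    seed = sim$seed,
    T = sim$T,
    package_version = as.character(utils::packageVersion("techadopt")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = as.list(basename(paths)))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read back written simulation results
#'
#' @param dir Directory written by [write_results()].
#' @param stem File-name stem used when writing.
#' @return A list with `trajectory` (data frame), `agents` (data frame) and
#'   `manifest` (list).
#' @export
read_results <- function(dir, stem = "") {
  pre <- if (nzchar(stem)) paste0(stem, "_") else ""
  traj_path <- file.path(dir, paste0(pre, "trajectory.csv"))
  agents_path <- file.path(dir, paste0(pre, "agents.csv"))
  manifest_path <- file.path(dir, paste0(pre, "manifest.json"))
  for (p in c(traj_path, agents_path, manifest_path))
    if (!file.exists(p)) stop("missing results file: ", p, call. = FALSE)
  list(trajectory = utils::read.csv(traj_path),
       agents = utils::read.csv(agents_path),
       manifest = jsonlite::read_json(manifest_path, simplifyVector = TRUE))
}
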