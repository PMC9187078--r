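# End-to-end pipeline driver: ingest -> patches -> classify -> severity ->
# map -> tables, with a serialisable config and reproducible seeds. The
# thin command-line wrapper in inst/cli/ccemap.R exposes these stages as
# shell subcommands.

#' Pipeline configuration
#'
#' Resolves a configuration for [run_pipeline()] from a YAML file and/or an
#' override list. A run writes its resolved config next to its outputs, so
#' any run is reproducible from (inputs, config, seeds).
#'
#' @param config Path to a YAML file, a list, or `NULL` for defaults.
#' @param ... Named overrides (override file values; flags win).
#' @return List of class `pipeline_config`. Fields: `mode` ("synthetic" or
#'   "files"), `manifest` (for files mode), `script`/`n_per_segment`/`fracs`
#'   (synthetic mode), `classifier` ("oracle"), `mask` ("none", "estimate" or
#'   a mask file path), `exclusion` (rule overrides), `n_stills`, `seed`,
#'   `out_dir`, `figure` (logical), `figure_format`.
#' @export
pipeline_config <- function(config = NULL, ...) {
  defaults <- list(mode = "synthetic", manifest = NULL, n_per_segment = 5L,
                   fracs = c(1, 0, 0, 0), classifier = "oracle",
                   mask = "none", exclusion = list(), n_stills = 50L,
                   seed = 1L, out_dir = "ccemap-out", figure = TRUE,
                   figure_format = "png")
  from_file <- if (is.character(config)) yaml::read_yaml(config)
               else if (is.list(config)) config else list()
  overrides <- list(...)
  cfg <- utils::modifyList(utils::modifyList(defaults, from_file), overrides)
  if (!cfg$mode %in% c("synthetic", "files")) {
    stop("mode must be 'synthetic' or 'files'", call. = FALSE)
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full severity-mapping pipeline
#'
#' Loads or generates the study's stills, extracts and classifies patches,
#' computes per-still severity profiles, assembles and renders the
#' topographic map, and writes all stage outputs (patch inventory,
#' profiles, percent-severity table, map JSON, figure, resolved config) to
#' the output directory. Per-stage counts — stills, eligible patches,
#' inadequate share — are logged via `message()`.
#'
#' @param config A [pipeline_config()], YAML path, or list.
#' @return The `topographic_map`, invisibly; outputs on disk in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  rule <- do.call(exclusion_rule, config$exclusion)

  if (config$mode == "synthetic") {
    script <- if (!is.null(config$script)) {
      if (is.character(config$script)) utils::read.csv(config$script)
      else config$script
    } else {
      make_profile_script(config$n_per_segment, config$fracs)
    }
    if (nrow(script) == 0L) stop("empty profile script", call. = FALSE)
    study <- generate_study(script, seed = config$seed)
    stills <- study$stills
  } else {
    manifest <- read_manifest(config$manifest)
    stills <- list()
    for (i in seq_len(nrow(manifest))) {
      entry <- manifest[i, ]
      files <- Sys.glob(entry$source)
      if (length(files) == 0L) {
        stop("manifest source matches no files: ", entry$source,
             call. = FALSE)
      }
      n <- min(config$n_stills, length(files))
      stills <- c(stills, extract_stills(sort(files), n_stills = n,
                                         study_id = "study",
                                         camera = as.character(entry$camera),
                                         segment = as.character(entry$segment)))
    }
  }
  message("stills: ", length(stills))

  model <- switch(config$classifier,
                  oracle = make_oracle_classifier(),
                  stop("no model available for classifier '",
                       config$classifier, "'; train one with ",
                       "train_classifier() or use classifier = 'oracle'",
                       call. = FALSE))
  mask <- if (identical(config$mask, "none")) NULL
          else if (identical(config$mask, "estimate")) "estimate"
          else read_mask(config$mask)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  inventories <- lapply(stills, function(s) {
    m <- if (identical(mask, "estimate")) estimate_fov_mask(s) else mask
    cbind(still_id = still_id(s), patch_inventory(s, m, rule))
  })
  inventory <- do.call(rbind, inventories)
  utils::write.csv(inventory, file.path(config$out_dir, "patch_inventory.csv"),
                   row.names = FALSE)
  eligible <- sum(inventory$inside_mask & !inventory$excluded)
  message("patch windows: ", nrow(inventory), "; eligible: ", eligible)

  map <- map_study(stills, model = model, mask = mask, rule = rule)
  utils::write.csv(as.data.frame(map),
                   file.path(config$out_dir, "profiles.csv"),
                   row.names = FALSE)
  export_table(map, file.path(config$out_dir, "severity_table.csv"))
  write_map_json(map, file.path(config$out_dir, "map.json"))
  if (isTRUE(config$figure)) {
    render_map(map, file.path(config$out_dir,
                              paste0("map.", config$figure_format)))
  }
  message("stills excluded (zero severity area): ", sum(map$excluded))
  resolved <- unclass(config)
  resolved$script <- NULL  # tabular; stored with the study when synthetic
  jsonlite::write_json(resolved,
                       file.path(config$out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(map)
}
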