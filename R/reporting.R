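config_keys <- function() {
  setdiff(names(formals(scenario_config)), "...")
}

merge_config <- function(defaults, overrides, where = "config") {
  merged <- modifyList(as.list(defaults), as.list(overrides))
  unknown <- setdiff(names(merged), config_keys())
  if (length(unknown) > 0) {
    abort(paste0("config error in ", where, ": unknown key(s) ",
                 paste(unknown, collapse = ", ")),
          class = "coansel_config_error")
  }
  do.call(scenario_config, merged)
}

#' Load scenario configurations from a file
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON configuration. Recognized keys are
#' the arguments of [scenario_config()]; unknown keys raise a config error
#' naming the key. Three layouts are accepted: an empty file (the single
#' default scenario), a flat mapping of overrides (one scenario), a
#' `scenarios:` list of per-scenario overrides (with any remaining
#' top-level keys as shared defaults), or `grid: true` to expand the
#' study's nine-scenario grid around the defaults.
#'
#' @param path Path to the configuration file.
#' @return A list of [scenario_config()] objects.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    # keep bare N / Y keys as strings (YAML 1.1 would read them as booleans)
    keep <- function(x, truth) {
      if (x %in% c("true", "True", "TRUE", "yes", "on")) return(TRUE)
      if (x %in% c("false", "False", "FALSE", "no", "off")) return(FALSE)
      x
    }
    yaml::read_yaml(path, handlers = list("bool#yes" = keep,
                                          "bool#no" = keep))
  } else {
    unwrap <- function(x) {
      lapply(x, function(v) if (is.list(v)) unlist(v) else v)
    }
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (!is.null(raw$scenarios)) raw$scenarios <- lapply(raw$scenarios,
                                                         unwrap)
    unwrap(raw[setdiff(names(raw), "scenarios")]) |>
      c(raw["scenarios"][!vapply(raw["scenarios"], is.null, TRUE)])
  }
  if (is.null(raw) || length(raw) == 0) {
    return(list(scenario_config()))
  }
  shared <- raw[setdiff(names(raw), c("scenarios", "grid"))]
  if (isTRUE(raw$grid)) {
    return(do.call(table_grid, shared))
  }
  if (!is.null(raw$scenarios)) {
    return(purrr::imap(raw$scenarios, function(ov, i) {
      merge_config(shared, as.list(ov), paste0("scenario ", i))
    }))
  }
  list(merge_config(list(), shared, "top level"))
}

#' Relationship matrices of one cohort
#'
#' Builds all four relationship matrices over the individuals of one
#' generation, defaulting to the last recorded generation (right before
#' selection would start).
#'
#' @param pop Accumulated `population`.
#' @param pedigree Pedigree tibble covering `pop`.
#' @param generation Cohort generation (default: the latest).
#' @param panel Optional [marker_panel()].
#' @param min_run ROH threshold in markers.
#' @return Named list of the four `relationship_matrix` objects.
#' @export
cohort_relationships <- function(pop, pedigree, generation = NULL,
                                 panel = NULL, min_run = 100) {
  generation <- generation %||% max(pop$generation)
  idx <- which(pop$generation == generation)
  sub <- subset_population(pop, idx)
  list(A = subset_relationship(pedigree_A(pedigree), idx),
       G = ibs_G(sub, panel),
       R = roh_R(sub, panel, min_run),
       V = vanraden_V(sub, panel))
}

#' Histograms of pairwise coancestries per matrix kind
#'
#' Bins the off-diagonal coancestries of each matrix and annotates each
#' kind with the variance of its distribution, mirroring the pre-selection
#' coancestry histograms of the study (where the genealogical coancestry is
#' multimodal with the largest variance).
#'
#' @param matrices A list of `relationship_matrix` objects (e.g. from
#'   [cohort_relationships()]).
#' @param bins Number of histogram bins.
#' @return A list of class `coancestry_histograms` with `histogram`
#'   (kind, bin_mid, bin_width, count) and `variances` (kind, n_pairs,
#'   mean_f, var_f) tibbles.
#' @export
coancestry_histograms <- function(matrices, bins = 30) {
  summaries <- purrr::map(matrices, coancestry_summary, bins = bins)
  structure(
    list(
      histogram = purrr::map(summaries, "histogram") |> dplyr::bind_rows(),
      variances = purrr::map(summaries, function(s) {
        dplyr::mutate(s$summary,
                      n_pairs = .data$n * (.data$n - 1) / 2,
                      .keep = "unused")[, c("kind", "n_pairs", "mean_f",
                                            "var_f")]
      }) |> dplyr::bind_rows()
    ),
    class = "coancestry_histograms"
  )
}

#' @export
print.coancestry_histograms <- function(x, ...) {
  print(x$variances)
  invisible(x)
}

#' Run manifest
#'
#' Snapshot of everything needed to reproduce a run bit-for-bit: the
#' configurations, the base seed and the derived per-replicate seeds, the
#' package version and a timestamp.
#'
#' @param configs A [scenario_config()] or list of them.
#' @param n_replicates Replicates per scenario.
#' @param seed Base seed used.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(configs, n_replicates = NULL, seed = NULL) {
  if (inherits(configs, "scenario_config")) configs <- list(configs)
  structure(
    list(
      package = "coansel",
      version = as.character(packageVersion("coansel")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed,
      scenarios = purrr::imap(configs, function(cfg, s) {
        cfg <- unclass(cfg)
        R <- n_replicates %||% cfg$n_replicates
        base_seed <- if (is.null(seed)) cfg$seed else
          as.integer(seed + 10000 * (s - 1))
        c(cfg, list(replicate_seeds = base_seed + seq_len(R)))
      })
    ),
    class = "run_manifest"
  )
}

#' Write a run manifest as JSON
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
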