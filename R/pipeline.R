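#' Category percentages per sample for a set of spectra
#'
#' Convenience chain annotate -> relative abundances -> categories for a
#' list of spectra sharing a library; the workhorse behind the group
#' tables.
#'
#' @param spectra list of `glycan_spectrum`s.
#' @param library a `glycan_library`.
#' @param tolerance,snr_min,policy passed through.
#' @return matrix with rows = samples, columns = categories (for O-glycan
#'   spectra, the `overall` categories).
#' @export
spectra_category_matrix <- function(spectra, library, tolerance = 0.5,
                                    snr_min = 6,
                                    policy = "representative") {
  rows <- lapply(spectra, function(sp) {
    prof <- relative_abundances(annotate(sp, library, tolerance, snr_min))
    ca <- category_abundances(prof, library, policy = policy)
    if (inherits(ca, "o_category_profile")) ca$overall else ca
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(spectra)
  mat
}

## stable content hash for the run log: two independent polynomial hashes
## over the serialized config text, modulo primes small enough for exact
## double arithmetic (avoids a digest dependency)
.config_hash <- function(x) {
  txt <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                          force = TRUE)
  bytes <- utf8ToInt(as.character(txt))
  p1 <- 67108859; p2 <- 67108837
  h1 <- 17; h2 <- 257
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% p1
    h2 <- (h2 * 37 + b) %% p2
  }
  sprintf("%07x%07x", h1, h2)
}

#' Default pipeline configuration
#'
#' All knobs of the synthetic-cohort pipeline in one serialisable list:
#' annotation parameters, policies, Endo H settings, the cohort design and
#' the seed. Can be written to / read from YAML.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param design cohort design data.frame (see [simulate_cohort()]).
#' @param tolerance,snr_min annotation parameters.
#' @param policy isomer category-splitting policy.
#' @param endoh_reference,endoh_thresholds Endo H inference settings.
#' @param run_endoh simulate and analyse a differential-digestion triplet.
#' @param effects per-group category effects.
#' @param top_k how many masses in the ranking table.
#' @param noise overrides for [sim_config()] fields.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            design = data.frame(
                              group = c("cortex", "cerebellum"),
                              template = c("cortexN", "cerebellumN"),
                              region = c("cortex", "cerebellum"),
                              n = c(6, 6)),
                            tolerance = 0.5, snr_min = 6,
                            policy = "representative",
                            endoh_reference = "FA1B",
                            endoh_thresholds = c(low = 0.1, high = 0.9),
                            run_endoh = TRUE,
                            effects = list(), top_k = 10,
                            noise = list()) {
  structure(list(out_dir = out_dir, seed = seed, design = design,
                 tolerance = tolerance, snr_min = snr_min, policy = policy,
                 endoh_reference = endoh_reference,
                 endoh_thresholds = endoh_thresholds,
                 run_endoh = run_endoh, effects = effects, top_k = top_k,
                 noise = noise),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any subset of the [pipeline_config()] fields.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$design)) y$design <- as.data.frame(y$design)
  if (!is.null(y$endoh_thresholds))
    y$endoh_thresholds <- unlist(y$endoh_thresholds)
  do.call(pipeline_config, y)
}

#' Run the full synthetic-cohort pipeline
#'
#' simulate -> annotate -> profile -> categorise -> compare: writes
#' per-sample profiles, the per-group mean/SEM tables, the category summary
#' with ANOVA, the percent-change-from-mean matrix, the top-k ranking and
#' (optionally) the Endo H call table into `config$out_dir`, together with
#' a run log that records the fully materialised configuration and its
#' hash. Reruns with identical config are bit-reproducible.
#'
#' @param config a [pipeline_config()].
#' @return list with the in-memory results (`profiles`, `group_profiles`,
#'   `category_summary`, `percent_change`, `top`, `endoh`, `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (nrow(config$design) == 0) stop("run_pipeline(): empty design")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  noise_cfg <- do.call(sim_config, config$noise)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("run_pipeline(): stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }
  cohort <- step("simulate",
                 simulate_cohort(config$design, config$effects, noise_cfg,
                                 seed = config$seed))
  library <- attr(cohort$truth[[1]], "library")
  profiles <- step("annotate", lapply(cohort$spectra, function(sp)
    relative_abundances(annotate(sp, library, config$tolerance,
                                 config$snr_min))))
  groups <- split(cohort$samples$sample_id, cohort$samples$group)
  groups <- groups[unique(cohort$samples$group)]
  group_profiles <- lapply(groups, function(ids)
    aggregate_profiles(profiles[ids]))
  cat_values <- lapply(groups, function(ids) {
    m <- do.call(rbind, lapply(profiles[ids], function(p) {
      ca <- category_abundances(p, library, policy = config$policy)
      if (inherits(ca, "o_category_profile")) ca$overall else ca
    }))
    rownames(m) <- ids
    m
  })
  cat_summary <- step("stats", summary_table(cat_values))
  cat_matrix <- vapply(cat_values, colMeans,
                       numeric(ncol(cat_values[[1]])))
  pct <- if (length(groups) >= 2) percent_change_matrix(cat_matrix) else NULL
  top <- step("rank", top_k(group_profiles, config$top_k))

  endoh_res <- NULL
  if (isTRUE(config$run_endoh)) {
    endoh_res <- step("endoh", {
      truth <- cohort$truth[[1]]
      trip <- simulate_endoh_triplet(truth, noise_cfg,
                                     seed = config$seed + 1)
      infer_sensitivity(trip$pre, trip$endoh, trip$post, library,
                        reference = config$endoh_reference,
                        thresholds = config$endoh_thresholds,
                        tolerance = config$tolerance,
                        snr_min = config$snr_min)
    })
  }

  ## ---- outputs -------------------------------------------------------
  files <- character()
  wr <- function(obj, name) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(obj, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }
  prof_tab <- do.call(rbind, lapply(names(profiles), function(id)
    cbind(sample_id = id, as.data.frame(profiles[[id]]))))
  wr(prof_tab, "profiles.csv")
  grp_tab <- do.call(rbind, lapply(names(group_profiles), function(g)
    cbind(group = g, as.data.frame(group_profiles[[g]]))))
  wr(grp_tab, "group_profiles.csv")
  wr(as.data.frame(cat_summary), "category_summary.csv")
  if (!is.null(pct))
    wr(data.frame(category = rownames(pct), round(pct, 4),
                  check.names = FALSE), "percent_change.csv")
  wr(top, "top_masses.csv")
  if (!is.null(endoh_res)) wr(as.data.frame(endoh_res), "endoh_calls.csv")

  log <- list(config = unclass(config), config_hash = .config_hash(config),
              n_spectra = length(cohort$spectra),
              package_version = as.character(utils::packageVersion("glycobrain")))
  log_path <- file.path(config$out_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, log_path)

  list(profiles = profiles, group_profiles = group_profiles,
       category_summary = cat_summary, category_matrix = cat_matrix,
       percent_change = pct, top = top, endoh = endoh_res, files = files)
}
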