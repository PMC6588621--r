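#' Pipeline run configuration
#'
#' Bundles every knob of the three analyses so a run is fully reproducible
#' from (config, seed): sample sizes default to the study design (64 prawns
#' per type and 64-image pools for the field survey; 25 individuals per type
#' and 26-image pools for the colour change experiment; 90 trials per type
#' for the choice experiment).
#'
#' @param seed Master integer seed; every stage derives its own sub-stream.
#' @param n_prawns,n_backgrounds Field survey sample sizes.
#' @param n_individuals,pool_size Colour-change sample sizes.
#' @param schedule A [colour_change_schedule()].
#' @param n_trials_per_type,p_choice_made,p_match_given_choice Choice-trial
#'   generator settings.
#' @param route `"direct"` (cone catches by spectral integration) or
#'   `"camera"` (camera band catches pushed through a fitted polynomial
#'   mapping, as in the imaging workflow).
#' @param mapping_degree Polynomial degree for the camera route.
#' @param systems Visual systems to model.
#' @return A `run_config` list.
#' @export
run_config <- function(seed, n_prawns = 64L, n_backgrounds = 64L,
                       n_individuals = 25L, pool_size = 26L,
                       schedule = colour_change_schedule(),
                       n_trials_per_type = 90L, p_choice_made = 79 / 180,
                       p_match_given_choice = 0.8,
                       route = c("direct", "camera"), mapping_degree = 2L,
                       systems = list(pollack(), goby())) {
  structure(list(seed = seed, n_prawns = n_prawns,
                 n_backgrounds = n_backgrounds,
                 n_individuals = n_individuals, pool_size = pool_size,
                 schedule = schedule, n_trials_per_type = n_trials_per_type,
                 p_choice_made = p_choice_made,
                 p_match_given_choice = p_match_given_choice,
                 route = match.arg(route), mapping_degree = mapping_degree,
                 systems = systems),
            class = "run_config")
}

.provenance <- function(config) {
  list(package = "prawnvision",
       version = as.character(utils::packageVersion("prawnvision")),
       seed = config$seed, config_hash = rlang::hash(unclass(config)))
}

# convert spectra to cone catch records for one system, by direct
# integration or through a fitted camera mapping
.records_from_spectra <- function(spectra, system, route = "direct",
                                  mapping = NULL, illuminant = NULL, ...) {
  if (is.null(illuminant)) illuminant <- d65(system$grid)
  meta <- list(...)
  lapply(spectra, function(s) {
    rec <- if (route == "direct") {
      cone_catch(s, illuminant, system, subject_id = s$name)
    } else {
      cam <- camera_catch(s, attr(mapping, "camera"), illuminant)
      apply_mapping(mapping, cam, subject_id = s$name)
    }
    for (f in names(meta)) rec[[f]] <- meta[[f]]
    rec
  })
}

.camera_mapping <- function(config, system) {
  camera <- camera_default(system$grid)
  lib <- sample_spectra_library(200L, sub_seed(config$seed, 90L), system$grid)
  m <- fit_mapping(camera, system, lib, d65(system$grid),
                   degree = config$mapping_degree)
  attr(m, "camera") <- camera
  m
}

#' Field camouflage analysis
#'
#' Generates (or accepts) the field survey, computes cone catches for every
#' prawn and seaweed image under each visual system, randomly pairs each
#' prawn with a background from each seaweed pool, and summarises the JNDs
#' of the four comparison groups (prawn type x seaweed) per system.
#'
#' @param config A [run_config()].
#' @param survey Optional pre-built survey (as from
#'   [simulate_field_survey()]); generated from the config when `NULL`.
#' @return List with `jnds` (tidy per-pairing table), `summary` (mean, SE, n
#'   per colour_type x substrate x system) and `provenance`.
#' @export
run_field_camouflage <- function(config, survey = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(survey)) {
    survey <- simulate_field_survey(config$n_prawns, config$n_backgrounds,
                                    sub_seed(config$seed, 1L))
  }
  if (length(survey$green_prawns) == 0L || length(survey$red_prawns) == 0L) {
    stop("field stage: empty subject set")
  }
  all_jnds <- list()
  for (system in config$systems) {
    mapping <- if (config$route == "camera") {
      .camera_mapping(config, system)
    } else NULL
    recs <- list(
      green = .records_from_spectra(survey$green_prawns, system,
                                    config$route, mapping,
                                    colour_type = "green"),
      red = .records_from_spectra(survey$red_prawns, system, config$route,
                                  mapping, colour_type = "red"),
      sea_lettuce = .records_from_spectra(survey$sea_lettuce, system,
                                          config$route, mapping,
                                          substrate = "sea_lettuce"),
      dulse = .records_from_spectra(survey$dulse, system, config$route,
                                    mapping, substrate = "dulse"))
    k <- 10L
    for (type in c("green", "red")) {
      for (sub in c("sea_lettuce", "dulse")) {
        k <- k + 1L
        all_jnds[[paste(system$name, type, sub)]] <-
          jnd_table(recs[[type]], recs[[sub]], system, "random",
                    seed = sub_seed(config$seed, k))
      }
    }
  }
  jnds <- dplyr::bind_rows(all_jnds)
  list(jnds = jnds,
       summary = group_summary(jnds, "delta_s", "system", "colour_type",
                               "substrate"),
       provenance = .provenance(config))
}

#' Colour-change analysis
#'
#' Runs the 30-day colour-change experiment for both colour types (green
#' prawns moved onto dulse, red prawns onto sea lettuce), computes per-day
#' hue values and prawn-vs-new-substrate JNDs for each visual system
#' (survivors only, random per-day pairing with the substrate image pool),
#' and returns tidy trajectories plus group summaries.
#'
#' @param config A [run_config()].
#' @return List with `hue` and `jnds` (tidy per-observation tables),
#'   `hue_summary` and `jnd_summary` (mean, SE, n per system x colour_type x
#'   day), `truth` (generator ground truth) and `provenance`.
#' @export
run_colour_change <- function(config) {
  stopifnot(inherits(config, "run_config"))
  runs <- list(
    green = simulate_colour_change(prawn_model("green"),
                                   seaweed_model("dulse"), config$schedule,
                                   config$n_individuals,
                                   sub_seed(config$seed, 21L),
                                   colour_type = "green"),
    red = simulate_colour_change(prawn_model("red"),
                                 seaweed_model("sea_lettuce"),
                                 config$schedule, config$n_individuals,
                                 sub_seed(config$seed, 22L),
                                 colour_type = "red"))
  pools <- with_seed(sub_seed(config$seed, 23L), list(
    green = lapply(seq_len(config$pool_size), function(i) {
      s <- .sample_reflectance(seaweed_model("dulse"), default_grid())
      s$name <- sprintf("du_pool_%02d", i)
      s
    }),
    red = lapply(seq_len(config$pool_size), function(i) {
      s <- .sample_reflectance(seaweed_model("sea_lettuce"), default_grid())
      s$name <- sprintf("sl_pool_%02d", i)
      s
    })))
  pool_substrate <- c(green = "dulse", red = "sea_lettuce")
  hue_rows <- list()
  jnd_rows <- list()
  for (system in config$systems) {
    for (type in c("green", "red")) {
      run <- runs[[type]]
      truth <- run$truth
      bg <- .records_from_spectra(pools[[type]], system,
                                  substrate = pool_substrate[[type]])
      for (d in config$schedule$days) {
        alive_ids <- truth$subject_id[truth$day == d & truth$alive]
        if (length(alive_ids) == 0L) stop("no survivors on day ", d)
        specs <- lapply(alive_ids, function(id) run$spectra[[id]][[as.character(d)]])
        sizes <- truth$size_mm[match(alive_ids, truth$subject_id)]
        recs <- lapply(seq_along(specs), function(i) {
          cone_catch(specs[[i]], d65(system$grid), system,
                     subject_id = alive_ids[i], colour_type = type,
                     day = as.integer(d), size_mm = sizes[i])
        })
        hue_rows[[paste(system$name, type, d)]] <- hue_table(recs, system)
        jnd_rows[[paste(system$name, type, d)]] <-
          jnd_table(recs, bg, system, "random",
                    seed = sub_seed(config$seed, 100L + d + ifelse(type == "green", 0L, 1000L) +
                                      ifelse(system$name == "pollack", 0L, 5000L)))
      }
    }
  }
  hue <- dplyr::bind_rows(hue_rows)
  jnds <- dplyr::bind_rows(jnd_rows)
  list(hue = hue, jnds = jnds,
       hue_summary = group_summary(hue, "hue", "system", "colour_type",
                                   "day"),
       jnd_summary = group_summary(jnds, "delta_s", "system", "colour_type",
                                   "day"),
       truth = dplyr::bind_rows(lapply(runs, `[[`, "truth")),
       provenance = .provenance(config))
}

#' Behavioural choice analysis
#'
#' Simulates (or accepts) the Y-maze trial table and reports per-type
#' matched-choice proportions with exact binomial tests plus the overall
#' decision rate.
#'
#' @param config A [run_config()].
#' @param trials Optional trial table (columns `colour_type`, `outcome`);
#'   simulated from the config when `NULL`.
#' @return List with `per_type` summary tibble, `tests`, `n_trials`,
#'   `n_decided`, `choice_rate`, `provenance`.
#' @export
run_choice_analysis <- function(config, trials = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(trials)) {
    trials <- simulate_choice_trials(config$n_trials_per_type,
                                     config$p_choice_made,
                                     config$p_match_given_choice,
                                     sub_seed(config$seed, 31L))
  }
  res <- summarise_choices(trials)
  res$provenance <- .provenance(config)
  res
}

#' Recompute field JND group means from a per-individual table
#'
#' Reads a CSV of per-individual JND values (one row per prawn-background
#' comparison) and recomputes the group mean and standard error per
#' colour type x substrate x visual system -- the summary statistics quoted
#' for the field camouflage comparison. Intended for re-analysis of a
#' published per-individual data table.
#'
#' @param path CSV path.
#' @param value Name of the JND column (default `"jnd"`).
#' @param keys Grouping columns (default
#'   `c("system", "colour_type", "substrate")`).
#' @return Tibble with the grouping columns plus `mean`, `se`, `n`.
#' @export
field_jnd_group_means <- function(path, value = "jnd",
                                  keys = c("system", "colour_type",
                                           "substrate")) {
  if (!file.exists(path)) {
    stop("per-individual JND table not found: ", path)
  }
  df <- utils::read.csv(path)
  missing <- setdiff(c(value, keys), names(df))
  if (length(missing)) {
    stop("table lacks column(s): ", paste(missing, collapse = ", "))
  }
  do.call(group_summary, c(list(df, value), as.list(keys)))
}
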