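#' Run a multi-stage analysis pipeline from a config
#'
#' Executes a sequence of simulation, fitting and comparison stages
#' described by a single configuration document (YAML or JSON file, or an
#' equivalent R list), writing every intermediate artifact (CSV data,
#' JSON results) plus a manifest to an output directory. Identical config
#' and seed produce byte-identical result files.
#'
#' The config has fields `seed` (integer; mandatory when any stochastic
#' simulation stage is present), optional `output_dir`, and `stages`: a
#' list of stage entries, each with a `stage` type, an optional `id`
#' (default `<stage><index>`), stage parameters, and input references —
#' either `input` (a file path) or `from` (the `id` of an earlier stage,
#' making the stage graph an explicit simulate -> fit -> compare DAG).
#'
#' Stage types: `simulate_quench`, `simulate_tempseries`,
#' `simulate_unfold`, `simulate_scatter`, `fit_sv`, `classify`,
#' `fit_binding`, `vant_hoff`, `residence`, `fit_unfolding`, `compare`,
#' `mre`.
#'
#' @param config Path to a YAML/JSON config file, or a list.
#' @param output_dir Output directory; overrides the config's. Created if
#'   missing.
#' @return The manifest, invisibly: stages run, files written with their
#'   MD5 hashes, seed and package version. Also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop_specbind(sprintf("no such config file: '%s'", config),
                    "specbind_config_error")
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config) || is.null(config$stages))
    stop_specbind("config must contain a 'stages' list",
                  "specbind_config_error")
  out_dir <- output_dir %||% config$output_dir %||%
    stop_specbind("no output_dir given in config or argument",
                  "specbind_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stages <- config$stages
  types <- vapply(stages, function(s) s$stage %||% "", character(1L))
  noisy <- vapply(stages, function(s) {
    startsWith(s$stage %||% "", "simulate") &&
      ((s$noise_cv %||% 0) > 0 || identical(s$stage, "simulate_scatter"))
  }, logical(1L))
  if (any(noisy) && is.null(config$seed))
    stop_specbind("config must set a seed when stochastic simulate stages are present",
                  "specbind_config_error")
  seed <- as.integer(config$seed %||% 1L)

  registry <- new.env(parent = emptyenv())
  fetch <- function(id, want = NULL) {
    if (!exists(id, envir = registry, inherits = FALSE))
      stop_specbind(sprintf("stage input '%s' not produced by an earlier stage",
                            id), "specbind_dependency_error")
    obj <- get(id, envir = registry)
    if (!is.null(want) && !inherits(obj, want))
      stop_specbind(sprintf("stage input '%s' is not a %s", id, want),
                    "specbind_dependency_error")
    obj
  }
  manifest_stages <- list()

  for (i in seq_along(stages)) {
    st <- stages[[i]]
    type <- st$stage %||% stop_specbind("stage entry without a 'stage' type",
                                        "specbind_config_error")
    id <- st$id %||% sprintf("%s%d", type, i)
    stage_seed <- seed + i
    files <- character()
    save_csv <- function(obj, suffix, writer) {
      path <- file.path(out_dir, sprintf("%s%s.csv", id, suffix))
      writer(obj, path)
      files <<- c(files, path)
      path
    }
    save_json <- function(obj) {
      path <- file.path(out_dir, paste0(id, ".json"))
      write_result(obj, path)
      files <<- c(files, path)
      path
    }
    grid_of <- function(st, default_max = 20e-6, default_step = 1e-6) {
      if (!is.null(st$conc_grid)) as.numeric(st$conc_grid)
      else seq(0, st$conc_max %||% default_max, by = st$conc_step %||% default_step)
    }

    obj <- switch(
      type,
      simulate_quench = {
        tr <- quench_truth(st$Ka, st$n_sites %||% 1, st$F0 %||% 1000,
                           st$noise_cv %||% 0, st$seed %||% stage_seed)
        s <- generate_quench(tr, grid_of(st),
                             temperature_K = st$temperature_K %||% 298,
                             protein_conc_M = st$protein_conc_M %||% 5e-6,
                             label = id)
        save_csv(s, "", write_titration)
        s
      },
      simulate_tempseries = {
        base <- quench_truth(1, st$n_sites %||% 1, st$F0 %||% 1000,
                             st$noise_cv %||% 0, st$seed %||% stage_seed)
        ss <- generate_temperature_series(st$dH, st$dS,
                                          as.numeric(st$temps_K), base,
                                          grid_of(st),
                                          st$protein_conc_M %||% 5e-6)
        for (k in seq_along(ss))
          save_csv(ss[[k]], sprintf("_%gK", ss[[k]]$temperature_K),
                   write_titration)
        structure(ss, class = "titration_series_list")
      },
      simulate_unfold = {
        tr <- unfold_truth(
          dG1_J_per_mol = st$dG1 %||% 17190,
          m1_J_per_mol_per_M = st$m1 %||% 3500,
          dG2_J_per_mol = st$dG2 %||% 15230,
          m2_J_per_mol_per_M = st$m2 %||% 2500,
          noise_cv = st$noise_cv %||% 0, seed = st$seed %||% stage_seed)
        p <- generate_unfolding(
          tr, seq(0, st$denat_max %||% 9, by = st$denat_step %||% 0.25),
          temperature_K = st$temperature_K %||% 298,
          signal_model = st$signal_model %||% "stepwise")
        save_csv(p, "", write_unfolding)
        p
      },
      simulate_scatter = {
        s <- generate_scattering(
          conc_grid = if (is.null(st$conc_grid))
            seq(0, st$conc_max %||% 60e-6, by = st$conc_step %||% 2.5e-6)
          else as.numeric(st$conc_grid),
          cmc_like_threshold_M = st$threshold_M,
          seed = st$seed %||% stage_seed)
        save_csv(s, "", write_titration)
        s
      },
      fit_sv = {
        s <- if (!is.null(st$input)) read_titration(st$input)
             else if (!is.null(st$index))
               fetch(st$from, "titration_series_list")[[st$index]]
             else fetch(st$from, "titration_series")
        ft <- fit_stern_volmer(s, st$tau0_s %||% 5e-9)
        save_json(ft)
        ft
      },
      classify = {
        fits <- lapply(as.character(st$from), fetch, want = "quench_fit")
        cl <- classify_mechanism(fits, st$collisional_limit %||% 1e10)
        save_json(cl)
        cl
      },
      fit_binding = {
        s <- if (!is.null(st$input)) read_titration(st$input)
             else if (!is.null(st$index))
               fetch(st$from, "titration_series_list")[[st$index]]
             else fetch(st$from, "titration_series")
        ft <- fit_double_log(s)
        save_json(ft)
        ft
      },
      vant_hoff = {
        pts <- if (!is.null(st$points)) {
          do.call(rbind, lapply(st$points, function(p)
            data.frame(temperature_K = p[[1L]], Ka_assoc_per_M = p[[2L]])))
        } else {
          fits <- lapply(as.character(st$from), fetch, want = "binding_fit")
          data.frame(
            temperature_K = vapply(fits, `[[`, numeric(1L), "temperature_K"),
            Ka_assoc_per_M = vapply(fits, `[[`, numeric(1L), "Ka_assoc_per_M"))
        }
        th <- fit_vant_hoff(pts)
        save_json(th)
        th
      },
      residence = {
        ka <- if (!is.null(st$from)) fetch(st$from, "binding_fit")$Ka_assoc_per_M
              else st$Ka
        kf <- st$kf %||% "auto"
        kin <- if (identical(kf, "auto"))
          residence_time(ka, D_m2_per_s = st$D %||% 1e-9, r_m = st$r %||% 4e-10)
        else residence_time(ka, kf_per_M_per_s = as.numeric(kf))
        save_json(kin)
        kin
      },
      fit_unfolding = {
        p <- if (!is.null(st$input)) read_unfolding(st$input)
             else fetch(st$from, "unfolding_profile")
        regions <- if (is.null(st$regions))
          list(N = c(0, 2.25), I = c(4.75, 5.25), U = c(8, Inf))
        else lapply(st$regions, as.numeric)
        an <- fit_unfolding(p, regions = regions,
                            method = st$method %||% "both")
        save_json(an)
        an
      },
      compare = {
        side <- function(ref, meth) {
          an <- fetch(ref, "unfolding_analysis")
          fits <- an$fits[[meth]]
          if (is.null(fits))
            stop_specbind(sprintf("analysis '%s' has no %s fits", ref, meth),
                          "specbind_dependency_error")
          list(fits$N_to_I, fits$I_to_U)
        }
        meth <- st$method %||% "nonlinear"
        key <- if (meth == "linear") "linear" else "nonlinear"
        cmp <- compare_stability(side(st$apo, key), side(st$complex, key))
        save_json(cmp)
        cmp
      },
      mre = {
        sp <- if (!is.null(st$input)) read_spectrum(st$input, "cd_millideg")
              else fetch(st$from, "specbind_spectrum")
        out <- to_mre(sp, mre_params(st$n_residues %||% 583L,
                                     path_cm = st$path_cm,
                                     protein_conc_M = st$protein_conc_M))
        save_csv(out, "_mre", write_spectrum)
        out
      },
      stop_specbind(sprintf("unknown stage type '%s'", type),
                    "specbind_config_error")
    )
    assign(id, obj, envir = registry)
    manifest_stages[[length(manifest_stages) + 1L]] <- list(
      id = id, stage = type,
      params = st[setdiff(names(st), c("stage", "id"))],
      outputs = basename(files),
      md5 = unname(tools::md5sum(files))
    )
  }

  manifest <- structure(
    list(seed = seed,
         package = "specbind",
         package_version = as.character(utils::packageVersion("specbind")),
         output_dir = out_dir,
         stages = manifest_stages),
    class = "pipeline_manifest")
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
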