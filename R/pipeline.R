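#' Default pipeline configuration
#'
#' Returns the fully resolved default configuration of [run_pipeline()].
#' Stage parameter defaults are the production thresholds of the analysis
#' chain (2/3 coverage, p < 1e-6, MAF > 0.05, mu = 2.3e-9 per site per
#' year, 2-year generations, 1000-year ROC intervals, smoothing span
#' 0.05, TSS gate 0.8, 70/30 evaluation split repeated twice); simulation
#' sizes are desk-scale so the full demo completes in minutes.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "afs", "fit", "climate", "sdm"),
    simulate = list(
      model = "two_pop_sizechange_split_mig",
      params = list(nu_anc = 1, t_anc = 0.2, nu1 = 1, nu2 = 1,
                    t_split = 0.1, m12 = 1, m21 = 1),
      sample_sizes = c(12L, 12L),
      n_sites = 20000L,
      theta_per_site = 0.05,
      mean_depth = 15,
      error_rate = 0.01
    ),
    afs = list(
      min_ind_frac = 2 / 3,
      p_max = 1e-6,
      maf_min = 0.05,
      folded = FALSE,
      mode = "posterior",
      mask_bed = NULL
    ),
    fit = list(
      model = "two_pop_sizechange_split_mig",
      n_starts = 6L,
      maxit = 300L,
      extra = 2L,
      fixed = NULL,
      mu_site_year = 2.3e-9,
      generation_years = 2,
      L_unfiltered = 1e7
    ),
    climate = list(
      duration = 120000,
      step = 200,
      baseline = -2,
      events = list(
        list(onset_bp = 105000, amplitude = 16, ramp_years = 1000),
        list(onset_bp = 70000, amplitude = -12, ramp_years = 1000),
        list(onset_bp = 15000, amplitude = 10, ramp_years = 2000)
      ),
      ar1_coeff = 0.5,
      noise_sd = 0.3,
      interval = 1000,
      span = 0.05,
      roc_mode = "absolute",
      quantile_threshold = 0.90,
      merge_gap = 1L,
      n_permutations = 999L
    ),
    sdm = list(
      grid_shape = c(40L, 60L),
      n_vars = 4L,
      spatial_corr_length = 3,
      niche_coeffs = c(-16, 8, -6, 6, -4),
      n_presence = 200L,
      n_background = 1000L,
      thin_cell_km = 50,
      learners = c("logistic_quadratic", "range_envelope"),
      gate = 0.8,
      split = 0.70,
      repeats = 2L,
      n_slices = 8L,
      crash_slices = c(5L, 6L),
      # per-variable shift (sd units) applied in the crash slices; the
      # default pushes each variable against its niche-coefficient sign
      crash_shift = c(-4, 4, -4, 4),
      slice_step_years = 15000,
      drop_frac = 0.5
    )
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config entry '", path, "' must be a list")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste(paste0(path, unknown), collapse = ", "))
  }
  for (nm in names(user)) {
    sub <- paste0(path, nm, ".")
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        nm != "params" && nm != "events") {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], sub)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Read a pipeline configuration file (YAML or JSON)
#' @param path file ending in .yaml/.yml or .json.
#' @return nested list (not yet merged with defaults).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json")
  }
}

stage_seed <- function(global_seed, stage) {
  idx <- match(stage, c("simulate", "afs", "fit", "climate", "sdm"))
  as.integer((as.numeric(global_seed) * 7919 + idx * 104729) %% 2147483647)
}

config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order
#' (simulate -> afs -> fit; climate and sdm are independent branches),
#' writing each stage's outputs into `out_dir/<stage>/` along with a
#' `manifest.json` echoing the fully resolved configuration. Stages are
#' cached: a stage whose configuration hash (including its upstream
#' hashes) matches the previous run is skipped. All randomness derives
#' from the global seed through a fixed per-stage hash, so a repeated run
#' with the same configuration and seed is byte-identical.
#'
#' @param config nested list overriding [default_config()] entries;
#'   unknown keys are rejected before any computation.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages?
#' @return invisibly, a list with the resolved config and per-stage
#'   results.
#' @export
run_pipeline <- function(config = list(), out_dir = "glacialsplit_run",
                         quiet = FALSE) {
  cfg <- merge_config(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(line, "\n", file = log_path, append = TRUE)
    if (!quiet) message(line)
  }
  results <- list()
  upstream_hash <- ""

  run_stage <- function(stage, deps_hash, fun) {
    sdir <- file.path(out_dir, stage)
    key <- config_hash(list(cfg = cfg[[stage]], seed = cfg$seed,
                            deps = deps_hash))
    key_file <- file.path(sdir, ".cache_key")
    if (dir.exists(sdir) && file.exists(key_file) &&
        identical(readLines(key_file, warn = FALSE)[1], key)) {
      logf("stage ", stage, ": cached, skipping")
      return(list(hash = key, dir = sdir, cached = TRUE))
    }
    unlink(sdir, recursive = TRUE)
    dir.create(sdir, recursive = TRUE)
    t0 <- Sys.time()
    out <- fun(sdir, stage_seed(cfg$seed, stage))
    writeLines(key, key_file)
    logf("stage ", stage, ": done in ",
         format(difftime(Sys.time(), t0), digits = 3))
    c(out, list(hash = key, dir = sdir, cached = FALSE))
  }

  stages <- cfg$stages
  bad <- setdiff(stages, c("simulate", "afs", "fit", "climate", "sdm"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))

  if ("simulate" %in% stages) {
    results$simulate <- run_stage("simulate", "", function(sdir, seed) {
      sc <- cfg$simulate
      model <- demographic_model(sc$model, unlist(sc$params))
      sim <- simulate_coalescent(model, sc$sample_sizes, sc$n_sites,
                                 sc$theta_per_site, seed = seed,
                                 return_genotypes = TRUE)
      gl <- simulate_genotype_likelihoods(sim$genotypes, sim$sites,
                                          sim$pop,
                                          mean_depth = sc$mean_depth,
                                          error_rate = sc$error_rate,
                                          seed = seed + 1L)
      write_beagle(gl, file.path(sdir, "sim.beagle"))
      write_fs(sim$sfs, file.path(sdir, "true_sfs.fs"))
      writeLines(paste(sim$pop, collapse = "\n"),
                 file.path(sdir, "pops.txt"))
      jsonlite::write_json(
        list(params = as.list(model$params), n_seg = sim$n_seg,
             sample_sizes = sc$sample_sizes),
        file.path(sdir, "truth.json"), auto_unbox = TRUE, digits = NA)
      list(n_seg = sim$n_seg)
    })
  }

  if ("afs" %in% stages) {
    sim_dir <- file.path(out_dir, "simulate")
    if (!file.exists(file.path(sim_dir, "sim.beagle"))) {
      stop("afs stage needs the simulate stage outputs (or run it first)")
    }
    results$afs <- run_stage("afs", results$simulate$hash %||% "",
                             function(sdir, seed) {
      ac <- cfg$afs
      pop <- readLines(file.path(sim_dir, "pops.txt"))
      gl <- read_beagle(file.path(sim_dir, "sim.beagle"), pop)
      if (!is.null(ac$mask_bed)) {
        keep <- apply_region_mask(gl$sites, read_bed(ac$mask_bed))
        gl <- gl[keep]
      }
      est <- estimate_site_frequencies(gl)
      write.table(est, file.path(sdir, "site_estimates.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      fl <- apply_site_filters(est, length(gl$ids), ac$min_ind_frac,
                               ac$p_max, ac$maf_min)
      jsonlite::write_json(
        list(n_input = nrow(est), n_retained = nrow(fl$retained),
             attrition = as.list(fl$attrition)),
        file.path(sdir, "attrition.json"), auto_unbox = TRUE, digits = NA)
      fs <- build_joint_sfs(gl[fl$keep], folded = ac$folded,
                            mode = ac$mode)
      # the MAF filter makes low-frequency cells unobservable; mask them
      # so the demographic fit stays consistent with the ascertainment
      if (ac$maf_min > 0) fs <- mask_low_maf(fs, ac$maf_min)
      write_fs(fs, file.path(sdir, "obs.fs"))
      list(n_retained = nrow(fl$retained), n_input = nrow(est))
    })
  }

  if ("fit" %in% stages) {
    afs_dir <- file.path(out_dir, "afs")
    if (!file.exists(file.path(afs_dir, "obs.fs"))) {
      stop("fit stage needs the afs stage outputs")
    }
    results$fit <- run_stage("fit", results$afs$hash %||% "",
                             function(sdir, seed) {
      fc <- cfg$fit
      obs <- read_fs(file.path(afs_dir, "obs.fs"))
      fit <- fit_model(obs, fc$model, n_starts = fc$n_starts, seed = seed,
                       fixed = unlist(fc$fixed), extra = fc$extra,
                       maxit = fc$maxit)
      att <- jsonlite::read_json(file.path(afs_dir, "attrition.json"),
                                 simplifyVector = TRUE)
      L <- estimate_L(fc$L_unfiltered, att$n_retained, att$n_input)
      units <- unit_system(fc$mu_site_year, fc$generation_years, L)
      st <- summarize_split_times(fit, units)
      cu <- convert_units(fit$best$theta_hat, fit$best$params, units)
      write.table(fit$runs, file.path(sdir, "runs.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        list(model = fc$model, n_converged = fit$n_converged,
             best = list(loglik = fit$best$loglik,
                         theta_hat = fit$best$theta_hat,
                         params = as.list(fit$best$params),
                         N_ref = cu$N_ref,
                         real_units = as.list(cu$real)),
             split_time_kya = as.list(st), L_effective = L),
        file.path(sdir, "fit.json"), auto_unbox = TRUE, digits = NA)
      list(split_kya = st, fit = fit)
    })
  }

  if ("climate" %in% stages) {
    results$climate <- run_stage("climate", results$fit$hash %||% "",
                                 function(sdir, seed) {
      cc <- cfg$climate
      series <- simulate_climate(cc$duration, cc$step, cc$baseline,
                                 cc$events, cc$ar1_coeff, cc$noise_sd,
                                 seed = seed)
      write_climate_csv(series, file.path(sdir, "climate.csv"))
      res <- resample_series(series, cc$interval)
      roc <- rate_of_change(res, mode = cc$roc_mode)
      utils::write.csv(roc, file.path(sdir, "roc.csv"), row.names = FALSE)
      sm <- smooth_series(series, cc$span)
      write_climate_csv(sm, file.path(sdir, "climate_smoothed.csv"))
      ep <- detect_episodes(roc, cc$quantile_threshold, cc$merge_gap)
      write.table(as.data.frame(ep), file.path(sdir, "episodes.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      overlap <- NULL
      fit_json <- file.path(out_dir, "fit", "fit.json")
      if (file.exists(fit_json)) {
        fj <- jsonlite::read_json(fit_json, simplifyVector = TRUE)
        iv <- as.numeric(c(fj$split_time_kya$q25_kya,
                           fj$split_time_kya$q75_kya)) * 1000
        if (length(iv) == 2L && all(is.finite(iv)) && iv[1] < iv[2] &&
            min(iv) >= min(attr(ep, "span")) &&
            max(iv) <= max(attr(ep, "span"))) {
          overlap <- interval_episode_overlap(iv, ep,
                                              n_permutations =
                                                cc$n_permutations,
                                              seed = seed + 1L)
          jsonlite::write_json(overlap, file.path(sdir, "overlap.json"),
                               auto_unbox = TRUE, digits = NA)
        }
      }
      list(n_episodes = nrow(ep), overlap = overlap)
    })
  }

  if ("sdm" %in% stages) {
    results$sdm <- run_stage("sdm", "", function(sdir, seed) {
      sc <- cfg$sdm
      L <- simulate_landscape(sc$grid_shape, sc$n_vars,
                              sc$spatial_corr_length, sc$niche_coeffs,
                              sc$n_presence, sc$n_background, seed = seed)
      pres <- thin_occurrences(L$presences, sc$thin_cell_km,
                               seed = seed + 1L)
      bg <- L$background
      members <- list()
      for (k in seq_along(sc$learners)) {
        kind <- sc$learners[k]
        cv <- cross_evaluate(kind, pres, bg, L$stack, sc$split,
                             sc$repeats, seed = seed + 1L + k)
        full <- fit_learner(kind, pres, bg, L$stack)
        members[[k]] <- list(model = full, tss = cv$mean_tss,
                             threshold = cv$mean_threshold, kind = kind)
      }
      ens <- build_ensemble(members, sc$gate)
      ref <- extract_env(L$stack, pres)
      stacks <- lapply(seq_len(sc$n_slices), function(s) {
        st <- L$stack
        st$time_bp <- s * sc$slice_step_years
        if (s %in% sc$crash_slices) {
          shift <- rep_len(sc$crash_shift, length(st$vars))
          st$vars <- stats::setNames(lapply(seq_along(st$vars), function(j) {
            st$vars[[j]] + shift[j]
          }), names(st$vars))
        }
        st
      })
      pr <- project_time_slices(ens, stacks, reference = ref)
      col <- detect_range_collapse(pr$area, sc$drop_frac)
      utils::write.csv(pres, file.path(sdir, "occurrences_thinned.csv"),
                       row.names = FALSE)
      utils::write.csv(bg, file.path(sdir, "background.csv"),
                       row.names = FALSE)
      write.table(pr$area, file.path(sdir, "area_series.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      write.table(col, file.path(sdir, "collapse.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        list(members = lapply(members, function(m) {
               list(kind = m$kind, tss = m$tss, threshold = m$threshold)
             }),
             gate = sc$gate, n_passing = length(ens$members),
             ensemble_threshold = ens$threshold),
        file.path(sdir, "ensemble.json"), auto_unbox = TRUE, digits = NA)
      list(area = pr$area, collapse = col, ensemble = ens)
    })
  }

  manifest <- list(
    package = "glacialsplit",
    version = as.character(utils::packageVersion("glacialsplit")),
    config = cfg,
    stage_hashes = lapply(results, `[[`, "hash")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(config = cfg, results = results))
}
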