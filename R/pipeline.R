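#' Read a pipeline run configuration
#'
#' A single YAML file drives the whole pipeline: the session design, the
#' treatment profiles (inline or a path to a profile file), feature
#' parameters, the interval-reduction window, and the classifier-harness
#' settings. Missing sections fall back to package defaults; validation
#' failures abort before any computation.
#'
#' @param path Path to a YAML config.
#' @return A validated config list (class `electromer_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config '%s' not found.", path), class = "electromer_io_error")
  }
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config A raw config list.
#' @export
validate_run_config <- function(config) {
  stopifnot(is.list(config))
  dn <- config$design %||% list()
  experiments <- if (!is.null(dn$experiments)) {
    purrr::map_dfr(dn$experiments, as_tibble)
  } else {
    tibble(
      experiment = c("water", "nutrient", "peg", "nacl"),
      n_plants = c(30L, 21L, 54L, 39L),
      n_sessions = c(10L, 7L, 18L, 13L)
    )
  }
  design <- session_design(
    experiments,
    samples_per_series = dn$samples_per_series %||% 450000L,
    rate = dn$rate %||% 62.5
  )
  profiles <- if (is.character(config$profiles)) {
    read_profiles(config$profiles)
  } else if (is.list(config$profiles)) {
    setNames(
      lapply(names(config$profiles), function(nm) {
        profile_from_list(nm, config$profiles[[nm]])
      }),
      names(config$profiles)
    )
  } else {
    default_profiles()
  }
  missing_prof <- setdiff(design$experiments$experiment, names(profiles))
  if (length(missing_prof) > 0L) {
    abort(sprintf("no profile for experiment(s): %s.", toString(missing_prof)),
      class = "electromer_config_error"
    )
  }
  harness <- config$harness %||% list()
  harness$classifiers <- harness$classifiers %||% c("knn", "dt", "rf", "bayes")
  harness$fractions <- harness$fractions %||% seq(0.1, 0.9, by = 0.1)
  harness$repetitions <- harness$repetitions %||% 20L
  harness$confusion_classifier <- harness$confusion_classifier %||% "knn"
  harness$confusion_fraction <- harness$confusion_fraction %||% 0.7
  if (harness$repetitions < 1L) {
    abort("harness repetitions must be >= 1.", class = "electromer_config_error")
  }
  if (!all(harness$classifiers %in% classifier_roster())) {
    abort("unknown classifier in harness config.",
      class = "electromer_config_error"
    )
  }
  features <- config$features %||% list()
  features$m <- features$m %||% 2L
  features$r_factor <- features$r_factor %||% 0.2
  features$max_scale <- features$max_scale %||% 50L
  features$max_points <- features$max_points %||% 10000L
  reduction <- config$reduction %||% list()
  reduction$window_size <- reduction$window_size %||% 30000L
  reduction$center <- reduction$center %||% "mean"
  out <- list(
    design = design, profiles = profiles, features = features,
    reduction = reduction, harness = harness,
    seed = config$seed %||% 1L
  )
  class(out) <- "electromer_config"
  out
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  message(sprintf("[%s] stage '%s' ...", format(t0, "%H:%M:%S"), name))
  res <- tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      class = "electromer_pipeline_error"
    )
  })
  message(sprintf(
    "[%s] stage '%s' done (%.1f s)", format(Sys.time(), "%H:%M:%S"),
    name, as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ))
  res
}

write_stamped_csv <- function(x, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s seed: %d", hash, seed), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Run the full electrome pipeline
#'
#' Orchestrates simulate -> characterize -> reduce -> classify -> compare
#' from one configuration: synthesizes every electrome series of the
#' design, computes the per-series feature ledger, reduces each series to
#' interval triplets, runs before/after learning curves and a pooled
#' confusion matrix per experiment (plus a multi-class run on the
#' post-stimulus series of all experiments), and builds the paired
#' before/after comparison table. All randomness derives from `seed`;
#' re-running an identical config reproduces every number.
#'
#' @param config An `electromer_config` (see [read_run_config()]) or a raw
#'   config list.
#' @param seed Master seed; overrides the config's seed when given.
#' @param out_dir Optional directory: when set, the manifest, ledger,
#'   learning curves, confusion matrices and comparison tables are written
#'   as CSV files stamped with the config hash and seed.
#' @return A list (class `electromer_run`) with elements `manifest`,
#'   `ledger`, `curves`, `confusions`, `comparisons`, `config_hash`,
#'   `seed`, `timings`.
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  if (!inherits(config, "electromer_config")) {
    config <- validate_run_config(config)
  }
  seed <- as.integer(seed %||% config$seed)
  hash <- rlang::hash(list(config, seed))
  t_start <- Sys.time()

  manifest <- stage("manifest", generate_manifest(config$design))
  el_rows <- which(!manifest$is_reference)

  series <- stage(
    "simulate",
    realize_series(manifest,
      rows = el_rows, profiles = config$profiles,
      seed = seed
    )
  )

  ledger <- stage("features", {
    led <- purrr::map2_dfr(series, el_rows, function(s, i) {
      row <- feature_ledger(s,
        m = config$features$m,
        r_factor = config$features$r_factor,
        max_scale = config$features$max_scale,
        max_points = config$features$max_points,
        include_fft = FALSE
      )
      row$series_id <- manifest$series_id[i]
      row
    })
    dplyr::relocate(led, "series_id")
  })

  features <- stage("reduce", {
    labels <- paste(
      manifest$experiment[el_rows],
      manifest$phase[el_rows],
      sep = "_"
    )
    ds <- reduce_dataset(series, labels,
      window_size = config$reduction$window_size,
      center = config$reduction$center
    )
    ds$experiment <- manifest$experiment[el_rows]
    ds$phase <- manifest$phase[el_rows]
    ds
  })

  harness <- config$harness
  curves <- list()
  confusions <- list()
  stage("classify", {
    for (ex in unique(features$experiment)) {
      sub <- features[features$experiment == ex, ]
      dat <- dplyr::select(sub, -"label", -"experiment")
      dat <- dplyr::rename(dat, label = "phase")
      curves[[ex]] <- run_learning_curve(
        dat,
        classifiers = harness$classifiers,
        fractions = harness$fractions,
        repetitions = harness$repetitions,
        seed = derive_seed(seed, "curve", ex)
      )
      confusions[[ex]] <- evaluate_confusion(
        dat,
        classifier = harness$confusion_classifier,
        fraction = harness$confusion_fraction,
        repetitions = harness$repetitions,
        seed = derive_seed(seed, "confusion", ex)
      )
    }
    if (length(unique(features$experiment)) >= 2L) {
      post <- features[features$phase == "after", ]
      dat <- dplyr::select(post, -"label", -"phase")
      dat <- dplyr::rename(dat, label = "experiment")
      confusions[["all_after"]] <- evaluate_confusion(
        dat,
        classifier = harness$confusion_classifier,
        fraction = harness$confusion_fraction,
        repetitions = harness$repetitions,
        seed = derive_seed(seed, "confusion", "all_after")
      )
    }
    NULL
  })

  comparisons <- stage("compare", {
    purrr::map_dfr(unique(ledger$experiment), function(ex) {
      tb <- phase_comparison_table(ledger[ledger$experiment == ex, ])
      tb$experiment <- ex
      dplyr::relocate(tb, "experiment")
    })
  })

  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_stamped_csv(
        as_tibble(manifest), file.path(out_dir, "manifest.csv"), hash, seed
      )
      scalar_ledger <- dplyr::select(ledger, -dplyr::any_of(c("fft", "msapen")))
      write_stamped_csv(
        scalar_ledger, file.path(out_dir, "ledger.csv"), hash, seed
      )
      write_stamped_csv(
        purrr::imap_dfr(curves, ~ dplyr::mutate(as_tibble(.x), experiment = .y)),
        file.path(out_dir, "learning_curves.csv"), hash, seed
      )
      write_stamped_csv(
        purrr::imap_dfr(
          confusions,
          ~ dplyr::mutate(as_tibble(.x), dataset = .y)
        ),
        file.path(out_dir, "confusions.csv"), hash, seed
      )
      write_stamped_csv(
        comparisons, file.path(out_dir, "comparisons.csv"), hash, seed
      )
      NULL
    })
  }

  structure(
    list(
      manifest = manifest, ledger = ledger, curves = curves,
      confusions = confusions, comparisons = comparisons,
      config_hash = hash, seed = seed,
      timings = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
    ),
    class = "electromer_run"
  )
}

#' @export
print.electromer_run <- function(x, ...) {
  cat(sprintf(
    "<electromer_run> %d series, %d experiment(s), seed %d, hash %s\n",
    sum(!x$manifest$is_reference),
    length(unique(x$manifest$experiment)), x$seed, x$config_hash
  ))
  cat(sprintf("  elapsed: %.1f s\n", x$timings))
  invisible(x)
}
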