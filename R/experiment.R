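#' Experiment configuration
#'
#' Bundles the configuration of a full pipeline run: synthetic corpus
#' generation, emotional-phase segmentation, difficulty-homogenised
#' splitting, a grid of models (task x head x feature kind), and
#' evaluation. The grid is expanded to one [model_config()] per
#' combination; each model is seeded from the experiment seed.
#'
#' @param synthetic A [synthetic_config()]; defaults to the package
#'   default corpus.
#' @param segmentation List of segmentation parameters: `threshold_frac`,
#'   `min_gap_s`, `pad_after_s`.
#' @param split List with `tail` (`"strict"` or `"balanced"`).
#' @param grid List with `tasks`, `heads`, `features` character vectors;
#'   expanded to the full cross product.
#' @param training List of overrides passed to every [model_config()]
#'   (e.g. `max_epochs`, `patience`).
#' @param include_svm Also fit the SVM baseline on video-level appearance
#'   features (default `TRUE`).
#' @param evaluation List with `B` bootstrap replicates.
#' @param seed Integer master seed; recorded in the emitted report.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(synthetic = synthetic_config(),
                              segmentation = list(threshold_frac = 0.1,
                                                  min_gap_s = 0.3,
                                                  pad_after_s = 1.0),
                              split = list(tail = "strict"),
                              grid = list(tasks = c("binary", "multiclass"),
                                          heads = c("average", "attention", "convolution"),
                                          features = "appearance"),
                              training = list(),
                              include_svm = TRUE,
                              evaluation = list(B = 1000),
                              seed = 1L) {
  if (length(grid$tasks) == 0 || length(grid$heads) == 0 || length(grid$features) == 0) {
    stop("model grid must name at least one task, one head and one feature kind")
  }
  needs_deep <- any(grid$features %in% c("deep", "concatenated"))
  if (needs_deep && !synthetic$include_deep) {
    stop("grid requests deep features but the synthetic config has include_deep = FALSE")
  }
  structure(
    list(synthetic = synthetic, segmentation = segmentation, split = split,
         grid = grid, training = training, include_svm = include_svm,
         evaluation = evaluation, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file; top-level keys mirror the arguments of
#'   [experiment_config()] (with `synthetic` passed to
#'   [synthetic_config()]).
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  syn_args <- raw$synthetic %||% list()
  if (!is.null(syn_args$per_emotion_counts)) {
    syn_args$per_emotion_counts <- unlist(syn_args$per_emotion_counts)
  }
  args <- raw[setdiff(names(raw), "synthetic")]
  args$synthetic <- do.call(synthetic_config, syn_args)
  do.call(experiment_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full experiment
#'
#' End-to-end pipeline: generate the synthetic corpus, detect and trim the
#' emotional phase of every video, score subject difficulty by
#' leave-one-subject-out SVMs, assign subjects to splits round-robin, train
#' every model in the grid, and evaluate each on the validation and test
#' splits. Artifacts (the configuration, the split assignment, per-model
#' reports and a summary table with feature kinds in rows and heads in
#' columns) are written to `out_dir` when given.
#'
#' @param cfg An [experiment_config()].
#' @param out_dir Optional output directory.
#' @param verbose Log per-stage progress lines (default `TRUE`).
#' @return A list of class `experiment_report`: `assignment`, `scores`,
#'   `models` (per-model fits and evaluation reports), `summary` (one row
#'   per task x feature x head with validation and test metrics), `seed`.
#' @export
run_experiment <- function(cfg, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                                 stage, sprintf(...)))
  }
  say("simulate", "generating corpus (seed %d)", cfg$synthetic$seed)
  corpus <- generate_corpus(cfg$synthetic)
  say("simulate", "%d videos, %d subjects", length(corpus),
      length(unique(corpus_subjects(corpus))))

  say("segment", "trimming to the emotional phase")
  seg <- cfg$segmentation
  segmented <- lapply(corpus, function(rec) {
    out <- tryCatch(
      segment_record(rec, seg$threshold_frac, seg$min_gap_s, seg$pad_after_s),
      error = function(e) stop("segmentation failed for subject ", rec$subject_id,
                               " (", rec$label, "): ", conditionMessage(e)))
    out$deep <- if (!is.null(rec$deep)) {
      w <- out$phase_in_source
      feature_sequence(rec$deep$values[(w[1] + 1):w[2], , drop = FALSE],
                       kind = "deep", fps = rec$deep$fps)
    }
    out
  })

  say("split", "scoring subject difficulty (LOSO SVM)")
  scores <- loso_difficulty_scores(segmented, segment = FALSE)
  assignment <- assign_splits(scores, tail = cfg$split$tail)
  parts <- partition_corpus(segmented, assignment)
  sizes <- split_sizes(assignment)
  say("split", "subjects train/val/test = %d/%d/%d", sizes[1], sizes[2], sizes[3])
  # leakage check before any fit
  for (pair in list(c("train", "validation"), c("train", "test"),
                    c("validation", "test"))) {
    ov <- intersect(unique(corpus_subjects(parts[[pair[1]]])),
                    unique(corpus_subjects(parts[[pair[2]]])))
    if (length(ov) > 0) {
      stop("subject leakage between ", pair[1], " and ", pair[2], ": ",
           paste(ov, collapse = ", "))
    }
  }

  B <- cfg$evaluation$B %||% 1000
  models <- list()
  summary_rows <- list()
  eval_on <- function(model, records, task) {
    truth <- .task_targets(task, corpus_labels(records))
    pred <- predict(model, records)
    evaluation_report(truth, pred, class_names = .task_classes(task),
                      B = B, seed = cfg$seed)
  }

  if (cfg$include_svm) {
    say("train", "SVM baseline")
    for (task in unique(cfg$grid$tasks)) {
      Xtr <- t(vapply(c(parts$train, parts$validation),
                      function(r) video_level_features(r$features), numeric(35)))
      ytr <- .task_targets(task, corpus_labels(c(parts$train, parts$validation)))
      svm_fit <- fit_svm_baseline(Xtr, ytr)
      for (split_name in c("validation", "test")) {
        recs <- parts[[split_name]]
        Xev <- t(vapply(recs, function(r) video_level_features(r$features), numeric(35)))
        truth <- .task_targets(task, corpus_labels(recs))
        pred <- predict(svm_fit, Xev)
        rep <- evaluation_report(truth, pred, class_names = .task_classes(task),
                                 B = B, seed = cfg$seed)
        summary_rows[[length(summary_rows) + 1]] <- data.frame(
          task = task, features = "appearance", head = "svm",
          split = split_name, uar = rep$uar, accuracy = rep$accuracy)
      }
      models[[paste("svm", task, sep = "_")]] <- list(model = svm_fit, task = task)
    }
  }

  model_id <- 0
  for (task in cfg$grid$tasks) {
    for (feat in cfg$grid$features) {
      for (head in cfg$grid$heads) {
        model_id <- model_id + 1
        mcfg_args <- c(list(task = task, head = head, feature_kind = feat,
                            seed = cfg$seed + model_id), cfg$training)
        mcfg <- do.call(model_config, mcfg_args)
        say("train", "GRU %s / %s / %s", task, head, feat)
        fit <- train_model(parts$train, parts$validation, mcfg)
        rep_val <- eval_on(fit, parts$validation, task)
        rep_test <- eval_on(fit, parts$test, task)
        key <- paste(task, feat, head, sep = "_")
        models[[key]] <- list(model = fit, validation = rep_val, test = rep_test)
        summary_rows[[length(summary_rows) + 1]] <- data.frame(
          task = task, features = feat, head = head, split = "validation",
          uar = rep_val$uar, accuracy = rep_val$accuracy)
        summary_rows[[length(summary_rows) + 1]] <- data.frame(
          task = task, features = feat, head = head, split = "test",
          uar = rep_test$uar, accuracy = rep_test$accuracy)
        say("evaluate", "%s: val UAR %.3f, test UAR %.3f", key,
            rep_val$uar, rep_test$uar)
      }
    }
  }
  summary <- do.call(rbind, summary_rows)
  report <- structure(
    list(assignment = assignment, scores = scores, models = models,
         summary = summary, seed = cfg$seed, config = cfg),
    class = "experiment_report"
  )
  if (!is.null(out_dir)) .write_experiment(report, out_dir)
  report
}

#' Summary table in the style of a results matrix
#'
#' Pivots the experiment summary for one task and split into a table with
#' feature kinds in rows and heads in columns, UAR values in percent
#' rounded half-up to one decimal.
#'
#' @param report An `experiment_report`.
#' @param task,split Which slice to tabulate.
#' @return A data.frame.
#' @export
summary_table <- function(report, task = "multiclass", split = "test") {
  s <- report$summary
  s <- s[s$task == task & s$split == split, ]
  heads <- unique(s$head)
  feats <- unique(s$features)
  out <- data.frame(features = feats)
  for (h in heads) {
    out[[h]] <- vapply(feats, function(f) {
      v <- s$uar[s$features == f & s$head == h]
      if (length(v) == 0) NA_real_ else round_half_up(100 * v, 1)
    }, numeric(1))
  }
  out
}

.write_experiment <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  yaml::write_yaml(.config_to_list(cfg), file.path(out_dir, "config.yaml"))
  write_split(report$assignment, file.path(out_dir, "split.csv"))
  utils::write.csv(data.frame(subject_id = names(report$scores),
                              uar = unname(report$scores)),
                   file.path(out_dir, "difficulty_scores.csv"), row.names = FALSE)
  utils::write.csv(report$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  reports <- lapply(report$models, function(m) {
    if (is.null(m$test)) return(NULL)
    list(validation = .report_to_list(m$validation),
         test = .report_to_list(m$test))
  })
  jsonlite::write_json(list(seed = report$seed, reports = reports),
                       file.path(out_dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

.report_to_list <- function(rep) {
  list(n = rep$n, accuracy = rep$accuracy, uar = rep$uar,
       ci_low = rep$ci_low, ci_high = rep$ci_high,
       cohen_kappa = rep$cohen_kappa, kappa_label = rep$kappa_label,
       p_above_chance = rep$p_above_chance,
       per_class_recall = as.list(rep$per_class_recall),
       per_class_balanced_accuracy = as.list(rep$per_class_balanced_accuracy))
}

.config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$synthetic <- unclass(out$synthetic)
  out$synthetic$per_emotion_counts <- as.list(out$synthetic$per_emotion_counts)
  out
}
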