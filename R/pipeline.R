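#' Experiment configuration
#'
#' Describes one end-to-end experiment: the data source (synthetic panel or a
#' dataset directory), the mask source, the plant-level split protocol, the
#' model variants to run, and nested module configurations. The split unit is
#' always the plant: frames of one plant never appear on both sides of a
#' split.
#'
#' @param panel accession panel for synthetic data (ignored when `data_dir`
#'   is given).
#' @param n_plants_per_class,n_days,canvas_size synthetic dataset shape.
#' @param models subset of `"svm"`, `"handcrafted-lstm"`, `"cnn"`,
#'   `"cnn-crf"`, `"cnn-lstm"`.
#' @param mask_source `"truth"` (generator ground truth) or `"segment"`
#'   (run [segment_plant()] on every frame).
#' @param train_fraction fraction of plants per class used for training
#'   (single split); set `k_folds` instead for cross-validation.
#' @param k_folds optional fold count (>= 2) for stratified-by-plant CV.
#' @param seed master seed; all stage seeds derive from it.
#' @param cnn,lstm,crf,svm named lists of overrides for the module
#'   configurations ([cnn_config()], [lstm_config()], [crf_baseline()],
#'   [svm_baseline()]).
#' @param n_bins area sub-classes per genotype for CNN training.
#' @param min_area frames whose mask has fewer foreground pixels are treated
#'   as plant-absent: excluded from CNN training and from the frame vote.
#' @param data_dir optional directory written by [generate_dataset()].
#' @param out_dir optional run directory for report/confusion/log artifacts.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(panel = default_accession_panel(),
                              n_plants_per_class = 20, n_days = 22,
                              canvas_size = 128,
                              models = c("svm", "handcrafted-lstm", "cnn",
                                         "cnn-crf", "cnn-lstm"),
                              mask_source = c("truth", "segment"),
                              train_fraction = 0.75, k_folds = NULL, seed = 1,
                              cnn = list(), lstm = list(), crf = list(),
                              svm = list(), n_bins = 5L, min_area = 16L,
                              data_dir = NULL, out_dir = NULL) {
  valid <- c("svm", "handcrafted-lstm", "cnn", "cnn-crf", "cnn-lstm")
  bad <- setdiff(models, valid)
  if (length(bad))
    stop("invalid model(s) ", paste(bad, collapse = ", "),
         "; valid choices: ", paste(valid, collapse = ", "), call. = FALSE)
  mask_source <- match.arg(mask_source)
  if (!is.null(k_folds) && k_folds < 2) stop("k_folds must be >= 2", call. = FALSE)
  structure(list(panel = panel, n_plants_per_class = n_plants_per_class,
                 n_days = n_days, canvas_size = canvas_size, models = models,
                 mask_source = mask_source, train_fraction = train_fraction,
                 k_folds = k_folds, seed = as.integer(seed), cnn = cnn,
                 lstm = lstm, crf = crf, svm = svm, n_bins = as.integer(n_bins),
                 min_area = as.integer(min_area),
                 data_dir = data_dir, out_dir = out_dir),
            class = "experiment_config")
}

#' Stratified plant-level splits
#'
#' Assigns plants to folds (or a train/test split) stratified by genotype,
#' deterministically for a given seed. The split unit is the plant.
#'
#' @param manifest tibble with at least `plant_id` and `genotype_index`
#'   (per-frame manifests are collapsed to plants).
#' @param k_folds fold count; each class must have at least `k_folds` plants.
#' @param train_fraction alternative to `k_folds`: fraction of each class's
#'   plants assigned to training.
#' @param seed RNG seed.
#' @return tibble `plant_id`, `genotype_index`, and `fold` (1-based) or
#'   `split` (`"train"`/`"test"`).
#' @export
make_splits <- function(manifest, k_folds = NULL, train_fraction = NULL, seed = 1) {
  plants <- dplyr::distinct(manifest[, c("plant_id", "genotype_index")])
  counts <- table(plants$genotype_index)
  if (any(counts < 2)) stop("need >= 2 plants per class", call. = FALSE)
  if (is.null(k_folds) == is.null(train_fraction))
    stop("give exactly one of k_folds or train_fraction", call. = FALSE)
  out <- with_local_seed(seed, {
    parts <- lapply(split(plants, plants$genotype_index), function(pl) {
      pl <- pl[sample.int(nrow(pl)), ]
      if (!is.null(k_folds)) {
        if (nrow(pl) < k_folds)
          stop("class ", pl$genotype_index[1], " has fewer plants than folds",
               call. = FALSE)
        pl$fold <- rep_len(seq_len(k_folds), nrow(pl))
      } else {
        n_tr <- max(1L, min(nrow(pl) - 1L, round(train_fraction * nrow(pl))))
        pl$split <- c(rep("train", n_tr), rep("test", nrow(pl) - n_tr))
      }
      pl
    })
    dplyr::bind_rows(parts)
  })
  dplyr::arrange(out, .data$plant_id)
}

# assert the plant-level leakage guard
check_no_leakage <- function(train_ids, test_ids) {
  overlap <- intersect(unique(train_ids), unique(test_ids))
  if (length(overlap))
    stop("plants on both sides of a split: ", paste(overlap, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

# deep-feature sequences (list of T x D matrices, day order) for given plants
deep_sequences <- function(model, sequences) {
  lapply(sequences, function(sq) extract_deep_features(model, sq$frames))
}

hc_sequences <- function(feat_tbl, plant_ids) {
  meta <- c("plant_id", "genotype", "day")
  lapply(plant_ids, function(pid) {
    rows <- feat_tbl[feat_tbl$plant_id == pid, ]
    rows <- rows[order(rows$day), ]
    as.matrix(rows[, setdiff(names(feat_tbl), meta)])
  })
}

run_one_split <- function(cfg, seqs, feat_tbl, masks, train_ids, test_ids, class_names) {
  check_no_leakage(train_ids, test_ids)
  ids <- vapply(seqs, function(s) s$plant_id, character(1))
  labs <- vapply(seqs, function(s) s$genotype, integer(1))
  names(labs) <- ids
  L <- length(class_names)
  tr <- match(train_ids, ids); te <- match(test_ids, ids)
  truth <- labs[te]
  preds <- list(); evals <- list(); timings <- c()

  need_cnn <- any(cfg$models %in% c("cnn", "cnn-crf", "cnn-lstm"))
  need_hc <- any(cfg$models %in% c("svm", "handcrafted-lstm"))

  if (need_hc) {
    tr_tbl <- feat_tbl[feat_tbl$plant_id %in% train_ids, ]
    te_tbl <- feat_tbl[feat_tbl$plant_id %in% test_ids, ]
  }

  if ("svm" %in% cfg$models) {
    t0 <- Sys.time()
    svm_args <- utils::modifyList(list(features = tr_tbl, n_classes = L), cfg$svm)
    m <- do.call(svm_baseline, svm_args)
    pr <- predict(m, te_tbl)
    pr <- pr[match(test_ids, pr$plant_id), ]
    preds$svm <- pr$pred
    evals$svm <- evaluate(pr$pred, truth, class_names)
    timings["svm"] <- as.numeric(Sys.time() - t0, units = "secs")
  }

  if ("handcrafted-lstm" %in% cfg$models) {
    t0 <- Sys.time()
    lcfg <- do.call(lstm_config, utils::modifyList(
      list(n_classes = L, seed = cfg$seed + 12L), cfg$lstm))
    m <- train_lstm(hc_sequences(feat_tbl, train_ids), labs[tr], lcfg)
    sc <- predict(m, hc_sequences(feat_tbl, test_ids))
    preds$`handcrafted-lstm` <- max.col(sc, ties.method = "first") - 1L
    evals$`handcrafted-lstm` <- evaluate(preds$`handcrafted-lstm`, truth, class_names)
    timings["handcrafted-lstm"] <- as.numeric(Sys.time() - t0, units = "secs")
  }

  cnn_model <- NULL
  if (need_cnn) {
    t0 <- Sys.time()
    # frames without a plant (area below the absent-plant threshold) carry no
    # genotype information and are excluded from per-frame training
    areas_tr <- unlist(lapply(masks[tr], function(ms) vapply(ms, sum, numeric(1))))
    gts_tr <- unlist(lapply(seqs[tr], function(s) rep(s$genotype, length(s$frames))))
    frames_tr <- unlist(lapply(seqs[tr], function(s) s$frames), recursive = FALSE)
    present <- areas_tr >= cfg$min_area
    sub <- assign_area_subclasses(areas_tr[present], gts_tr[present],
                                  n_bins = cfg$n_bins)
    ccfg <- do.call(cnn_config, utils::modifyList(
      list(n_outputs = L * cfg$n_bins, seed = cfg$seed + 11L), cfg$cnn))
    cnn_model <- train_cnn(frames_tr[present], sub$flat_label, ccfg)
    timings["cnn_train"] <- as.numeric(Sys.time() - t0, units = "secs")
  }

  if ("cnn" %in% cfg$models) {
    t0 <- Sys.time()
    preds$cnn <- vapply(te, function(i) {
      probs <- predict(cnn_model, seqs[[i]]$frames, type = "prob")
      gp <- collapse_subclass_probs(probs, cfg$n_bins)
      v <- max.col(gp, ties.method = "first") - 1L
      # only frames that contain a plant vote
      keep <- vapply(masks[[i]], sum, numeric(1)) >= cfg$min_area
      if (!any(keep)) keep <- rep(TRUE, length(v))
      majority_vote(v[keep], L)
    }, integer(1))
    evals$cnn <- evaluate(preds$cnn, truth, class_names)
    timings["cnn"] <- as.numeric(Sys.time() - t0, units = "secs")
  }

  if (any(cfg$models %in% c("cnn-crf", "cnn-lstm"))) {
    t0 <- Sys.time()
    dseq_tr <- deep_sequences(cnn_model, seqs[tr])
    dseq_te <- deep_sequences(cnn_model, seqs[te])
    timings["deep_features"] <- as.numeric(Sys.time() - t0, units = "secs")
    if ("cnn-crf" %in% cfg$models) {
      t0 <- Sys.time()
      crf_args <- utils::modifyList(
        list(sequences = dseq_tr, labels = labs[tr], n_classes = L), cfg$crf)
      m <- do.call(crf_baseline, crf_args)
      sc <- predict(m, dseq_te)
      preds$`cnn-crf` <- max.col(sc, ties.method = "first") - 1L
      evals$`cnn-crf` <- evaluate(preds$`cnn-crf`, truth, class_names)
      timings["cnn-crf"] <- as.numeric(Sys.time() - t0, units = "secs")
    }
    if ("cnn-lstm" %in% cfg$models) {
      t0 <- Sys.time()
      lcfg <- do.call(lstm_config, utils::modifyList(
        list(n_classes = L, seed = cfg$seed + 13L), cfg$lstm))
      m <- train_lstm(dseq_tr, labs[tr], lcfg)
      sc <- predict(m, dseq_te)
      preds$`cnn-lstm` <- max.col(sc, ties.method = "first") - 1L
      evals$`cnn-lstm` <- evaluate(preds$`cnn-lstm`, truth, class_names)
      timings["cnn-lstm"] <- as.numeric(Sys.time() - t0, units = "secs")
    }
  }
  pred_tbl <- dplyr::bind_rows(lapply(names(preds), function(mn)
    tibble::tibble(model = mn, plant_id = test_ids, truth = unname(truth),
                   pred = unname(preds[[mn]]))))
  list(evals = evals, predictions = pred_tbl, timings = timings)
}

#' Run a configured experiment end-to-end
#'
#' Simulates (or loads) the dataset, derives masks, extracts the feature
#' representations the configured model variants need, trains every variant on
#' the training plants and evaluates on the held-out plants (or pools
#' predictions over cross-validation folds). Returns per-variant evaluations
#' and a result-table-style report with one row per variant.
#'
#' @param cfg an [experiment_config()].
#' @return a `phenoseq_experiment`: list with `report` (tibble: model,
#'   per-class accuracies, `avg`), `evals`, `predictions`, `timings`,
#'   `config`, `seed`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  t_start <- Sys.time()
  if (!is.null(cfg$data_dir)) {
    ds <- read_dataset(cfg$data_dir)
  } else {
    ds <- generate_sequences(cfg$panel, cfg$n_plants_per_class, cfg$n_days,
                             cfg$canvas_size, seed = cfg$seed)
  }
  seqs <- ds$sequences
  class_names <- unique(ds$manifest$genotype_name[order(ds$manifest$genotype_index)])
  masks <- if (cfg$mask_source == "truth") {
    lapply(seqs, function(s) {
      if (is.null(s$truth_masks))
        stop("mask_source = 'truth' but sequences carry no truth masks; ",
             "use mask_source = 'segment'", call. = FALSE)
      s$truth_masks
    })
  } else {
    lapply(seqs, function(s) lapply(s$frames, segment_plant))
  }

  need_hc <- any(cfg$models %in% c("svm", "handcrafted-lstm"))
  feat_tbl <- if (need_hc) extract_features_table(seqs, masks) else NULL

  plant_tbl <- dplyr::distinct(tibble::tibble(
    plant_id = vapply(seqs, function(s) s$plant_id, character(1)),
    genotype_index = vapply(seqs, function(s) s$genotype, integer(1))))

  if (!is.null(cfg$k_folds)) {
    folds <- make_splits(plant_tbl, k_folds = cfg$k_folds, seed = cfg$seed + 1L)
    runs <- lapply(seq_len(cfg$k_folds), function(f) {
      run_one_split(cfg, seqs, feat_tbl, masks,
                    folds$plant_id[folds$fold != f],
                    folds$plant_id[folds$fold == f], class_names)
    })
    pred_tbl <- dplyr::bind_rows(lapply(runs, `[[`, "predictions"))
    evals <- lapply(split(pred_tbl, pred_tbl$model), function(d)
      evaluate(d$pred, d$truth, class_names))
    timings <- Reduce(`+`, lapply(runs, `[[`, "timings"))
  } else {
    sp <- make_splits(plant_tbl, train_fraction = cfg$train_fraction,
                      seed = cfg$seed + 1L)
    res <- run_one_split(cfg, seqs, feat_tbl, masks,
                         sp$plant_id[sp$split == "train"],
                         sp$plant_id[sp$split == "test"], class_names)
    pred_tbl <- res$predictions
    evals <- res$evals
    timings <- res$timings
  }

  order_models <- intersect(c("svm", "handcrafted-lstm", "cnn", "cnn-crf", "cnn-lstm"),
                            names(evals))
  report <- dplyr::bind_rows(lapply(order_models, function(mn) {
    ev <- evals[[mn]]
    row <- as.list(setNames(ev$summary$accuracy, ev$summary$class))
    tibble::as_tibble(c(list(model = mn), row, list(avg = ev$macro_accuracy)))
  }))

  out <- structure(list(report = report, evals = evals, predictions = pred_tbl,
                        timings = timings, config = cfg, seed = cfg$seed,
                        elapsed = as.numeric(Sys.time() - t_start, units = "secs")),
                   class = "phenoseq_experiment")
  if (!is.null(cfg$out_dir)) write_experiment(out, cfg$out_dir)
  out
}

#' @export
print.phenoseq_experiment <- function(x, ...) {
  cat(sprintf("<phenoseq_experiment> seed %d, %.1f s\n", x$seed, x$elapsed))
  print(as.data.frame(x$report), digits = 3)
  invisible(x)
}

#' @rdname run_experiment
#' @param x a `phenoseq_experiment`.
#' @param ... unused.
#' @export
tidy.phenoseq_experiment <- function(x, ...) {
  tidyr::pivot_longer(x$report, -"model", names_to = "class",
                      values_to = "accuracy")
}

#' @rdname run_experiment
#' @export
glance.phenoseq_experiment <- function(x, ...) {
  tibble::tibble(model = x$report$model, avg_accuracy = x$report$avg,
                 seed = x$seed, elapsed = x$elapsed)
}

# write report.json, confusion_<model>.csv and log.txt under a run directory
write_experiment <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(seed = res$seed, report = res$report),
                       file.path(out_dir, "report.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  for (mn in names(res$evals)) {
    utils::write.csv(res$evals[[mn]]$confusion,
                     file.path(out_dir, sprintf("confusion_%s.csv", gsub("[^a-z-]", "", mn))))
  }
  cfg <- res$config
  lines <- c(sprintf("phenoseq %s", as.character(utils::packageVersion("phenoseq"))),
             sprintf("R %s", R.version.string),
             sprintf("seed: %d", res$seed),
             sprintf("models: %s", paste(cfg$models, collapse = ", ")),
             sprintf("mask_source: %s", cfg$mask_source),
             sprintf("plants/class: %s, days: %s, canvas: %s",
                     cfg$n_plants_per_class, cfg$n_days, cfg$canvas_size),
             sprintf("split: %s", if (is.null(cfg$k_folds))
               sprintf("train_fraction %.2f", cfg$train_fraction)
               else sprintf("%d-fold CV", cfg$k_folds)),
             "stage timings (s):",
             sprintf("  %s: %.1f", names(res$timings), res$timings),
             sprintf("total elapsed: %.1f s", res$elapsed))
  writeLines(lines, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' The bundled synthetic benchmark
#'
#' Runs the five model variants on the default four-accession panel
#' (20 plants/class, 22 daily frames, 128 px canvas, ground-truth masks,
#' 75/25 plant-level split) -- the package's desk-scale analogue of a
#' multi-accession classification benchmark.
#'
#' @param seed master seed.
#' @param models model variants to run.
#' @param ... overrides passed to [experiment_config()].
#' @return a `phenoseq_experiment`.
#' @export
run_benchmark <- function(seed = 1,
                          models = c("svm", "handcrafted-lstm", "cnn",
                                     "cnn-crf", "cnn-lstm"), ...) {
  cfg <- experiment_config(panel = default_accession_panel(),
                           n_plants_per_class = 20, n_days = 22,
                           canvas_size = 128, models = models,
                           mask_source = "truth", train_fraction = 0.75,
                           seed = seed, ...)
  run_experiment(cfg)
}

#' Temporal-benefit contrast on the dynamics-only pair
#'
#' Trains the frame-CNN (majority vote) and the CNN-LSTM on the two accessions
#' that share every static appearance parameter and differ only in growth
#' dynamics, and reports both held-out accuracies and their difference -- the
#' desk-scale analogue of the accuracy gained by modelling the sequence.
#'
#' @param seed master seed.
#' @param n_plants_per_class plants per class.
#' @param ... overrides passed to [experiment_config()].
#' @return list with `cnn_accuracy`, `lstm_accuracy`, `gain_points` (in
#'   percentage points) and the underlying `experiment`.
#' @export
temporal_contrast <- function(seed = 1, n_plants_per_class = 20, ...) {
  cfg <- experiment_config(panel = dynamics_panel(),
                           n_plants_per_class = n_plants_per_class,
                           n_days = 22, canvas_size = 128,
                           models = c("cnn", "cnn-lstm"), mask_source = "truth",
                           train_fraction = 0.75, seed = seed, ...)
  res <- run_experiment(cfg)
  cnn_acc <- res$evals$cnn$macro_accuracy
  lstm_acc <- res$evals$`cnn-lstm`$macro_accuracy
  list(cnn_accuracy = cnn_acc, lstm_accuracy = lstm_acc,
       gain_points = lstm_acc - cnn_acc, experiment = res)
}
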