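# End-to-end orchestration: cohort (EDF directory or synthetic spec) ->
# filter-bank design -> sub-band norm features -> optional class balancing
# -> ensemble fit with repeated stratified 10-fold CV -> report tables.

#' Configure an experiment
#'
#' @param data either a \code{"cohort_spec"} (synthetic cohort) or a list
#'   with \code{edf} (named character: group -> EDF path) and
#'   \code{hypnogram} (matching hypnogram paths).
#' @param channels channels to feed the feature stage (concatenated).
#' @param filter list of filter-design parameters ([default_filter_bank()]
#'   arguments: L, M, omega_p, alpha, gamma, R, V).
#' @param balance \code{"none"} (unbalanced), \code{"dataset"} (balance the
#'   whole dataset before CV, the study protocol) or \code{"strict"}
#'   (balance within training folds only; not the study protocol).
#' @param target_per_class per-class target when balancing.
#' @param classifier list with \code{n_learners}, \code{max_splits} and the
#'   inert \code{learning_rate}.
#' @param k,trials CV protocol.
#' @param seed master seed for the whole run.
#' @param out_dir optional directory for CSV reports.
#' @return object of class \code{"experiment_config"}.
#' @export
experiment_config <- function(data,
                              channels = c("F4-C4", "C4-A1"),
                              filter = list(),
                              balance = c("none", "dataset", "strict"),
                              target_per_class = NULL,
                              classifier = list(n_learners = 30L,
                                                max_splits = NULL,
                                                learning_rate = 1),
                              k = 10L, trials = 5L, seed = 1L,
                              out_dir = NULL) {
  balance <- match.arg(balance)
  if (!length(channels)) stop("channels must be non-empty", call. = FALSE)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (trials < 1L) stop("trials must be >= 1", call. = FALSE)
  structure(list(data = data, channels = channels, filter = filter,
                 balance = balance, target_per_class = target_per_class,
                 classifier = classifier, k = as.integer(k),
                 trials = as.integer(trials), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Flat key-value config; synthetic cohorts are given as
#' \code{data: {groups: {healthy: {W: 10, ...}}, fs: 512, epoch_s: 30}}.
#'
#' @param path YAML file.
#' @return an \code{"experiment_config"}.
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  data <- if (!is.null(cfg$data$groups)) {
    cohort_spec(lapply(cfg$data$groups, unlist),
                fs = cfg$data$fs %||% 512,
                epoch_s = cfg$data$epoch_s %||% 30,
                seed = cfg$data$seed %||% cfg$seed %||% 1L,
                channels = cfg$channels %||% c("F4-C4", "C4-A1"))
  } else {
    list(edf = unlist(cfg$data$edf), hypnogram = unlist(cfg$data$hypnogram))
  }
  experiment_config(
    data = data,
    channels = cfg$channels %||% c("F4-C4", "C4-A1"),
    filter = cfg$filter %||% list(),
    balance = cfg$balance %||% "none",
    target_per_class = cfg$target_per_class,
    classifier = utils::modifyList(list(n_learners = 30L, max_splits = NULL,
                                        learning_rate = 1),
                                   cfg$classifier %||% list()),
    k = cfg$k %||% 10L, trials = cfg$trials %||% 5L,
    seed = cfg$seed %||% 1L, out_dir = cfg$out_dir
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_experiment_epochs <- function(cfg) {
  if (inherits(cfg$data, "cohort_spec")) {
    message("pipeline: generating synthetic cohort (seed ", cfg$data$seed, ")")
    return(generate_cohort(cfg$data))
  }
  stopifnot(is.list(cfg$data), !is.null(cfg$data$edf), !is.null(cfg$data$hypnogram))
  sets <- lapply(seq_along(cfg$data$edf), function(i) {
    path <- cfg$data$edf[[i]]
    grp <- names(cfg$data$edf)[i] %||% NA_character_
    message("pipeline: reading ", path)
    chans <- lapply(cfg$channels, function(ch) read_edf_channel(path, ch))
    fs <- unique(vapply(chans, `[[`, 1, "fs"))
    if (length(fs) != 1L) stop("channel sampling rates differ", call. = FALSE)
    samples <- lapply(chans, `[[`, "samples")
    names(samples) <- cfg$channels
    hyp <- parse_hypnogram(cfg$data$hypnogram[[i]])
    segment_epochs(samples, fs = fs, hypnogram = hyp,
                   subject_id = basename(path), group = grp)
  })
  records <- do.call(c, lapply(sets, `[[`, "records"))
  epoch_set(records, channels = cfg$channels, fs = sets[[1]]$fs,
            epoch_s = sets[[1]]$epoch_s)
}

#' Run a full scoring experiment
#'
#' Executes the pipeline end to end and returns (and optionally writes) the
#' report bundle: epoch accounting before and after balancing, the designed
#' filter bank, the ANOVA feature screening and the cross-validated
#' classification results.  Fully reproducible from the master seed.
#'
#' @param cfg an \code{"experiment_config"}.
#' @return list with \code{accounting}, \code{balanced_accounting},
#'   \code{bank}, \code{features}, \code{anova}, \code{cv}.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  stage <- "load epochs"
  result <- tryCatch({
    epochs <- load_experiment_epochs(cfg)
    groups <- vapply(epochs$records, function(r) as.character(r$group), "")
    sets <- split(seq_along(epochs$records), groups)
    accounting <- epoch_accounting(lapply(sets, function(ii) {
      epoch_set(epochs$records[ii], epochs$channels, epochs$fs, epochs$epoch_s)
    }))

    stage <- "filter design"
    bank <- do.call(default_filter_bank, cfg$filter)

    stage <- "feature extraction"
    message("pipeline: extracting features for ", length(epochs), " epochs")
    fm <- build_feature_matrix(epochs, bank, channels = cfg$channels)

    stage <- "balancing"
    balanced_accounting <- NULL
    if (cfg$balance == "dataset") {
      target <- cfg$target_per_class %||% min(table(stage_factor(fm$label)))
      fm <- balance_classes(fm, target, seed = derive_seed(cfg$seed, "balance"))
      balanced_accounting <- accounting_table(
        matrix(as.integer(table(stage_factor(fm$label))), ncol = 1,
               dimnames = list(stage_levels(), "balanced")))
    }

    stage <- "feature screening"
    screening <- rank_features(fm)

    stage <- "cross-validation"
    message("pipeline: ", cfg$trials, " x ", cfg$k, "-fold CV")
    cv <- repeated_cv(fm, fm$label,
                      n_learners = cfg$classifier$n_learners %||% 30L,
                      max_splits = cfg$classifier$max_splits,
                      k = cfg$k, trials = cfg$trials,
                      seed = derive_seed(cfg$seed, "cv"))

    list(accounting = accounting, balanced_accounting = balanced_accounting,
         bank = bank, features = fm, anova = screening, cv = cv)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, name) utils::write.csv(
      x, file.path(cfg$out_dir, paste0(name, ".csv")), row.names = TRUE)
    wr(result$accounting, "accounting")
    if (!is.null(result$balanced_accounting)) {
      wr(result$balanced_accounting, "accounting_balanced")
    }
    wr(as.data.frame(result$anova), "anova")
    wr(unclass(result$cv$confusion), "confusion_counts")
    wr(round(row_percent(result$cv$confusion), 2), "confusion_row_percent")
    wr(result$cv$per_class, "per_class_metrics")
    wr(data.frame(trial = seq_along(result$cv$per_trial_accuracy),
                  accuracy = result$cv$per_trial_accuracy,
                  kappa = result$cv$per_trial_kappa), "trials")
    write_filter_bank(result$bank, file.path(cfg$out_dir, "filter_bank.txt"))
  }
  result
}
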