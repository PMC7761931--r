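#' Default pipeline parameters
#'
#' The numeric settings used throughout the pipeline: two-second epochs,
#' +/-100 uV amplitude limit, theta/alpha ratio threshold 1, 30 randomly
#' selected epochs, all 11 canonical bands, SFS cap 30, 10 x 10-fold CV,
#' significance level 0.05.
#'
#' @return named list of defaults; pass (a modified copy) to [run_full()].
#' @export
pipeline_defaults <- function() {
  list(
    epoch_seconds = 2,
    amplitude_limit = 100,
    ratio_threshold = 1,
    k_epochs = 30,
    bands = band_table()$name,
    edge_trim = 0.1,
    plv_method = "epochs",
    max_k = 30,
    n_folds = 10,
    repeats = 10,
    sfs_folds = 10,
    alpha = 0.05,
    mode = "paper",
    pairs = list("group"),
    seed = 1L
  )
}

# Per-subject: preprocess epochs, band-pass each requested band, PLV, graph
# features. Returns the named feature vector.
subject_features <- function(epochs, params, seed) {
  ep <- preprocess_epochs(epochs, limit = params$amplitude_limit,
                          threshold = params$ratio_threshold,
                          k = params$k_epochs, seed = seed,
                          allow_fewer = TRUE)
  mats <- lapply(params$bands, function(b) {
    plv_matrix(bandpass(ep, b), band = b,
               method = params$plv_method, edge_trim = params$edge_trim)
  })
  assemble_features(mats)
}

#' Build the cohort feature table
#'
#' Runs preprocessing, band-pass decomposition, PLV connectivity and graph
#' features for every subject and stacks the feature vectors into a matrix
#' (one row per subject).
#'
#' @param cohort list of subjects as from [generate_cohort()] (each with
#'   `id`, `group`, `epochs`, optionally `panss`).
#' @param params parameter list, see [pipeline_defaults()].
#' @return numeric matrix `subjects x features`, rownames = subject ids,
#'   with attribute `groups` (integer vector) and attribute `panss`
#'   (data.frame of items, when present).
#' @export
cohort_features <- function(cohort, params = pipeline_defaults()) {
  rows <- lapply(seq_along(cohort), function(i) {
    subject_features(cohort[[i]]$epochs, params,
                     seed = derive_seed(params$seed, 100L, i))
  })
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(cohort, `[[`, character(1), "id")
  attr(X, "groups") <- vapply(cohort, `[[`, numeric(1), "group")
  if (!is.null(cohort[[1L]]$panss)) {
    attr(X, "panss") <- as.data.frame(do.call(rbind, lapply(cohort, `[[`, "panss")))
  }
  X
}

# Labels for one classification pair.
pair_labels <- function(pair, groups, panss) {
  if (identical(pair, "group")) {
    return(factor(ifelse(groups == 2, "case", "control"),
                  levels = c("control", "case")))
  }
  if (is.null(panss)) stop(sprintf("pair '%s' needs PANSS items but none are available", pair))
  factor_name <- match.arg(pair, c("positive", "negative", "cognitive",
                                   "excitement", "depression"))
  scores <- vapply(seq_len(nrow(panss)), function(i) {
    score_factors(panss[i, , drop = FALSE])[[factor_name]]
  }, numeric(1))
  sp <- median_split(scores)
  factor(sp$labels, levels = c("low", "high"))
}

#' Run the full analysis pipeline
#'
#' Simulation (optional) - preprocessing - connectivity - network features -
#' labels - classification - significance threshold, for each requested
#' classification pair. With identical configuration and seeds the report is
#' identical.
#'
#' @param config either a [cohort_config] (the cohort is generated) or a
#'   cohort list as from [generate_cohort()] / [read_subject()].
#' @param params parameter list, see [pipeline_defaults()]. `params$pairs`
#'   selects the contrasts: `"group"` (group 2 vs group 1) and/or a PANSS
#'   five-factor name (`"positive"`, `"negative"`, `"cognitive"`, ...) for a
#'   high/low median-split contrast.
#' @return object of class `srcnet_report`: list with `features` (matrix),
#'   `params` and `pairs` (named list of `cv_report`s).
#' @export
run_full <- function(config, params = pipeline_defaults()) {
  cohort <- if (inherits(config, "cohort_config")) {
    generate_cohort(config)
  } else config
  X <- cohort_features(cohort, params)
  groups <- attr(X, "groups")
  panss <- attr(X, "panss")
  pairs <- list()
  for (pair in params$pairs) {
    y <- pair_labels(pair, groups, panss)
    pairs[[pair]] <- run_pair(X, y, mode = params$mode,
                              max_k = params$max_k,
                              n_folds = params$n_folds,
                              repeats = params$repeats,
                              sfs_folds = params$sfs_folds,
                              alpha = params$alpha,
                              seed = derive_seed(params$seed, 200L,
                                                 match(pair, params$pairs)))
  }
  structure(list(features = X, params = params, pairs = pairs),
            class = "srcnet_report")
}

#' @export
print.srcnet_report <- function(x, ...) {
  cat(sprintf("<srcnet_report> %d subjects x %d features; %d pair(s)\n",
              nrow(x$features), ncol(x$features), length(x$pairs)))
  for (nm in names(x$pairs)) {
    p <- x$pairs[[nm]]
    cat(sprintf("  %-12s acc %6.2f %%  sens %6.2f %%  spec %6.2f %%  thr %5.2f %% (%s)\n",
                nm, p$accuracy, p$sensitivity, p$specificity,
                p$threshold_pct,
                if (isTRUE(p$exceeds_threshold)) "above" else "not above"))
  }
  invisible(x)
}

#' Serialise a pipeline report to JSON
#'
#' @param report a `srcnet_report` or single `cv_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(p) list(
    mode = p$mode, n = p$n, accuracy = p$accuracy,
    sensitivity = p$sensitivity, specificity = p$specificity,
    auc = p$auc, threshold_pct = p$threshold_pct,
    exceeds_threshold = p$exceeds_threshold,
    selected = p$selected,
    selected_names = if (!is.null(p$feature_names)) p$feature_names[p$selected],
    trace = p$trace)
  out <- if (inherits(report, "cv_report")) strip(report) else {
    list(n_subjects = nrow(report$features),
         n_features = ncol(report$features),
         params = report$params[setdiff(names(report$params), "pairs")],
         pairs = lapply(report$pairs, strip))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Rank selected features by region and band
#'
#' Counts how often each region tag and each band occurs among the selected
#' features of a classification report and ranks them, marking ties with
#' equal rank. Region tags are free-text labels attached to nodes (for real
#' data, e.g. a lobe grouping; synthetic nodes get synthetic tags).
#'
#' @param report a `cv_report` from [run_pair()] with `feature_names` of the
#'   form `{band}__{kind}__{node}` (as produced by [assemble_features()]).
#' @param regions optional named character vector mapping node label ->
#'   region tag; unmapped nodes count under their own label.
#' @return list with data.frames `by_region` and `by_band` (`name`, `count`,
#'   `rank`; ties share the minimum rank).
#' @export
summarize_selected <- function(report, regions = NULL) {
  sel <- report$selected
  if (is.null(sel) || !length(sel)) {
    empty <- data.frame(name = character(0), count = integer(0),
                        rank = integer(0))
    return(list(by_region = empty, by_band = empty))
  }
  nms <- report$feature_names[sel]
  parts <- strsplit(nms, "__", fixed = TRUE)
  band <- vapply(parts, `[[`, character(1), 1L)
  node <- vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else NA_character_,
                 character(1))
  reg <- node
  if (!is.null(regions)) {
    mapped <- !is.na(node) & node %in% names(regions)
    reg[mapped] <- regions[node[mapped]]
  }
  rank_table <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(data.frame(name = character(0),
                                      count = integer(0), rank = integer(0)))
    tab <- sort(table(v), decreasing = TRUE)
    data.frame(name = names(tab), count = as.integer(tab),
               rank = as.integer(rank(-as.integer(tab), ties.method = "min")),
               row.names = NULL)
  }
  list(by_region = rank_table(reg), by_band = rank_table(band))
}
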