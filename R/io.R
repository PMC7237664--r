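#' Cohort input/output and pipeline orchestration
#'
#' Cohorts are written as a TSV (subjects x columns, header row, subject-ID
#' first column) plus a JSON sidecar carrying the configuration, seed,
#' ground-truth causal ids and per-feature kinds, so that a written cohort
#' round-trips exactly. [orchestrate()] ties the stages together: simulate
#' (or read) a cohort, evaluate a model registry on one shared fold plan,
#' emit the group-comparison report and the marker analysis, and write a
#' MANIFEST with a checksum for every output.
#'
#' @name cli_io
#' @keywords internal
NULL

#' Write a cohort to a directory
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, "cohort.tsv")
  js <- file.path(dir, "cohort.json")
  # %.17g so that doubles survive the text round trip bit-identically
  feat_chr <- apply(cohort$features, 2, function(x) sprintf("%.17g", x))
  df <- data.frame(subject_id = sprintf("S%04d", seq_len(nrow(cohort$features))),
                   feat_chr, outcome = cohort$outcome,
                   check.names = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(config = unclass(cohort$config),
                  feature_kinds = as.list(cohort$feature_kinds),
                  metabolite_names = cohort$metabolite_names,
                  covariate_names = cohort$covariate_names,
                  causal_ids = cohort$causal_ids,
                  causal_links = as.list(cohort$causal_links),
                  missing_flag = cohort$missing_flag,
                  unreliable_flag = cohort$unreliable_flag)
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA, null = "null"), js)
  invisible(c(tsv = tsv, json = js))
}

#' Read a cohort from TSV (+ JSON sidecar)
#'
#' Expects the layout written by [write_cohort()]: a header row, a
#' `subject_id` first column, an `outcome` column, and a sidecar declaring
#' per-feature kinds. Subjects with a missing outcome are listwise-deleted
#' with a message. A written-then-read synthetic cohort round-trips
#' bit-identically.
#'
#' @param path the TSV file.
#' @param sidecar the JSON sidecar; defaults to `cohort.json` next to `path`.
#' @return a `cohort`.
#' @export
read_cohort_tsv <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- file.path(dirname(path), "cohort.json")
  if (!file.exists(path)) stop("read_cohort_tsv: no such file: ", path)
  if (!file.exists(sidecar)) stop("read_cohort_tsv: missing sidecar: ", sidecar)
  meta <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(colnames(df)[1], "subject_id"))
    stop("read_cohort_tsv: malformed header, first column must be 'subject_id' (got '",
         colnames(df)[1], "')")
  if (!"outcome" %in% colnames(df))
    stop("read_cohort_tsv: malformed header, no 'outcome' column")
  feat_names <- setdiff(colnames(df), c("subject_id", "outcome"))
  kinds <- unlist(meta$feature_kinds)
  unknown <- setdiff(feat_names, names(kinds))
  if (length(unknown))
    stop("read_cohort_tsv: feature(s) with no declared kind: ",
         paste(unknown, collapse = ", "))
  bad_kind <- setdiff(unique(kinds), c("continuous", "categorical"))
  if (length(bad_kind))
    stop("read_cohort_tsv: unknown feature kind: ", paste(bad_kind, collapse = ", "))
  for (f in feat_names) {
    if (!is.numeric(df[[f]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[f]]))))[1]
      stop("read_cohort_tsv: non-numeric value in column '", f, "', row ", bad)
    }
  }
  miss <- is.na(df$outcome)
  if (any(miss)) {
    message("read_cohort_tsv: listwise-deleting ", sum(miss),
            " subject(s) with missing outcome")
    df <- df[!miss, , drop = FALSE]
  }
  n <- nrow(df)
  features <- as.matrix(df[, feat_names, drop = FALSE])
  cfg <- meta$config
  config <- if (!is.null(cfg)) {
    cfg$covariate_effects <- unlist(cfg$covariate_effects)
    if (is.null(cfg$intercept)) cfg$intercept <- NA_real_
    do.call(cohort_config, cfg)
  } else {
    cohort_config(n_subjects = n, n_metabolites = length(meta$metabolite_names))
  }
  structure(list(features = features,
                 feature_kinds = kinds[feat_names],
                 metabolite_names = meta$metabolite_names,
                 covariate_names = meta$covariate_names,
                 outcome = as.integer(df$outcome),
                 missing_flag = if (!is.null(meta$missing_flag) && length(meta$missing_flag) == n)
                   meta$missing_flag else rep(FALSE, n),
                 unreliable_flag = if (!is.null(meta$unreliable_flag) && length(meta$unreliable_flag) == n)
                   meta$unreliable_flag else rep(FALSE, n),
                 causal_ids = meta$causal_ids,
                 causal_links = unlist(meta$causal_links),
                 config = config),
            class = "cohort")
}

#' Run the full pipeline end to end
#'
#' Simulate (or read) a cohort, apply exclusions, evaluate every model in
#' the registry on one shared fold plan (quantitative branch, plus a binary
#' branch at `cutoff` when `binary = TRUE`), write the group-comparison
#' report, run the marker analysis over the feature-selecting models, and
#' emit a MANIFEST listing every output file with its MD5 checksum. Fully
#' deterministic given (`config`, `seed`).
#'
#' @param config a [cohort_config()] (the synthetic source), or a path to a
#'   cohort TSV.
#' @param out_dir output directory.
#' @param seed seed for the fold plan and model fits.
#' @param models named list of `model_spec`s for the quantitative branch;
#'   defaults to [default_model_registry()].
#' @param models_binary same for the binary branch (`NULL` to derive).
#' @param cutoff binarization cutoff.
#' @param binary also run the binary branch?
#' @param verbose print progress?
#' @return invisibly, the manifest data.frame.
#' @export
orchestrate <- function(config, out_dir, seed = 1L,
                        models = NULL, models_binary = NULL,
                        cutoff = 16, binary = TRUE, verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- if (inherits(config, "cohort_config")) generate_cohort(config)
            else read_cohort_tsv(config)
  cohort <- suppressMessages(apply_exclusions(cohort))
  write_cohort(cohort, file.path(out_dir, "cohort"))

  X <- cohort$features
  kinds <- cohort$feature_kinds
  yq <- cohort$outcome
  yb <- binarize_outcome(yq, cutoff)
  if (is.null(models)) models <- default_model_registry("quantitative")
  if (binary && is.null(models_binary)) {
    models_binary <- lapply(models, function(m) {
      model_spec(m$name,
                 selector = m$selector,
                 predictor = switch(m$predictor,
                                    kernel_ridge = "svm_rbf",
                                    linear_regression = "logistic_regression",
                                    m$predictor),
                 selector_grid = as.list(m$selector_grid),
                 predictor_grid = as.list(m$predictor_grid))
    })
  }

  run_branch <- function(specs, y, kind, plan) {
    res <- lapply(specs, function(sp) {
      if (verbose) message("evaluating: ", sp$name, " (", kind, ")")
      suppressWarnings(run_nested_cv(X, y, sp, plan, kind, kinds,
                                     cohort$metabolite_names,
                                     cohort$covariate_names))
    })
    names(res) <- names(specs)
    res
  }
  plan_q <- make_fold_plan(nrow(X), seed)
  res_q <- run_branch(models, yq, "quantitative", plan_q)
  res_b <- if (binary) {
    plan_b <- make_fold_plan(nrow(X), seed, stratify_labels = yb)
    run_branch(models_binary, yb, "binary", plan_b)
  } else NULL

  score_tab <- do.call(rbind, lapply(c(res_q, res_b), function(r)
    data.frame(model = r$model, metric = r$metric,
               fold = seq_along(r$scores), score = r$scores)))
  utils::write.table(score_tab, file.path(out_dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  prov <- list(seed = seed, cutoff = cutoff,
               config = if (inherits(config, "cohort_config")) unclass(config) else config,
               models = lapply(c(res_q, res_b), function(r)
                 list(model = r$model, metric = r$metric, scores = r$scores,
                      hyperparams = r$hyperparams, selected = r$selected,
                      audit_ok = r$audit_ok)))
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA, null = "null"),
             file.path(out_dir, "provenance.json"))

  report <- build_cohort_report(cohort, cutoff)
  utils::write.table(report, file.path(out_dir, "cohort_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  selecting <- names(models)[vapply(models, function(m)
    m$selector %in% c("hsic_lasso", "lasso", "pvalue_screen"), logical(1))]
  selq <- res_q[selecting]
  if (binary && length(selq)) {
    selb <- res_b[intersect(names(selq), names(res_b))]
    if (length(selb)) {
      mk <- marker_report(selq, selb, cohort, cutoff = cutoff)
      utils::write.table(mk$frequencies, file.path(out_dir, "marker_frequencies.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (nrow(mk$consistent))
        utils::write.table(mk$consistent, file.path(out_dir, "consistent_markers.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      dep_vars <- c(list(outcome = yq),
                    lapply(cohort$covariate_names, function(v) X[, v]),
                    lapply(utils::head(mk$consistent$feature, 6), function(v) X[, v]))
      names(dep_vars) <- c("outcome", cohort$covariate_names,
                           utils::head(mk$consistent$feature, 6))
      dep_kinds <- c(outcome = "continuous", kinds)
      dep <- pairwise_hsic_table(dep_vars, dep_kinds,
                                 covariate_names = cohort$covariate_names)
      utils::write.table(round(dep$values, 3), file.path(out_dir, "dependency_table.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
    }
  }

  files <- setdiff(list.files(out_dir, recursive = TRUE), "MANIFEST.tsv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "MANIFEST.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
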