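# Plain-text serialization: trial archives (one CSV per trial with a JSON
# sidecar), pipeline configs (JSON/YAML), evaluation reports (JSON), and a
# JSON export of MDRM / decision-tree models.

#' Write a trial archive
#'
#' Writes one CSV per trial (rows = channels, no header) into `dir`, plus a
#' `meta.json` sidecar holding labels (`null` for unlabelled), the sampling
#' rate, and the file manifest.
#'
#' @param x An `mi_trials` object, or a list with `trials`, `labels`, `fs`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trials <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("trial_%04d.csv", seq_along(x$trials))
  for (i in seq_along(x$trials)) {
    utils::write.table(x$trials[[i]], file.path(dir, files[i]), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  labels <- as.character(x$labels)
  meta <- list(fs = x$fs, files = files,
               labels = ifelse(is.na(labels), NA, labels))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a trial archive written by [write_trials()]
#'
#' @param dir Archive directory.
#' @return List with `trials` (list of matrices), `labels` (factor with
#'   `NA` for unlabelled), `fs`; class `mi_trials`.
#' @export
read_trials <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  trials <- lapply(meta$files, function(f) {
    as.matrix(utils::read.table(file.path(dir, f), sep = ",", header = FALSE))
  })
  trials <- lapply(trials, unname)
  labels <- factor(meta$labels)
  structure(list(trials = trials, labels = labels,
                 true_labels = labels, fs = meta$fs),
            class = "mi_trials")
}

#' Write / read a pipeline configuration
#'
#' JSON (default) or YAML, by file extension.
#'
#' @param config A [pipeline_config()].
#' @param path Target file (`.json` or `.yaml`/`.yml`).
#' @return `path` / the config, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml package not available")
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  defaults <- pipeline_config()
  for (nm in names(x)) defaults[[nm]] <- x[[nm]]
  class(defaults) <- "pipeline_config"
  defaults
}

#' Export an evaluation report to JSON
#'
#' @param report An `mi_cv` report from [crossval()].
#' @param path Target JSON file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(folds = report$folds,
              mean_accuracy = report$mean_accuracy,
              mean_kappa = report$mean_kappa,
              per_fold = report$per_fold,
              confusion = as.data.frame.matrix(report$confusion),
              routing = as.list(report$routing),
              seed = report$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Export an MDRM model or decision-tree skeleton to JSON
#'
#' MDRM models are exported in full (class means as arrays); decision trees
#' export their skeleton (node order, kinds, targets, CV accuracies) plus
#' any MDRM node models.
#'
#' @param model An `mdrm` or `ssdt` object.
#' @param path Target JSON file.
#' @return `path`, invisibly.
#' @export
export_model_json <- function(model, path) {
  ser <- function(m) {
    if (inherits(m, "mdrm")) {
      list(kind = "mdrm", classes = m$classes,
           means = lapply(m$means, function(M) unclass(unname(M))))
    } else if (inherits(m, "riemi_knn")) {
      list(kind = "knn", k = m$k, labels = as.character(m$labels),
           points = unclass(unname(m$points)))
    } else {
      list(kind = class(m)[1])
    }
  }
  out <- if (inherits(model, "ssdt")) {
    list(kind = "ssdt", classes = model$classes, base_kind = model$base_kind,
         final_scope = model$final_scope,
         nodes = lapply(model$nodes, function(nd) {
           list(node_id = nd$node_id, kind = nd$kind,
                target_class = nd$target_class, cv_accuracy = nd$cv_accuracy,
                model = ser(nd$model))
         }))
  } else {
    ser(model)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
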