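annotation_columns <- c("subject_id", "finding", "r1_stage1", "r2_stage1",
                        "merged_stage1", "r1_stage2", "r2_stage2", "group")

#' Write / read annotation tables (TSV)
#'
#' Tab-separated, UTF-8, one header line. On reading, every row is
#' revalidated: binary call fields must be 0/1, the merged first-stage
#' call must equal the union of the two first-stage reads, and the stored
#' group must equal the group recomputed from the calls.
#'
#' @param annotations Tibble with the annotation columns (see
#'   [simulate_annotations()]).
#' @param path File path.
#' @return `read_annotations()` returns the validated tibble;
#'   `write_annotations()` returns `path` invisibly.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(all(annotation_columns %in% names(annotations)))
  readr::write_tsv(annotations[annotation_columns], path)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  tbl <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    subject_id = "c", finding = "c", r1_stage1 = "i", r2_stage1 = "i",
    merged_stage1 = "c", r1_stage2 = "i", r2_stage2 = "i", group = "c"
  )))
  missing <- setdiff(annotation_columns, names(tbl))
  if (length(missing) > 0L) {
    stop("annotation file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(tbl) == 0L) return(tbl)
  bin <- c("r1_stage1", "r2_stage1", "r1_stage2", "r2_stage2")
  for (col in bin) {
    bad <- which(!tbl[[col]] %in% c(0L, 1L))
    if (length(bad) > 0L) {
      stop("non-binary value in column ", col, " at data line ", bad[[1L]],
           " of ", path, call. = FALSE)
    }
  }
  merged <- ifelse(tbl$r1_stage1 | tbl$r2_stage1, "P", "N")
  bad <- which(merged != tbl$merged_stage1)
  if (length(bad) > 0L) {
    stop("merged_stage1 inconsistent with first-stage reads at data line ",
         bad[[1L]], " of ", path, call. = FALSE)
  }
  regroup <- derive_group(tbl$merged_stage1, tbl$r1_stage2, tbl$r2_stage2)
  bad <- which(regroup != tbl$group)
  if (length(bad) > 0L) {
    stop("group inconsistent with recorded calls at data line ", bad[[1L]],
         " of ", path, call. = FALSE)
  }
  tbl
}

#' Write / read prediction tables (TSV)
#'
#' Columns `subject_id`, `finding`, `model_index`, `logit`. Reading
#' rejects duplicate `(subject, finding, model)` cells, non-finite
#' logits, and incomplete grids (every subject must carry every model
#' index for every finding).
#'
#' @param predictions Prediction tibble.
#' @param path File path.
#' @return `read_predictions()` returns the validated tibble;
#'   `write_predictions()` returns `path` invisibly.
#' @export
write_predictions <- function(predictions, path) {
  cols <- c("subject_id", "finding", "model_index", "logit")
  stopifnot(all(cols %in% names(predictions)))
  readr::write_tsv(predictions[cols], path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    subject_id = "c", finding = "c", model_index = "i", logit = "d"
  ))
  if (!all(c("subject_id", "finding", "model_index", "logit") %in%
           names(tbl))) {
    stop("prediction file ", path, " lacks the required columns",
         call. = FALSE)
  }
  if (nrow(tbl) == 0L) return(tbl)
  bad <- which(!is.finite(tbl$logit))
  if (length(bad) > 0L) {
    stop("non-finite logit at data line ", bad[[1L]], " of ", path,
         call. = FALSE)
  }
  key <- paste(tbl$subject_id, tbl$finding, tbl$model_index)
  if (anyDuplicated(key)) {
    dup <- key[which(duplicated(key))[1L]]
    stop("duplicate prediction cell (", dup, ") in ", path, call. = FALSE)
  }
  counts <- tbl |>
    dplyr::summarise(n = dplyr::n(), .by = c("subject_id", "finding"))
  k <- length(unique(tbl$model_index))
  bad <- counts[counts$n != k, ]
  if (nrow(bad) > 0L) {
    stop("incomplete prediction grid: subject ", bad$subject_id[[1L]],
         ", finding ", bad$finding[[1L]], " has ", bad$n[[1L]], " of ", k,
         " model entries", call. = FALSE)
  }
  tbl
}

#' Pipeline configuration
#'
#' Bundles the per-stage configurations and a global seed; every stage
#' reads only its own section plus the seed, and the object round-trips
#' through YAML unchanged.
#'
#' @param simulation A [sim_config()].
#' @param images An [image_config()], or `NULL` to skip image rendering.
#' @param training A [train_config()], or `NULL` to use ideal simulated
#'   logits instead of training.
#' @param cv Named list of [make_cv_plan()] parameters `k` and `test_n`.
#' @param calibration A [distance_config()].
#' @param n_models Number of simulated model replicates in ideal-logit
#'   mode.
#' @param seed Global seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            images = NULL,
                            training = NULL,
                            cv = list(k = 10L, test_n = 1000L),
                            calibration = distance_config(),
                            n_models = 10L,
                            seed = 1L) {
  structure(list(simulation = simulation, images = images,
                 training = training, cv = cv, calibration = calibration,
                 n_models = as.integer(n_models), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns the configuration;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  stripped <- rapply(unclass(config), f = identity, how = "replace")
  yaml::write_yaml(stripped, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  simplify <- function(x) lapply(x, function(v) {
    if (is.list(v)) unlist(v) else v
  })
  pipeline_config(
    simulation = do.call(sim_config, simplify(raw$simulation)),
    images = if (!is.null(raw$images)) {
      do.call(image_config, simplify(raw$images))
    },
    training = if (!is.null(raw$training)) {
      args <- simplify(raw$training)
      args$optimizer <- NULL
      args$policy <- if (!is.null(raw$training$policy)) {
        do.call(augment_policy, simplify(raw$training$policy))
      } else {
        augment_policy()
      }
      do.call(train_config, args)
    },
    cv = simplify(raw$cv),
    calibration = do.call(distance_config, simplify(raw$calibration)),
    n_models = raw$n_models,
    seed = raw$seed
  )
}
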