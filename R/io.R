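# Plain-text IO: subject tables (CSV), connectome matrices (delimited
# text, one per subject, with a manifest), serialized models and
# validation reports (JSON + aligned text table).

#' Read and validate a subject table
#'
#' Expects a CSV with header `subject_id,score,scale,group,age,gender`.
#' Scores must lie in the named scale's range, scales in {BDI, HDRS},
#' groups in {HC, MDD}, gender codes in {0, 1}, and subject ids must be
#' unique; violations raise an error naming the offending row.
#'
#' @param path CSV file path.
#' @return Validated `data.frame`.
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "score", "scale", "group", "age", "gender")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id at row ",
         which(duplicated(df$subject_id))[1L])
  }
  rng <- scale_ranges()
  bad_scale <- which(!df$scale %in% names(rng))
  if (length(bad_scale)) {
    stop("unknown scale '", df$scale[bad_scale[1L]], "' at row ",
         bad_scale[1L])
  }
  bad_score <- which(!is.finite(df$score) | df$score < 0 |
                       df$score > rng[df$scale])
  if (length(bad_score)) {
    stop("score ", df$score[bad_score[1L]], " outside 0-",
         rng[[df$scale[bad_score[1L]]]], " at row ", bad_score[1L])
  }
  bad_group <- which(!df$group %in% c("HC", "MDD"))
  if (length(bad_group)) {
    stop("unknown group '", df$group[bad_group[1L]], "' at row ",
         bad_group[1L])
  }
  bad_gender <- which(!df$gender %in% c(0, 1))
  if (length(bad_gender)) {
    stop("gender must be coded 0/1; offending row ", bad_gender[1L])
  }
  df
}

#' Write a subject table
#' @param subjects Cohort `data.frame` (see [gen_cohort()]).
#' @param path Output CSV path.
#' @export
write_subject_table <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a connectome matrix from delimited text
#'
#' Enforces the connectome contract: square, numeric, entries in `[0, 1]`,
#' symmetric within `tol` (then exactly symmetrized), diagonal zeroed.
#'
#' @param path Delimited text file (whitespace or comma separated).
#' @param expected_n Expected number of regions (default 68).
#' @param tol Maximum tolerated asymmetry (default 1e-8).
#' @return `cpm_connectome` matrix.
#' @export
read_connectome <- function(path, expected_n = 68, tol = 1e-8) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  mat <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(mat) <- NULL
  if (!is.numeric(mat)) stop(path, ": non-numeric entries")
  if (nrow(mat) != ncol(mat)) {
    stop(path, ": not square (", nrow(mat), " x ", ncol(mat), ")")
  }
  if (!is.null(expected_n) && nrow(mat) != expected_n) {
    stop(path, ": expected ", expected_n, " regions, found ", nrow(mat))
  }
  if (any(mat < 0 | mat > 1)) stop(path, ": entries outside [0, 1]")
  if (max(abs(mat - t(mat))) > tol) {
    stop(path, ": asymmetry exceeds tolerance ", tol)
  }
  mat <- (mat + t(mat)) / 2
  diag(mat) <- 0
  structure(mat, subject_id = sub("\\.[^.]*$", "", basename(path)),
            class = "cpm_connectome")
}

#' Write a connectome matrix as tab-delimited text
#' @param mat Square symmetric matrix.
#' @param path Output path.
#' @export
write_connectome <- function(mat, path) {
  utils::write.table(format(unclass(mat), digits = 10, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a cohort's connectomes via a manifest
#'
#' @param manifest CSV with columns `subject_id`, `file` (paths relative to
#'   the manifest's directory or absolute).
#' @param expected_n Regions per matrix (default 68).
#' @return Subjects x edges matrix with subject ids as row names.
#' @export
read_connectome_set <- function(manifest, expected_n = 68) {
  mf <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "file") %in% names(mf)))
  base <- dirname(manifest)
  mats <- lapply(seq_len(nrow(mf)), function(i) {
    p <- mf$file[i]
    if (!file.exists(p)) p <- file.path(base, mf$file[i])
    m <- read_connectome(p, expected_n = expected_n)
    attr(m, "subject_id") <- mf$subject_id[i]
    m
  })
  stack_connectomes(mats)
}

#' Serialize a trained CPM model to JSON
#'
#' Stores the scale parameters, frozen edge standardization, network edge
#' indices, regressor coefficients, hyperparameters, and an optional config
#' echo; [read_model()] restores a model that predicts identically.
#'
#' @param model A [cpm_train()] model.
#' @param path Output JSON path.
#' @param config Optional named list echoed into the file.
#' @export
write_model <- function(model, path, config = NULL) {
  stopifnot(inherits(model, "cpm_model"))
  reg <- model$regressor
  doc <- list(
    package = "eegcpm",
    feature_mode = model$feature_mode,
    q = model$q, C = model$C, epsilon = model$epsilon,
    train_mean = model$train_mean,
    scale_params = if (is.null(model$scale_params)) NULL
                   else unclass(model$scale_params),
    network = list(pos_edges = model$network$pos_edges,
                   neg_edges = model$network$neg_edges),
    edge_std = list(means = model$edge_std$means, sds = model$edge_std$sds,
                    degenerate = which(model$edge_std$degenerate)),
    regressor = if (inherits(reg, "dummy_model")) {
      list(type = "dummy", mean = reg$mean)
    } else {
      list(type = "svr", w = reg$w, b = reg$b, C = reg$C,
           epsilon = reg$epsilon, d = reg$d)
    },
    config = config
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Restore a CPM model from JSON
#' @param path JSON file written by [write_model()].
#' @return A `cpm_model`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  int <- function(x) as.integer(unlist(x))   # empty JSON arrays -> list()
  m <- length(doc$edge_std$means)
  degenerate <- logical(m)
  degenerate[int(doc$edge_std$degenerate)] <- TRUE
  std <- structure(list(means = doc$edge_std$means, sds = doc$edge_std$sds,
                        degenerate = degenerate),
                   class = "edge_standardization")
  net <- predictive_network(int(doc$network$pos_edges),
                            int(doc$network$neg_edges))
  reg <- if (identical(doc$regressor$type, "dummy")) {
    structure(list(mean = doc$regressor$mean), class = "dummy_model")
  } else {
    structure(list(w = doc$regressor$w, b = doc$regressor$b,
                   beta = NULL, C = doc$regressor$C,
                   epsilon = doc$regressor$epsilon, d = doc$regressor$d),
              class = "svr_model")
  }
  sp <- if (is.null(doc$scale_params)) NULL
        else scale_params(doc$scale_params$scale, doc$scale_params$mean,
                          doc$scale_params$sd, doc$scale_params$range_max)
  structure(list(edge_std = std, network = net,
                 feature_mode = doc$feature_mode, regressor = reg,
                 q = doc$q, C = doc$C, epsilon = doc$epsilon,
                 train_mean = doc$train_mean, scale_params = sp),
            class = "cpm_model")
}

#' Write a validation report as JSON plus an aligned text table
#'
#' @param report A `cpm_cv` (or any named list of numeric summaries).
#' @param path Output JSON path; a sibling `.txt` summary table is written
#'   unless `txt_path = NA`.
#' @param txt_path Text table path (default: `path` with `.txt`).
#' @param config Optional config echo (seed, flags) stored in the JSON and
#'   printed in the table header.
#' @export
write_report <- function(report, path, txt_path = NULL, config = NULL) {
  fields <- c("r", "mae", "r_squared", "dummy_mae")
  doc <- list(config = config)
  for (f in intersect(fields, names(report))) doc[[f]] <- as.list(report[[f]])
  for (f in c("k", "n_iterations", "q", "feature_mode", "n", "seed",
              "p", "observed_mae", "n_perm", "boot_p", "scale")) {
    if (!is.null(report[[f]])) doc[[f]] <- report[[f]]
  }
  if (!is.null(report$edge_counts)) {
    doc$edge_counts <- list(min = min(report$edge_counts),
                            max = max(report$edge_counts),
                            mean = mean(report$edge_counts))
  }
  if (!is.null(report$per_group)) doc$per_group <- report$per_group
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (is.null(txt_path)) txt_path <- sub("\\.json$", ".txt", path)
  if (!is.na(txt_path)) {
    con <- file(txt_path, "w")
    on.exit(close(con))
    writeLines("eegcpm validation report", con)
    if (!is.null(config)) {
      writeLines(paste0("config: ",
                        paste(names(config), unlist(config), sep = "=",
                              collapse = " ")), con)
    }
    fmt <- function(v) {
      if (length(v) == 2L && all(c("mean", "sd") %in% names(v)))
        sprintf("%.4f +/- %.4f", v[["mean"]], v[["sd"]])
      else sprintf("%.4f", as.numeric(v)[1L])
    }
    for (f in intersect(c(fields, "p", "boot_p"), names(doc))) {
      writeLines(sprintf("  %-12s %s", f, fmt(doc[[f]])), con)
    }
    if (!is.null(doc$per_group)) {
      for (g in names(doc$per_group)) {
        writeLines(sprintf("  group %-6s r %.4f  mae %.4f", g,
                           doc$per_group[[g]]$r, doc$per_group[[g]]$mae),
                   con)
      }
    }
  }
  invisible(path)
}
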