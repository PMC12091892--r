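# File formats: headered TSV for stimuli and spikes, JSON for models,
# schedules, and run configs.  All text, schema-versioned, round-trip
# exact at the stored precision.

MODEL_SCHEMA <- "1.0"

#' Write / read a stimulus trace
#'
#' A stimulus serializes to a two-file pair: a headered TSV
#' (`frame_index`, `value`, `segment_label`) and a JSON sidecar
#' (`<path>.json`) with the frame rate and segment table.
#'
#' @param stim a [stimulus_trace()].
#' @param path TSV file path; the sidecar is written to `<path>.json`.
#' @return `write_stimulus`: `path`, invisibly. `read_stimulus`: the
#'   [stimulus_trace()].
#' @export
write_stimulus <- function(stim, path) {
  n <- length(stim$values)
  label <- rep(NA_character_, n)
  for (i in seq_len(nrow(stim$segments))) {
    label[(stim$segments$start[i] + 1L):stim$segments$end[i]] <-
      stim$segments$label[i]
  }
  utils::write.table(
    data.frame(frame_index = seq_len(n) - 1L,
               value = sprintf("%.17g", stim$values),
               segment_label = label),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(schema_version = MODEL_SCHEMA,
         frame_rate_hz = stim$frame_rate_hz,
         segments = stim$segments),
    paste0(path, ".json"), auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_stimulus
#' @export
read_stimulus <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("frame_index", "value")
  if (!all(need %in% names(tab))) {
    stop_invalid("%s: expected columns %s", path, paste(need, collapse = ", "))
  }
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop_invalid("missing sidecar %s", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  check_schema(meta, side)
  stimulus_trace(tab$value, meta$frame_rate_hz,
                 as.data.frame(meta$segments))
}

#' Write / read binned spike counts
#'
#' Headered TSV with columns `bin_index` and `count` (one `count_trialK`
#' column per trial for trial matrices).  Counts must be non-negative
#' integers; malformed files raise a parse error naming the offending
#' line.
#'
#' @param counts integer vector, or a trial-by-bin matrix.
#' @param path TSV file path.
#' @return `write_spikes`: `path`, invisibly. `read_binned_spikes`: an
#'   integer vector, or a trial-by-bin matrix when the file holds several
#'   trial columns.
#' @export
write_spikes <- function(counts, path) {
  if (is.matrix(counts)) {
    df <- data.frame(bin_index = seq_len(ncol(counts)) - 1L,
                     t(counts))
    names(df)[-1L] <- paste0("count_trial", seq_len(nrow(counts)))
  } else {
    df <- data.frame(bin_index = seq_along(counts) - 1L, count = counts)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_binned_spikes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  cols <- setdiff(names(tab), "bin_index")
  if (!"bin_index" %in% names(tab) || length(cols) == 0L) {
    stop_invalid("%s: expected columns bin_index and count...", path)
  }
  for (cl in cols) {
    v <- tab[[cl]]
    bad <- which(!is.finite(v) | v < 0 | abs(v - round(v)) > 1e-8)
    if (length(bad) > 0L) {
      stop_invalid("%s: line %d, column %s: invalid spike count %s",
                   path, bad[1L] + 1L, cl, format(v[bad[1L]]))
    }
  }
  if (length(cols) == 1L) {
    as.integer(tab[[cols]])
  } else {
    t(as.matrix(tab[cols]))
  }
}

check_schema <- function(meta, path) {
  if (is.null(meta$schema_version) ||
      !identical(as.character(meta$schema_version), MODEL_SCHEMA)) {
    stop_invalid("%s: schema version mismatch (found %s, expected %s)",
                 path, meta$schema_version %||% "none", MODEL_SCHEMA)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an encoding model
#'
#' Models serialize to a schema-versioned JSON document holding the kind,
#' frame rate, tap vectors, knots/weights with their shape class, and
#' rectifier parameters; numbers are stored at full precision so the
#' round trip is exact.
#'
#' @param model an [encoding_model()].
#' @param path JSON file path.
#' @return `write_model`: `path`, invisibly. `read_model`: the
#'   [encoding_model()].
#' @export
write_model <- function(model, path) {
  nl_doc <- function(nl) {
    if (is.null(nl)) return(NULL)
    list(shape = nl$shape, knots = nl$knots, weights = nl$weights)
  }
  doc <- list(schema_version = MODEL_SCHEMA,
              kind = model$kind,
              frame_rate_hz = model$frame_rate_hz,
              n_taps = model$n_taps,
              exc = list(taps = model$exc$taps, nl = nl_doc(model$exc$nl)),
              sup = if (is.null(model$sup)) NULL else
                list(taps = model$sup$taps, nl = nl_doc(model$sup$nl)),
              fb_taps = model$fb_taps,
              rectifier = model$rectifier[c("a", "b", "c", "m")])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_schema(doc, path)
  nl_from <- function(d) {
    if (is.null(d)) return(NULL)
    tent_nonlinearity(d$weights, d$shape, as.numeric(d$knots))
  }
  encoding_model(doc$kind,
                 as.numeric(doc$exc$taps), nl_from(doc$exc$nl),
                 if (is.null(doc$sup)) NULL else as.numeric(doc$sup$taps),
                 if (is.null(doc$sup)) NULL else nl_from(doc$sup$nl),
                 if (is.null(doc$fb_taps)) NULL else as.numeric(doc$fb_taps),
                 softplus_rectifier(doc$rectifier$a, doc$rectifier$b,
                                    doc$rectifier$c, doc$rectifier$m),
                 doc$frame_rate_hz)
}

#' Read a run configuration
#'
#' JSON config with the training settings; missing fields take the
#' standard defaults (`n_taps = 15`, `n_runs = 5`, `max_iter = 100`,
#' `tol = 1e-4` i.e. 0.01%, `seed = 1`).
#'
#' @param path JSON file path, or a named list (returned normalized).
#' @return named list of settings.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    path
  }
  defaults <- list(preset = "divisive_off", kinds = "divisive",
                   n_taps = 15L, n_runs = 5L, max_iter = 100L, tol = 1e-4,
                   seed = 1L, n_train_block = 1500L, n_frozen = 300L,
                   n_blocks = 12L, chirp_trials = 0L,
                   n_eval_feedback = 100L, out_dir = ".")
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  cfg
}

#' Run the simulate-fit-evaluate pipeline
#'
#' Simulates a recording from a ground-truth preset, fits the requested
#' model kinds, evaluates each on the held-out data, writes the fitted
#' models plus a summary TSV to `out_dir`, and returns the summary.
#'
#' @param config a named list or JSON path (see [read_run_config()]).
#' @return data.frame with one row per fitted kind: train/test information
#'   per spike, Poisson explained variance (where frozen repeats exist),
#'   and the excitatory-filter cosine similarity to the ground truth.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  cell <- make_cell(cfg$preset, n_taps = cfg$n_taps,
                    seed = derive_seed(cfg$seed, 1L))
  rec <- simulate_recording(cell,
                            n_train_block = cfg$n_train_block,
                            n_frozen = cfg$n_frozen,
                            n_blocks = cfg$n_blocks,
                            chirp_trials = cfg$chirp_trials,
                            seed = derive_seed(cfg$seed, 2L))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  rows <- lapply(cfg$kinds, function(kind) {
    fit <- fit_model(kind, rec$stim, rec$counts, rec$schedule,
                     n_taps = cfg$n_taps, n_runs = cfg$n_runs,
                     seed = derive_seed(cfg$seed, 3L),
                     max_iter = cfg$max_iter, tol = cfg$tol)
    write_model(fit$model, file.path(cfg$out_dir,
                                     sprintf("model_%s.json", kind)))
    ev <- evaluate_model(fit$model, rec$stim, rec$counts, rec$schedule,
                         n_eval_feedback = cfg$n_eval_feedback,
                         seed = derive_seed(cfg$seed, 4L))
    data.frame(kind = kind,
               preset = cfg$preset,
               train_nll = fit$train_nll,
               info_train = ev$info_train,
               info_test = ev$info_test,
               pev_test = ev$pev_test,
               cos_exc = abs(sum(fit$model$exc$taps * cell$exc$taps)))
  })
  summary <- do.call(rbind, rows)
  utils::write.table(summary, file.path(cfg$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary
}
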