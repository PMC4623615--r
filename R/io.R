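# Serialization: models as JSON documents, stimulus/spike and mosaic tables
# as CSV with a commented metadata header, plus run manifests. All formats
# round-trip losslessly.

IO_FORMAT_VERSION <- "1.0"

#' Write / read a model as JSON
#'
#' Subunit models are stored as a JSON document holding the assignment (a
#' list of cone-index lists per subunit), the within-subunit weight rows,
#' the subunit weights, both spline nonlinearities (nodes, nodal values and
#' derived piecewise coefficients), and optional metadata (e.g. seed, fit
#' log-likelihood). LN models store weights and the output nonlinearity.
#' \code{write_model_json(read_model_json(path))} reproduces the file text
#' exactly.
#'
#' @param model A \code{subunit_model} or \code{ln_model}.
#' @param path Output/input file path.
#' @param metadata Optional named list stored verbatim.
#' @return \code{read_model_json} returns the model with a
#'   \code{"metadata"} attribute; \code{write_model_json} returns
#'   \code{path} invisibly.
#' @export
write_model_json <- function(model, path, metadata = NULL) {
  if (inherits(model, "subunit_model")) {
    subunits <- apply(model$indicator, 1, function(r) which(r == 1),
                      simplify = FALSE)
    doc <- list(
      version = IO_FORMAT_VERSION,
      type = "subunit_model",
      cone_ids = model$cone_ids,
      subunits = subunits,
      cone_weights = lapply(seq_along(subunits), function(s)
        unname(model$cone_weights[s, subunits[[s]]])),
      subunit_weights = model$subunit_weights,
      f = spline_doc(model$f),
      g = spline_doc(model$g))
  } else if (inherits(model, "ln_model")) {
    doc <- list(version = IO_FORMAT_VERSION, type = "ln_model",
                cone_ids = model$cone_ids, weights = model$weights,
                g = spline_doc(model$g))
  } else stop("model must be a subunit_model or ln_model")
  if (!is.null(metadata)) doc$metadata <- metadata
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

spline_doc <- function(sp) {
  cf <- spline_coefficients(sp)
  list(node_x = sp$node_x, node_y = sp$node_y,
       coefficients = apply(unname(cf$intervals), 1, function(r) unname(r),
                            simplify = FALSE),
       extrapolation_slopes = cf$extrapolation_slopes)
}

need_field <- function(doc, field, path) {
  if (is.null(doc[[field]]))
    stop("model JSON '", path, "' is missing required field '", field, "'")
  doc[[field]]
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = FALSE)
  type <- need_field(doc, "type", path)
  g <- parse_spline(need_field(doc, "g", path), path)
  if (type == "subunit_model") {
    subunits <- need_field(doc, "subunits", path)
    A_rows <- need_field(doc, "cone_weights", path)
    w <- need_field(doc, "subunit_weights", path)
    cone_ids <- need_field(doc, "cone_ids", path)
    C <- length(cone_ids); S <- length(subunits)
    ind <- matrix(0, S, C); A <- matrix(0, S, C)
    for (s in seq_len(S)) {
      ind[s, subunits[[s]]] <- 1
      A[s, subunits[[s]]] <- A_rows[[s]]
    }
    f <- parse_spline(need_field(doc, "f", path), path)
    model <- subunit_model(ind, A, as.numeric(w), f, g, cone_ids = cone_ids)
  } else if (type == "ln_model") {
    model <- ln_model(as.numeric(need_field(doc, "weights", path)), g,
                      cone_ids = need_field(doc, "cone_ids", path))
  } else stop("model JSON '", path, "' has unknown type '", type, "'")
  attr(model, "metadata") <- doc$metadata
  model
}

parse_spline <- function(node, path) {
  if (is.null(node$node_x) || is.null(node$node_y))
    stop("model JSON '", path, "' has a spline without 'node_x'/'node_y'")
  nl_spline(as.numeric(node$node_x), as.numeric(node$node_y))
}

#' Write / read a cone stimulus (and optional spike counts) as CSV
#'
#' Plain-text container for the stimulus/response pair: commented header
#' lines carry the frame rate and cone identifiers, then one row per frame
#' with one column per cone (full precision) plus a \code{count} column when
#' spike counts are stored. Round-trips losslessly.
#'
#' @param stim A [cone_stimulus()].
#' @param path File path.
#' @param counts Optional spike-count vector aligned to the frames.
#' @return \code{read_stimulus_csv} returns a list with \code{stimulus} and
#'   \code{counts} (NULL if absent).
#' @export
write_stimulus_csv <- function(stim, path, counts = NULL) {
  if (!inherits(stim, "cone_stimulus")) stop("stim must be a cone_stimulus")
  if (!is.null(counts)) counts <- spike_counts(counts, n_frames(stim))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# rgcsubunits_stimulus v", IO_FORMAT_VERSION),
               paste0("# frame_rate_hz: ",
                      format(stim$frame_rate_hz, digits = 17)),
               paste0("# cone_ids: ", paste(stim$cone_ids, collapse = ","))),
             con)
  df <- as.data.frame(t(stim$values))
  names(df) <- stim$cone_ids
  if (!is.null(counts)) df$count <- counts
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_csv
#' @export
read_stimulus_csv <- function(path) {
  header <- readLines(path, n = 3)
  if (!startsWith(header[1], "# rgcsubunits_stimulus"))
    stop("'", path, "' is not a stimulus CSV (missing signature line)")
  fr <- as.numeric(sub("# frame_rate_hz: *", "", header[2]))
  if (is.na(fr)) stop("'", path, "' is missing the 'frame_rate_hz' header")
  ids <- strsplit(sub("# cone_ids: *", "", header[3]), ",")[[1]]
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  counts <- NULL
  if ("count" %in% names(df)) {
    counts <- spike_counts(df$count)
    df$count <- NULL
  }
  if (!identical(names(df), ids))
    stop("'", path, "' cone columns do not match the 'cone_ids' header")
  vals <- t(as.matrix(df))
  dimnames(vals) <- NULL
  list(stimulus = cone_stimulus(vals, fr, cone_ids = ids),
       counts = counts)
}

#' Write / read a cone mosaic as CSV
#'
#' @param mosaic A [make_mosaic()] table.
#' @param path File path.
#' @return \code{read_mosaic_csv} returns the \code{cone_mosaic} data frame.
#' @export
write_mosaic_csv <- function(mosaic, path) {
  utils::write.csv(as.data.frame(mosaic)[, c("id", "x", "y", "sigma", "gain")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mosaic_csv
#' @export
read_mosaic_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "x", "y", "sigma", "gain")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("mosaic CSV '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  class(df) <- c("cone_mosaic", "data.frame")
  df
}

#' Write a reproducibility manifest
#'
#' Records everything needed to regenerate a run's outputs bit-identically:
#' the seed, the full configuration values, package and R versions, and the
#' output files written.
#'
#' @param path Output JSON path.
#' @param seed The run's seed.
#' @param config Configuration list (e.g. a [fit_config()]).
#' @param outputs Character vector of files the run wrote.
#' @export
write_manifest <- function(path, seed, config = NULL, outputs = character(0)) {
  doc <- list(version = IO_FORMAT_VERSION,
              package = "rgcsubunits",
              package_version = as.character(utils::packageVersion("rgcsubunits")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              seed = seed,
              config = unclass(config),
              outputs = outputs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Simulate a dataset to files
#'
#' Generates a white-noise stimulus, Poisson responses from a ground-truth
#' model, and writes the stimulus/spikes CSV, the ground-truth model JSON,
#' the mosaic CSV and a manifest into a directory. Idempotent per seed.
#'
#' @param dir Output directory (created if needed).
#' @param model Ground-truth model (default [example_ground_truth()]).
#' @param duration_min Stimulus duration (minutes).
#' @param frame_rate_hz Frame rate.
#' @param contrast Binary noise contrast.
#' @param seed Integer seed.
#' @return Invisibly, the named vector of files written.
#' @export
simulate_dataset <- function(dir, model = example_ground_truth(),
                             duration_min = 16, frame_rate_hz = 12,
                             contrast = 0.96, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  C <- ncol(model$indicator)
  stim <- white_noise_cone_stimulus(C, duration_min, frame_rate_hz, contrast,
                                    seed = seed)
  counts <- simulate_spikes(model, stim, seed = seed + 1L)
  mosaic <- make_mosaic(C, seed = seed)
  files <- c(stimulus = file.path(dir, "stimulus.csv"),
             model = file.path(dir, "ground_truth_model.json"),
             mosaic = file.path(dir, "mosaic.csv"),
             manifest = file.path(dir, "manifest.json"))
  write_stimulus_csv(stim, files["stimulus"], counts)
  write_model_json(model, files["model"], metadata = list(seed = seed))
  write_mosaic_csv(mosaic, files["mosaic"])
  write_manifest(files["manifest"], seed,
                 config = list(duration_min = duration_min,
                               frame_rate_hz = frame_rate_hz,
                               contrast = contrast),
                 outputs = unname(files[1:3]))
  invisible(files)
}
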