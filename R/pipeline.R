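#' End-to-end pipeline configuration
#'
#' Bundles everything a reproducible two-phase run needs: the cutout
#' geometry, the backend/predictor selection, post-processing toggles
#' and the RNG seed. Serializable to/from a single JSON file; unknown
#' keys are rejected so stale configs fail loudly.
#'
#' @param cutout A [cutout_config].
#' @param backend `"oracle"`, `"noisy"` or `"external"` (phase-1
#'   semantic backend; oracle/noisy require a phantom at run time).
#' @param predictor `"oracle"`, `"noisy"` or `"external"` (phase-2
#'   cutout predictor).
#' @param postprocess_skip Rule names to skip (see [postprocess_pair]).
#' @param noise List of noise parameters (`flip_rate`,
#'   `boundary_jitter`) for the noisy backend/predictor.
#' @param seed Integer seed governing every stochastic component.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cutout = cutout_config(),
                            backend = c("oracle", "noisy", "external"),
                            predictor = c("oracle", "noisy", "external"),
                            postprocess_skip = character(),
                            noise = list(flip_rate = 0.02,
                                         boundary_jitter = 0.1),
                            seed = 1L) {
  stopifnot(inherits(cutout, "cutout_config"))
  backend <- match.arg(backend)
  predictor <- match.arg(predictor)
  rules <- c("remove_unsupported", "rescue_missing", "remove_isolated",
             "relabel_articular")
  bad <- setdiff(postprocess_skip, rules)
  if (length(bad))
    stop("unknown post-processing rule(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  structure(list(cutout = cutout, backend = backend, predictor = predictor,
                 postprocess_skip = as.character(postprocess_skip),
                 noise = noise, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` to serialize.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- config
  stopifnot(inherits(cfg, "pipeline_config"))
  jsonlite::write_json(
    list(cutout = list(size = cfg$cutout$size, spacing = cfg$cutout$spacing,
                       orientation = cfg$cutout$orientation),
         backend = cfg$backend, predictor = cfg$predictor,
         postprocess_skip = cfg$postprocess_skip, noise = cfg$noise,
         seed = cfg$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("cutout", "backend", "predictor", "postprocess_skip", "noise",
             "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  co <- if (is.null(raw$cutout)) cutout_config()
  else do.call(cutout_config, raw$cutout[intersect(names(raw$cutout),
                                                   c("size", "spacing",
                                                     "orientation"))])
  pipeline_config(cutout = co,
                  backend = raw$backend %||na% "oracle",
                  predictor = raw$predictor %||na% "oracle",
                  postprocess_skip = raw$postprocess_skip %||na% character(),
                  noise = as.list(raw$noise %||na%
                                    list(flip_rate = 0.02,
                                         boundary_jitter = 0.1)),
                  seed = raw$seed %||na% 1L)
}

`%||na%` <- function(a, b) if (is.null(a)) b else a

#' Run the full two-phase pipeline
#'
#' Canonicalizes the input to P-I-R, runs the semantic stage (phase 1),
#' converts the semantic mask to instances via the cutout machinery
#' (phase 2), applies the post-processing chain, and optionally
#' evaluates against a reference pair. When `output_dir` is given, the
#' semantic mask, instance mask, label-scheme sidecar, resolved config
#' and a plain-text log are written there; reruns from the same config
#' and seed reproduce the outputs exactly.
#'
#' @param input An [anat_volume]: the image (for image-driven backends)
#'   or a semantic mask when `semantic_input = TRUE`.
#' @param config A [pipeline_config].
#' @param phantom A `spine_phantom`, required for the oracle/noisy
#'   backend and predictor.
#' @param backend,predictor Explicit backend/predictor functions for
#'   `"external"` selections.
#' @param reference Optional [mask_pair] to evaluate against.
#' @param semantic_input If `TRUE`, `input` is already a semantic mask
#'   and phase 1 is skipped (after validation).
#' @param output_dir Optional output directory.
#' @return List with `semantic`, `instances`, `report` (or `NULL`) and
#'   the resolved `config`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), phantom = NULL,
                         backend = NULL, predictor = NULL, reference = NULL,
                         semantic_input = FALSE, output_dir = NULL) {
  stopifnot(is_anat_volume(input), inherits(config, "pipeline_config"))
  input <- reorient(input, "PIR")

  if (semantic_input) {
    .validate_semantic_codes(input$data)
    storage.mode(input$data) <- "integer"
    semantic <- input
  } else {
    be <- switch(config$backend,
      oracle = { .need_phantom(phantom, "oracle backend")
                 oracle_semantic_backend(phantom) },
      noisy = { .need_phantom(phantom, "noisy backend")
                noisy_semantic_backend(
                  phantom,
                  flip_rate = config$noise$flip_rate %||na% 0.02,
                  boundary_jitter = config$noise$boundary_jitter %||na% 0.1,
                  seed = config$seed) },
      external = {
        if (!is.function(backend))
          stop("external backend selected but no backend function given",
               call. = FALSE)
        backend
      })
    semantic <- segment_semantic(input, be)
    semantic <- reorient(semantic, "PIR")
  }

  pr <- switch(config$predictor,
    oracle = { .need_phantom(phantom, "oracle predictor")
               oracle_cutout_predictor(phantom) },
    noisy = { .need_phantom(phantom, "noisy predictor")
              noisy_cutout_predictor(
                phantom,
                flip_rate = config$noise$flip_rate %||na% 0.02,
                boundary_jitter = config$noise$boundary_jitter %||na% 0.1,
                seed = config$seed) },
    external = {
      if (!is.function(predictor))
        stop("external predictor selected but no predictor function given",
             call. = FALSE)
      predictor
    })

  stage2 <- segment_instances(semantic, pr, config$cutout)
  pair <- postprocess_pair(mask_pair(semantic, stage2$instances),
                           skip = config$postprocess_skip)
  report <- if (!is.null(reference)) evaluate_subject(pair, reference)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(pair$semantic, file.path(output_dir, "semantic.nii.gz"))
    write_volume(pair$instances, file.path(output_dir, "instances.nii.gz"))
    write_scheme_sidecar(file.path(output_dir, "label_scheme.json"))
    write_pipeline_config(config, file.path(output_dir, "config.json"))
    log_lines <- c(
      paste0("spinemask ", as.character(utils::packageVersion("spinemask"))),
      paste0("seed: ", config$seed),
      paste0("backend: ", config$backend, "; predictor: ", config$predictor),
      paste0("cutout: size ", paste(config$cutout$size, collapse = "x"),
             ", spacing ", paste(config$cutout$spacing, collapse = "x")),
      paste0("postprocess_skip: ",
             if (length(config$postprocess_skip))
               paste(config$postprocess_skip, collapse = ", ") else "none"),
      paste0("vertebrae detected: ", nrow(stage2$centers)))
    writeLines(log_lines, file.path(output_dir, "run.log"))
  }
  list(semantic = pair$semantic, instances = pair$instances,
       report = report, config = config, centers = stage2$centers,
       appearance_sets = stage2$appearance_sets)
}

.need_phantom <- function(phantom, what) {
  if (!inherits(phantom, "spine_phantom"))
    stop(what, " requires a spine_phantom", call. = FALSE)
  invisible(TRUE)
}
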