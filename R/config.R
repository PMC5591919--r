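#' Write / read a study configuration file
#'
#' Serializes a [study_design()] (acquisition schedule, waveform, per-arm
#' effects, frame and grid layout) to a plain-text YAML file so that a run
#' is fully reproducible from its configuration and seed.
#'
#' @param design A [study_design()].
#' @param path File path (YAML).
#' @return `write_study_config()` returns `path` invisibly;
#'   `read_study_config()` returns a [study_design()].
#' @export
write_study_config <- function(design, path) {
  stopifnot(inherits(design, "study_design"))
  cfg <- list(
    study = list(
      n_syncytia = design$n_syncytia,
      minutes = as.numeric(design$minutes),
      fs = design$tb$fs,
      duration = design$tb$duration,
      frame = as.numeric(design$frame),
      grid = list(rows = length(unique(design$grid$y)),
                  cols = length(unique(design$grid$x)),
                  margin = min(design$grid$x))
    ),
    waveform = unclass(design$base),
    conditions = lapply(design$conditions, function(cp)
      unclass(cp)[c("amp_mult", "tau_mult", "rate_mult", "between_cv")])
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("study", "waveform", "conditions")
  missing_top <- setdiff(need, names(cfg))
  if (length(missing_top) > 0)
    abort(paste0("config is missing section(s): ", paste(missing_top, collapse = ", ")))
  s <- cfg$study
  base <- do.call(beat_waveform_params, cfg$waveform)
  conds <- lapply(names(cfg$conditions), function(a)
    do.call(condition_params, c(list(condition = a), cfg$conditions[[a]])))
  names(conds) <- names(cfg$conditions)
  study_design(
    n_syncytia = s$n_syncytia, minutes = s$minutes,
    tb = time_base(fs = s$fs, duration = s$duration),
    base = base, conditions = conds, frame = s$frame,
    rows = s$grid$rows, cols = s$grid$cols, margin = s$grid$margin
  )
}
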