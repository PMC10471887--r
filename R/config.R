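## Run configuration: nested YAML mirroring the constructor arguments of
## synth_config / preprocess_config / arch_config / train_config, plus
## out_dir, log_level and a global seed. Unknown keys are rejected (typo
## safety) with a field-path message.

run_config_sections <- function() {
  list(synth = synth_config, preprocess = preprocess_config,
       architecture = arch_config, train = train_config)
}

check_keys <- function(x, allowed, path) {
  bad <- setdiff(names(x), allowed)
  if (length(bad) > 0) {
    stop_config("unknown configuration key(s): %s",
                paste(paste0(path, "$", bad), collapse = ", "),
                subclass = "fusenet_unknown_key")
  }
}

#' Assemble and validate a run configuration
#'
#' @param x nested named list (typically parsed from YAML); sections
#'   `synth`, `preprocess`, `architecture`, `train`, plus optional `out_dir`,
#'   `log_level` and `seed`. Every section key must name a constructor
#'   argument; unknown keys are rejected with the offending field path.
#' @param seed optional global seed overriding `x$seed`; it is pushed into
#'   the section seeds that are not set explicitly.
#' @return list of validated configuration objects.
#' @export
run_config <- function(x = list(), seed = NULL) {
  check_keys(x, c(names(run_config_sections()), "out_dir", "log_level", "seed"),
             "config")
  seed <- as.integer(seed %||% x$seed %||% 1L)
  out <- list(seed = seed, out_dir = x$out_dir %||% ".",
              log_level = x$log_level %||% "info")
  for (sec in names(run_config_sections())) {
    ctor <- run_config_sections()[[sec]]
    args <- x[[sec]] %||% list()
    check_keys(args, names(formals(ctor)), sec)
    if ("seed" %in% names(formals(ctor)) && is.null(args$seed)) {
      args$seed <- derive_seed(seed, sec)
    }
    out[[sec]] <- do.call(ctor, args)
  }
  out
}

#' @rdname run_config
#' @param file YAML file path.
#' @export
read_run_config <- function(file, seed = NULL) {
  if (!file.exists(file)) stop_data("config file '%s' not found", file)
  run_config(yaml::read_yaml(file) %||% list(), seed = seed)
}

#' @rdname run_config
#' @param cfg a list returned by [run_config()].
#' @export
write_run_config <- function(cfg, file) {
  plain <- lapply(cfg, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, file)
  invisible(file)
}
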