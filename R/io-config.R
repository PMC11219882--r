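#' Serialise / restore simulation and pipeline configurations
#'
#' Configurations round-trip through JSON with all numeric fields and the
#' seed preserved.
#'
#' @param config A [sim_config()] or [pipeline_config()] object.
#' @param path JSON file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   the restored, re-validated object.
#' @export
write_config <- function(config, path) {
  kind <- if (inherits(config, "sim_config")) "sim_config"
          else if (inherits(config, "pipeline_config")) "pipeline_config"
          else stop("unsupported config class")
  fields <- unclass(config)
  # named atomic vectors must become lists to keep names in JSON
  for (nm in c("phase_medians", "phase_dispersions", "oligomycin_scenario"))
    if (!is.null(fields[[nm]])) fields[[nm]] <- as.list(fields[[nm]])
  if (!is.null(fields$sim)) {
    s <- unclass(fields$sim)
    for (nm in c("phase_medians", "phase_dispersions",
                 "oligomycin_scenario"))
      if (!is.null(s[[nm]])) s[[nm]] <- as.list(s[[nm]])
    fields$sim <- s
  }
  payload <- list(kind = kind, fields = fields)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  f <- payload$fields
  f$n_frames <- NULL
  if (identical(payload$kind, "sim_config")) {
    # named vectors come back as named lists or arrays: coerce
    for (nm in c("phase_medians", "phase_dispersions", "oligomycin_scenario"))
      if (!is.null(f[[nm]])) f[[nm]] <- unlist(f[[nm]])
    f$image_size <- as.integer(unlist(f$image_size))
    cfg <- f
    return(validate_sim_config(cfg))
  }
  if (identical(payload$kind, "pipeline_config")) {
    if (!is.null(f$sim)) {
      s <- f$sim
      s$n_frames <- NULL
      for (nm in c("phase_medians", "phase_dispersions",
                   "oligomycin_scenario"))
        if (!is.null(s[[nm]])) s[[nm]] <- unlist(s[[nm]])
      s$image_size <- as.integer(unlist(s$image_size))
      f$sim <- validate_sim_config(s)
    }
    return(do.call(pipeline_config,
                   f[setdiff(names(f), character(0))]))
  }
  stop("unknown config kind in ", path)
}

# polynomial rolling hash of a deterministic serialisation (manifest id)
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
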