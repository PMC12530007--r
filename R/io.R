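#' Read and write model configurations
#'
#' A configuration file is one YAML document per scenario holding any subset
#' of the fields of [thiamalloc_params()] (growth and grid settings nested
#' under `growth:` and `grid:`). Omitted fields take the documented
#' defaults; unknown fields and out-of-range values raise an error naming
#' the offending field. Writing serializes the fully resolved, validated
#' parameter set (including the derived constants `p0`, `px`, `a_g`, `a_m`
#' and the package version) so that `read_params(write_params(p))`
#' round-trips to an equivalent object.
#'
#' @param path File path of the YAML configuration.
#' @param params A [thiamalloc_params()] object.
#' @return `read_params()`: a validated `thiamalloc_params` object.
#'   `write_params()`: `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_params(thiamalloc_params(c_b_mean = 6), f)
#' read_params(f)$c_b_mean
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  cfg$metadata <- NULL
  derived <- c("p0", "px", "a_g", "a_m")
  cfg <- cfg[setdiff(names(cfg), derived)]
  known <- names(formals(thiamalloc_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(cfg$growth)) {
    gk <- names(formals(growth_params))
    bad <- setdiff(names(cfg$growth), gk)
    if (length(bad))
      stop("unknown growth field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    cfg$growth <- do.call(growth_params, cfg$growth)
  }
  if (!is.null(cfg$grid)) {
    gk <- names(formals(grid_params))
    bad <- setdiff(names(cfg$grid), gk)
    if (length(bad))
      stop("unknown grid field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    cfg$grid <- do.call(grid_params, cfg$grid)
  }
  do.call(thiamalloc_params, cfg)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "thiamalloc_params"))
  lst <- unclass(params)
  lst$growth <- unclass(lst$growth)
  lst$grid <- unclass(lst$grid)
  lst$metadata <- list(
    package = "thiamalloc",
    version = as.character(utils::packageVersion("thiamalloc")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(lst, path)
  invisible(path)
}
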