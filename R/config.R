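#' Read generator parameters from a YAML or JSON config file
#'
#' Accepts a file with top-level keys `striation` and/or `morphometry`,
#' whose entries are the arguments of [striation_params()] and
#' [morpho_params()] respectively. Unknown keys raise a validation error
#' so typos do not silently fall back to defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a list with any of `striation` (a `striation_params`) and
#'   `morphometry` (a `morpho_params`).
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop_validation("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_validation("config must be .yaml, .yml or .json: ", path)
  }
  out <- list()
  if (!is.null(raw$striation)) {
    allowed <- names(formals(striation_params))
    bad <- setdiff(names(raw$striation), allowed)
    if (length(bad)) {
      stop_validation("unknown striation keys: ", paste(bad, collapse = ", "))
    }
    out$striation <- do.call(striation_params, raw$striation)
  }
  if (!is.null(raw$morphometry)) {
    allowed <- names(formals(morpho_params))
    bad <- setdiff(names(raw$morphometry), allowed)
    if (length(bad)) {
      stop_validation("unknown morphometry keys: ",
                      paste(bad, collapse = ", "))
    }
    args <- raw$morphometry
    if (!is.null(args$groups)) args$groups <- as.character(args$groups)
    out$morphometry <- do.call(morpho_params, args)
  }
  out
}
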