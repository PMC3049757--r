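#' Read a pipeline configuration from YAML
#'
#' All tunable thresholds live in one YAML file with optional sections
#' `ssr`, `snv_calling`, `filters`, `caps` and `simulation`; keys within a
#' section are the arguments of [ssr_params()], [snv_call_params()],
#' [filter_params()], [caps] (`window_bp`, `enzymes` = path to a TSV panel)
#' and [simulation_config()] respectively. Missing sections and keys fall
#' back to the package defaults.
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @return List with elements `ssr`, `snv_calling`, `filters`, `caps`
#'   (list with `window_bp`, `enzymes`), `simulation`.
#' @export
read_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  take <- function(section, fn) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    args <- args[names(args) %in% names(formals(fn))]
    do.call(fn, args)
  }
  caps <- list(window_bp = 60L, enzymes = default_enzymes())
  if (!is.null(raw$caps$window_bp)) {
    caps$window_bp <- as.integer(raw$caps$window_bp)
  }
  if (!is.null(raw$caps$enzymes)) {
    caps$enzymes <- read_enzymes(raw$caps$enzymes)
  }
  list(ssr = take("ssr", ssr_params),
       snv_calling = take("snv_calling", snv_call_params),
       filters = take("filters", filter_params),
       caps = caps,
       simulation = take("simulation", simulation_config))
}
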