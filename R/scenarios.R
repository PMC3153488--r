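# Built-in scenario library for replicate studies, plus YAML scenario
# configuration round-tripping for the command-line interface.

#' Built-in admixture scenario library
#'
#' Ten scenarios spanning the qualitative contrasts of interest: four
#' stratified nulls of increasing allele-frequency divergence (no
#' within-subpopulation LD, so any detected association is spurious), five
#' non-null scenarios combining divergence with genuine within-subpopulation
#' LD, and a strong null with a reversed additive effect. All use
#' `m = 0.5`, `n = 200` individuals, `d = 1` (except where noted), `h = 0`,
#' `sigma2 = 1`, subpopulation frequencies `0.5 +/- delta/2`, and a control
#' marker with frequencies 0.8/0.2 -- the analyst's control marker is chosen
#' by maximizing the structure signal, so the library models a strongly
#' divergent control.
#'
#' @return A named list of scenarios; each element is a list with fields
#'   `name`, `spec` (an [admixture_spec()]) and `n`.
#' @export
default_scenarios <- function() {
  mk <- function(name, delta, D, d = 1, n = 200) {
    p1 <- 0.5 + delta / 2; p2 <- 0.5 - delta / 2
    list(name = name,
         spec = admixture_spec(
           0.5,
           subpop_model(q = p1, p = p1, c = 0.8, D = D),
           subpop_model(q = p2, p = p2, c = 0.2, D = D),
           qtl_effects(mu = 0, d = d, h = 0, sigma2 = 1)),
         n = n)
  }
  scens <- list(
    mk("null_weak",       delta = 0.2, D = 0),
    mk("null_moderate",   delta = 0.4, D = 0),
    mk("null_strong",     delta = 0.6, D = 0),
    mk("null_strong_d2",  delta = 0.6, D = 0, d = 2),
    mk("ld_weak_struct",      delta = 0.2, D = 0.05),
    mk("ld_moderate_struct",  delta = 0.4, D = 0.08),
    mk("ld_strong_struct",    delta = 0.6, D = 0.08),
    mk("ld_moderate_weakld",  delta = 0.4, D = 0.05),
    mk("ld_weak_strongld",    delta = 0.2, D = 0.08),
    mk("null_strong_negd", delta = 0.6, D = 0, d = -1)
  )
  names(scens) <- vapply(scens, `[[`, "", "name")
  scens
}

#' Convert an admixture scenario to/from a plain list
#'
#' Plain-list form is what the YAML scenario configuration stores.
#'
#' @param spec An [admixture_spec()].
#' @return `spec_to_list()`: a nested plain list; `spec_from_list()`: an
#'   [admixture_spec()].
#' @export
spec_to_list <- function(spec) {
  stopifnot(inherits(spec, "admixture_spec"))
  list(m = spec$m,
       subpop1 = spec$subpop1[c("q", "p", "c", "D")],
       subpop2 = spec$subpop2[c("q", "p", "c", "D")],
       effects = unclass(spec$effects))
}

#' @rdname spec_to_list
#' @param x A plain list with fields `m`, `subpop1`, `subpop2`, `effects`.
#' @export
spec_from_list <- function(x) {
  admixture_spec(
    x$m,
    do.call(subpop_model, x$subpop1),
    do.call(subpop_model, x$subpop2),
    do.call(qtl_effects, x$effects))
}

#' Read or write a scenario configuration file (YAML)
#'
#' The file holds a scenario name, the sample size `n`, and the full
#' admixture parameterization (see [spec_to_list()] for the layout).
#'
#' @param path File path.
#' @return `read_scenario_config()` returns a list with `name`, `n`,
#'   `spec`; `write_scenario_config()` returns `path` invisibly.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$spec)) stop("scenario config lacks a 'spec' block: ", path)
  list(name = cfg$name %||% "scenario",
       n = as.integer(cfg$n %||% 200L),
       spec = spec_from_list(cfg$spec))
}

#' @rdname read_scenario_config
#' @param scenario A list with `name`, `n` and `spec` (an
#'   [admixture_spec()]), e.g. one element of [default_scenarios()].
#' @export
write_scenario_config <- function(scenario, path) {
  yaml::write_yaml(list(name = scenario$name,
                        n = scenario$n,
                        spec = spec_to_list(scenario$spec)),
                   path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
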