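#' Read a simulation configuration file
#'
#' Flat YAML key/value file mirroring the [scaffold_spec()] and
#' [kinetic_params()] fields plus run controls; unknown keys are rejected so
#' typos fail loudly.  Example:
#'
#' ```yaml
#' alpha: 0.5
#' arrangement: lattice
#' pitch: 600
#' voxel_size: 10
#' d_s: 2.4924e-5
#' dt_growth: 2
#' t_end: 1440
#' ```
#'
#' @param path YAML file path.
#' @return list with `spec` ([scaffold_spec()]), `params`
#'   ([kinetic_params()]) and `control` (a list for [run_simulation()]).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  spec_keys <- c("total_thickness", "layer_height", "pitch", "alpha",
                 "strut_width", "arrangement", "voxel_size")
  param_keys <- c("v_max", "k_m", "k", "c_0", "rho_0", "rho_max", "t_d",
                  "d_t", "d_s", "k_d")
  control_keys <- c("dt_growth", "t_end", "stop_when_steady",
                    "eps_per_day", "use_symmetry", "oxygen_tol")
  unknown <- setdiff(names(raw), c(spec_keys, param_keys, control_keys))
  if (length(unknown) > 0L)
    ps_stop("permstrut_malformed_input",
            paste("unknown config keys:", paste(unknown, collapse = ", ")))
  list(spec = do.call(scaffold_spec, raw[intersect(names(raw), spec_keys)]),
       params = do.call(kinetic_params,
                        raw[intersect(names(raw), param_keys)]),
       control = raw[intersect(names(raw), control_keys)])
}

#' Read a bleach-scenario configuration file
#'
#' Flat YAML key/value file mirroring the [bleach_scenario()] fields.
#'
#' @param path YAML file path.
#' @return a [bleach_scenario()].
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(bleach_scenario))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    ps_stop("permstrut_malformed_input",
            paste("unknown scenario keys:", paste(unknown, collapse = ", ")))
  do.call(bleach_scenario, raw)
}
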