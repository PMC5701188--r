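#' Model and program configuration round-trips
#'
#' Models and temperature programs can be serialized to a plain YAML-friendly
#' list in laboratory units (kJ for energies and enthalpies, kJ mol^-1 K^-1
#' for heat capacities and baselines, degrees Celsius and degrees C per
#' minute for programs) and reconstructed losslessly.
#'
#' @param model An [unfolding_model()].
#' @return `model_to_config()`: a list; `config_to_model()`: a model.
#' @examples
#' m <- table2_preset("DbjA")
#' identical_cfg <- model_to_config(config_to_model(model_to_config(m)))
#' @export
model_to_config <- function(model) {
  stopifnot(inherits(model, "unfolding_model"))
  steps <- lapply(model$steps, function(s) {
    if (s$kind == "equilibrium") {
      p <- s$params
      c(list(kind = "equilibrium", tm_K = p$tm, dh_kJ = p$dh / 1e3,
             dcp_kJ = p$dcp / 1e3),
        if (!is.null(p$dh_vh)) list(dh_vh_kJ = p$dh_vh / 1e3))
    } else if (s$kind == "irreversible") {
      p <- s$params
      list(kind = "irreversible", e_kJ = p$e / 1e3, tf_K = p$tf,
           dh_kJ = p$dh / 1e3, dcp_kJ = p$dcp / 1e3)
    } else {
      list(kind = "two_rate", e_fwd_kJ = s$fwd$e / 1e3, tf_fwd_K = s$fwd$tf,
           e_rev_kJ = s$rev$e / 1e3, tf_rev_K = s$rev$tf,
           dh_kJ = s$fwd$dh / 1e3, dcp_kJ = s$fwd$dcp / 1e3)
    }
  })
  list(steps = steps,
       baseline = list(b0_kJ = model$b0 / 1e3, b1_kJ = model$b1 / 1e3))
}

#' @rdname model_to_config
#' @param config A list as produced by `model_to_config()` (or read from YAML).
#' @export
config_to_model <- function(config) {
  steps <- lapply(config$steps, function(s) {
    switch(s$kind,
      equilibrium = step_equilibrium(
        tm = s$tm_K, dh = s$dh_kJ * 1e3, dcp = (s$dcp_kJ %||% 0) * 1e3,
        dh_vh = if (!is.null(s$dh_vh_kJ)) s$dh_vh_kJ * 1e3),
      irreversible = step_irreversible(
        e = s$e_kJ * 1e3, tf = s$tf_K, dh = s$dh_kJ * 1e3,
        dcp = (s$dcp_kJ %||% 0) * 1e3),
      two_rate = step_two_rate(
        e_fwd = s$e_fwd_kJ * 1e3, tf_fwd = s$tf_fwd_K,
        e_rev = s$e_rev_kJ * 1e3, tf_rev = s$tf_rev_K,
        dh = s$dh_kJ * 1e3, dcp = (s$dcp_kJ %||% 0) * 1e3),
      abort(paste0("Unknown step kind: ", s$kind)))
  })
  b <- config$baseline %||% list()
  unfolding_model(steps, b0 = (b$b0_kJ %||% 0) * 1e3, b1 = (b$b1_kJ %||% 0) * 1e3)
}

#' @rdname model_to_config
#' @param program A [temperature_program()].
#' @export
program_to_config <- function(program) {
  lapply(seq_len(nrow(program)), function(i) list(
    start_C = program$t_start[i] - 273.15,
    end_C = program$t_end[i] - 273.15,
    rate_C_per_min = program$rate[i] * 60,
    role = program$role[i]))
}

#' @rdname model_to_config
#' @export
config_to_program <- function(config) {
  temperature_program(lapply(config, function(s) list(
    t_start = s$start_C + 273.15, t_end = s$end_C + 273.15,
    rate = s$rate_C_per_min / 60, role = s$role)))
}

#' @rdname model_to_config
#' @param path YAML file path.
#' @export
write_model_config <- function(model, path) {
  yaml::write_yaml(model_to_config(model), path, precision = 15)
  invisible(path)
}

#' @rdname model_to_config
#' @export
read_model_config <- function(path) {
  config_to_model(yaml::read_yaml(path))
}
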