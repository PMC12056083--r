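#' Steady-state classification rule
#'
#' Steady states are labeled by the activation of a readout node:
#' pro-anabolic when `readout >= threshold` (boundary inclusive),
#' pro-catabolic otherwise.
#'
#' @param readout readout node name. Default `"ACAN"`.
#' @param threshold classification threshold in (0, 1). Default 0.5.
#' @return an object of class `classification_rule`.
#' @export
classification_rule <- function(readout = "ACAN", threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  structure(list(readout = readout, threshold = threshold),
            class = "classification_rule")
}

#' Classify a steady state
#'
#' @param state named numeric state vector.
#' @param rule a [classification_rule()].
#' @return `"pro-anabolic"` or `"pro-catabolic"`.
#' @export
classify_state <- function(state, rule = classification_rule()) {
  if (!rule$readout %in% names(state)) {
    stop("readout node '", rule$readout, "' not present in state")
  }
  if (state[[rule$readout]] >= rule$threshold) "pro-anabolic" else "pro-catabolic"
}

#' Condition preset
#'
#' A named experimental condition encoded as a set of sustained clamps:
#' mechanoreceptor clamps represent the loading regime, a `TNF = 1` clamp
#' represents pro-inflammatory stimulation.
#'
#' @param name preset name, e.g. `"lit_TNF_dynamic"`.
#' @param derivation `"literature"` or `"experiment"` (how the clamp set was
#'   derived).
#' @param treatment `"control"` or `"TNF"`.
#' @param loading `"day0"`, `"unloaded"` or `"dynamic"`.
#' @param clamps named numeric vector of clamp values in \[0,1\].
#' @return an object of class `condition_preset`.
#' @export
condition_preset <- function(name, derivation, treatment, loading, clamps) {
  derivation <- match.arg(derivation, c("literature", "experiment"))
  treatment <- match.arg(treatment, c("control", "TNF"))
  loading <- match.arg(loading, c("day0", "unloaded", "dynamic"))
  clamps <- unlist(clamps)
  if (length(clamps) && any(clamps < 0 | clamps > 1)) {
    stop("clamp values must lie in [0, 1]")
  }
  structure(list(name = name, derivation = derivation, treatment = treatment,
                 loading = loading, clamps = clamps),
            class = "condition_preset")
}

#' Built-in condition presets
#'
#' The ten standard clamp sets: for each derivation (literature- or
#' experiment-derived mechanoreceptor activation) a day-0 baseline plus the
#' four culture conditions (control/TNF crossed with unloaded/dynamic).
#' Literature-derived presets clamp the mechanosensors a5b1, avb3 and TRPV4
#' (0.5 = free swelling, 1 = activated by dynamic compression); the
#' experiment-derived presets instead encode the observed lack of
#' mechanotransduction: `Actin = 0` (no cytoskeletal engagement),
#' `IL4 = 0.2585` (the critical IL-4 level), reduced TRPV4 under TNF, and
#' identical clamps for unloaded and dynamic loading. TNF stimulation is
#' `TNF = 1` in either derivation.
#'
#' @return named list of [condition_preset()] objects.
#' @export
builtin_presets <- function() {
  lit_base <- c(a5b1 = 0.5, avb3 = 0.5, TRPV4 = 0.5)
  lit_dyn <- c(a5b1 = 1, avb3 = 1, TRPV4 = 1)
  exp_base <- function(trpv4, tnf = NULL) {
    cl <- c(a5b1 = 0.5, TRPV4 = trpv4, Actin = 0, IL4 = 0.2585)
    if (!is.null(tnf)) cl <- c(cl, TNF = tnf)
    cl
  }
  p <- list(
    condition_preset("lit_day0", "literature", "control", "day0", lit_base),
    condition_preset("lit_control_unloaded", "literature", "control",
                     "unloaded", lit_base),
    condition_preset("lit_control_dynamic", "literature", "control",
                     "dynamic", lit_dyn),
    condition_preset("lit_TNF_unloaded", "literature", "TNF", "unloaded",
                     c(lit_base, TNF = 1)),
    condition_preset("lit_TNF_dynamic", "literature", "TNF", "dynamic",
                     c(lit_dyn, TNF = 1)),
    condition_preset("exp_day0", "experiment", "control", "day0",
                     exp_base(1)),
    condition_preset("exp_control_unloaded", "experiment", "control",
                     "unloaded", exp_base(0.5)),
    # dynamic clamps identical to unloaded: mechanotransduction was absent
    condition_preset("exp_control_dynamic", "experiment", "control",
                     "dynamic", exp_base(0.5)),
    condition_preset("exp_TNF_unloaded", "experiment", "TNF", "unloaded",
                     exp_base(0.25, tnf = 1)),
    condition_preset("exp_TNF_dynamic", "experiment", "TNF", "dynamic",
                     exp_base(0.25, tnf = 1))
  )
  stats::setNames(p, vapply(p, `[[`, "", "name"))
}

#' Condition label of a preset
#'
#' Maps a preset to its experimental-condition vocabulary entry
#' (`"control_unloaded"`, `"control_dynamic"`, `"TNF_unloaded"`,
#' `"TNF_dynamic"` or `"day0"`), dropping the derivation prefix.
#'
#' @param preset a [condition_preset()].
#' @return character condition label.
#' @export
preset_condition <- function(preset) {
  if (preset$loading == "day0") return("day0")
  paste(preset$treatment, preset$loading, sep = "_")
}
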