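#' The Lake Pavin spring-bloom food-web models
#'
#' Two steady-state carbon-flow models of the Lake Pavin (Massif Central,
#' France) pelagic food web during the spring 2007 diatom bloom, packaged as
#' plain-text model files: `"mwc"`, the model with parasitic chytrid fungi
#' (11 compartments, 53 flows, sporangia `spg` and zoospores `zsp`
#' included), and `"mwoc"`, the same web without the chytrid compartments
#' (9 compartments, 44 flows). Measured equalities fix total gross primary
#' production (360.54), total net primary production (245.17), net bacterial
#' production (90) and viral lysis of bacteria (9.90), all in mg C m-2 d-1.
#' The inequality set combines the constraints documented for the original
#' study (chytrid respiration at most 20% of carbon uptake, zoospore
#' ingestion by microzooplankton at least twice that by mesozooplankton,
#' bounded gross-primary-production size-fraction shares, minimum
#' nanoflagellate bacterivory) with generic planktonic physiological ranges;
#' the published mean-flow vectors are feasible under it.
#'
#' @param which `"mwc"` or `"mwoc"`.
#' @return `pavin_model()`: a `fw_model`. `pavin_flows()`: the published
#'   mean flow vector (named numeric, mg C m-2 d-1). `pavin_model_file()`:
#'   path to the installed model file.
#' @examples
#' spec <- pavin_model("mwc")
#' x <- pavin_flows("mwc")
#' max(abs(flow_residuals(spec, x)))  # printed-rounding residuals only
#' @export
pavin_model <- function(which = c("mwc", "mwoc")) {
  which <- match.arg(which)
  read_model(pavin_model_file(which))
}

#' @rdname pavin_model
#' @export
pavin_model_file <- function(which = c("mwc", "mwoc")) {
  which <- match.arg(which)
  system.file("extdata", paste0("pavin_", which, ".lim"),
              package = "limnet", mustWork = TRUE)
}

#' @rdname pavin_model
#' @export
pavin_flows <- function(which = c("mwc", "mwoc")) {
  which <- match.arg(which)
  read_flows(system.file("extdata", paste0("pavin_", which, "_flows.csv"),
                         package = "limnet", mustWork = TRUE),
             spec = pavin_model(which))
}
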