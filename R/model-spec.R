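#' Construct a food-web model specification
#'
#' A `fw_model` bundles everything that defines one steady-state carbon-flow
#' inverse problem: the compartments, the flow topology, the linear equality
#' constraints (mass balances plus measured flows) and the linear inequality
#' constraints (ecological bounds). Flow values are in mg C m-2 d-1
#' throughout.
#'
#' Flows connect compartments to each other or to the outside. The outside is
#' represented by three reserved tokens: `"gpp"` as the virtual source of
#' import flows (gross primary production), `"res"` as the sink of
#' dissipation (respiration) flows, and `"los"` as the sink of export flows
#' (sinking, harvest by unmodeled predators).
#'
#' @param name model name (single string).
#' @param compartments data.frame with columns `id`, `kind`
#'   (`"living"`/`"nonliving"`) and optionally `label`.
#' @param flows data.frame with columns `id`, `source`, `target` and
#'   optionally `role` (one of `"internal"`, `"import"`, `"export"`,
#'   `"dissipation"`; inferred from source/target when absent).
#' @param equalities,inequalities lists of constraints as returned by
#'   [linear_constraint()]. Mass-balance equalities (one per compartment,
#'   inflows minus outflows = 0) are generated automatically and need not be
#'   supplied.
#' @return an object of class `fw_model`.
#' @seealso [parse_model()], [assemble_system()], [pavin_model()]
#' @export
fw_model <- function(name, compartments, flows,
                     equalities = list(), inequalities = list()) {
  compartments <- as.data.frame(compartments, stringsAsFactors = FALSE)
  flows <- as.data.frame(flows, stringsAsFactors = FALSE)
  if (is.null(compartments$label)) compartments$label <- compartments$id
  if (is.null(flows$role)) flows$role <- NA_character_
  flows$role <- ifelse(is.na(flows$role), infer_role(flows), flows$role)
  spec <- structure(
    list(name = name, compartments = compartments, flows = flows,
         equalities = equalities, inequalities = inequalities),
    class = "fw_model")
  spec$equalities <- c(mass_balance_equalities(spec),
                       Filter(function(e) e$origin != "mass_balance",
                              equalities))
  validate_model(spec)
  spec
}

# role of a flow from its endpoints; the reserved endpoint tokens win
infer_role <- function(flows) {
  role <- rep("internal", nrow(flows))
  role[flows$source == "gpp"] <- "import"
  role[flows$target == "res"] <- "dissipation"
  role[flows$target == "los"] <- "export"
  role
}

#' Build one linear constraint on flows
#'
#' @param coefficients named numeric vector: signed weight per flow id.
#' @param rhs right-hand side value.
#' @param origin for equalities, `"mass_balance"` or `"measurement"`.
#' @param note free-text provenance.
#' @return a list with class `fw_constraint`.
#' @export
linear_constraint <- function(coefficients, rhs, origin = "measurement",
                              note = "") {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            length(rhs) == 1L)
  structure(list(coefficients = coefficients, rhs = rhs,
                 origin = origin, note = note),
            class = "fw_constraint")
}

# one inflow-minus-outflow = 0 equality per compartment, from the topology
mass_balance_equalities <- function(spec) {
  lapply(spec$compartments$id, function(cid) {
    cin <- spec$flows$id[spec$flows$target == cid]
    cout <- spec$flows$id[spec$flows$source == cid]
    coef <- c(stats::setNames(rep(1, length(cin)), cin),
              stats::setNames(rep(-1, length(cout)), cout))
    linear_constraint(coef, 0, origin = "mass_balance",
                      note = paste("mass balance for", cid))
  })
}

#' Validate a food-web model specification
#'
#' Checks id uniqueness, cross-references of flows against compartments and
#' of constraints against flows, reserved-token usage and role consistency.
#' Errors name the offending token.
#'
#' @param spec a `fw_model`.
#' @return `spec`, invisibly, if valid.
#' @export
validate_model <- function(spec) {
  comps <- spec$compartments
  flows <- spec$flows
  if (anyDuplicated(comps$id))
    stop("duplicate compartment id: ",
         comps$id[duplicated(comps$id)][1], call. = FALSE)
  bad_kind <- setdiff(unique(comps$kind), c("living", "nonliving"))
  if (length(bad_kind))
    stop("unknown compartment kind: ", bad_kind[1], call. = FALSE)
  if (anyDuplicated(flows$id))
    stop("duplicate flow id: ", flows$id[duplicated(flows$id)][1],
         call. = FALSE)
  known_src <- c(comps$id, "gpp")
  known_tgt <- c(comps$id, "res", "los")
  bad <- setdiff(flows$source, known_src)
  if (length(bad))
    stop("flow source references unknown compartment: ", bad[1],
         call. = FALSE)
  bad <- setdiff(flows$target, known_tgt)
  if (length(bad))
    stop("flow target references unknown compartment: ", bad[1],
         call. = FALSE)
  want <- infer_role(flows)
  if (any(flows$role != want))
    stop("flow role inconsistent with endpoints: ",
         flows$id[flows$role != want][1], call. = FALSE)
  for (con in c(spec$equalities, spec$inequalities)) {
    bad <- setdiff(names(con$coefficients), flows$id)
    if (length(bad))
      stop("constraint references unknown flow: ", bad[1], call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.fw_model <- function(x, ...) {
  n_mb <- sum(vapply(x$equalities, function(e) e$origin == "mass_balance",
                     logical(1)))
  cat("Food-web LIM model '", x$name, "'\n", sep = "")
  cat("  compartments:", nrow(x$compartments),
      sprintf("(%d living, %d nonliving)",
              sum(x$compartments$kind == "living"),
              sum(x$compartments$kind == "nonliving")), "\n")
  cat("  flows:       ", nrow(x$flows), "\n")
  cat("  equalities:  ", length(x$equalities),
      sprintf("(%d mass balance, %d measured)", n_mb,
              length(x$equalities) - n_mb), "\n")
  cat("  inequalities:", length(x$inequalities), "\n")
  invisible(x)
}

#' Living and nonliving compartment ids of a model
#' @param spec a `fw_model`.
#' @return character vector of compartment ids.
#' @export
living_compartments <- function(spec)
  spec$compartments$id[spec$compartments$kind == "living"]

#' @rdname living_compartments
#' @export
nonliving_compartments <- function(spec)
  spec$compartments$id[spec$compartments$kind == "nonliving"]

#' Primary producers: living compartments receiving an import flow
#' @param spec a `fw_model`.
#' @return character vector of compartment ids.
#' @export
primary_producers <- function(spec) {
  imp <- unique(spec$flows$target[spec$flows$role == "import"])
  intersect(living_compartments(spec), imp)
}
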