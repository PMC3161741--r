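#' Assemble the matrix form of a food-web LIM problem
#'
#' Builds `E x = f` (one mass-balance row per compartment followed by the
#' measured-flow equalities) and `G x >= h` (declared inequalities followed
#' by nonnegativity bounds `x_i >= 0` for every flow). Column order is the
#' flow declaration order; assembly is deterministic.
#'
#' @param spec a `fw_model`.
#' @return an object of class `fw_system`: list with `flow_order`, `E`, `f`,
#'   `G`, `h` and row annotations `eq_note`, `iq_note`.
#' @export
assemble_system <- function(spec) {
  ids <- spec$flows$id
  n <- length(ids)
  row_of <- function(con) {
    r <- numeric(n)
    r[match(names(con$coefficients), ids)] <- con$coefficients
    r
  }
  E <- do.call(rbind, lapply(spec$equalities, row_of))
  f <- vapply(spec$equalities, function(e) e$rhs, numeric(1))
  nn <- diag(n)  # x >= 0 box rows
  G <- rbind(do.call(rbind, c(lapply(spec$inequalities, row_of), list(nn))))
  if (!length(spec$inequalities)) G <- nn
  h <- c(vapply(spec$inequalities, function(e) e$rhs, numeric(1)), numeric(n))
  colnames(E) <- colnames(G) <- ids
  structure(list(
    flow_order = ids, E = E, f = f, G = G, h = h,
    eq_note = vapply(spec$equalities, function(e)
      if (nzchar(e$note)) e$note else e$origin, character(1)),
    iq_note = c(vapply(spec$inequalities, function(e)
      if (nzchar(e$note)) e$note else "inequality", character(1)),
      paste0(ids, " >= 0"))),
    class = "fw_system")
}

#' @export
print.fw_system <- function(x, ...) {
  cat("Food-web linear system:", length(x$flow_order), "flows,",
      nrow(x$E), "equalities,", nrow(x$G), "inequalities (incl. x >= 0)\n")
  invisible(x)
}

#' Mass-balance residuals of a flow vector
#'
#' For each compartment, the residual is the sum of its inflows minus the
#' sum of its outflows, evaluated exactly on the given values. At steady
#' state every residual is zero; vectors of printed (rounded) means carry
#' residuals up to the rounding error.
#'
#' @param spec a `fw_model`.
#' @param x named flow vector keyed on the model's flow ids.
#' @return named numeric vector of residuals (mg C m-2 d-1), one per
#'   compartment.
#' @export
flow_residuals <- function(spec, x) {
  x <- match_flows(spec, x)
  vapply(spec$compartments$id, function(cid) {
    sum(x[spec$flows$id[spec$flows$target == cid]]) -
      sum(x[spec$flows$id[spec$flows$source == cid]])
  }, numeric(1))
}

#' Check a flow vector against a model's inequality constraints
#'
#' @param spec a `fw_model`.
#' @param x named flow vector.
#' @param tol relative tolerance: a row `g.x >= h` passes when
#'   `g.x >= h - tol * max(|h|, 1)`. Nonnegativity of every flow is checked
#'   as well.
#' @return data.frame of violated constraints (columns `note`, `value`,
#'   `rhs`); zero rows when all constraints hold.
#' @export
check_constraints <- function(spec, x, tol = 0) {
  x <- match_flows(spec, x)
  sys <- assemble_system(spec)
  gx <- drop(sys$G %*% x)
  slack <- tol * pmax(abs(sys$h), 1)
  bad <- which(gx < sys$h - slack)
  data.frame(note = sys$iq_note[bad], value = gx[bad], rhs = sys$h[bad],
             row.names = NULL)
}

#' Compartment throughputs of a flow vector
#'
#' The throughput of a compartment is the total carbon passing through it;
#' at steady state inflows equal outflows, and the outflow sum is used.
#'
#' @inheritParams flow_residuals
#' @return named numeric vector, one entry per compartment.
#' @export
compartment_throughput <- function(spec, x) {
  x <- match_flows(spec, x)
  vapply(spec$compartments$id, function(cid)
    sum(x[spec$flows$id[spec$flows$source == cid]]), numeric(1))
}
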