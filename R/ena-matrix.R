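#' Extended flow matrix for Ecological Network Analysis
#'
#' Arranges a flow vector into the square matrix `T` over the model's
#' compartments augmented with three virtual nodes: an `import` row (gross
#' primary production entering producers), an `export` column (sinking and
#' predation by unmodeled higher trophic levels) and a `dissipation` column
#' (respiration). `T[i, j]` is the carbon flow from node `i` to node `j`
#' in mg C m-2 d-1.
#'
#' @param spec a `fw_model`.
#' @param x named flow vector keyed on the model's flows.
#' @return object of class `fw_flowmat`: list with `T` (matrix),
#'   `compartments`, `living`, `nonliving`, `virtual` node names.
#' @export
extend_matrix <- function(spec, x) {
  x <- match_flows(spec, x)
  if (any(x < 0))
    stop("negative flow value: ", names(x)[which(x < 0)[1]], call. = FALSE)
  comps <- spec$compartments$id
  virtual <- c("import", "export", "dissipation")
  nodes <- c(comps, virtual)
  T <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  src <- spec$flows$source
  tgt <- spec$flows$target
  src[src == "gpp"] <- "import"
  tgt[tgt == "los"] <- "export"
  tgt[tgt == "res"] <- "dissipation"
  for (k in seq_along(x)) T[src[k], tgt[k]] <- T[src[k], tgt[k]] + x[[k]]
  structure(list(T = T, compartments = comps,
                 living = living_compartments(spec),
                 nonliving = nonliving_compartments(spec),
                 virtual = virtual),
            class = "fw_flowmat")
}

#' @export
print.fw_flowmat <- function(x, ...) {
  cat("Extended flow matrix:", length(x$compartments),
      "compartments + 3 virtual nodes, TST =",
      format(sum(x$T), digits = 6), "\n")
  invisible(x)
}

#' Export an extended flow matrix in SCOR text format
#'
#' A minimal SCOR-style listing (compartment count, names, then one line
#' per flow `i j value` with 0 for imports and negative codes for
#' export/dissipation rows following the legacy convention of network
#' analysis programs), for cross-checking against legacy ENA software.
#'
#' @param fm a `fw_flowmat`.
#' @param path output path.
#' @param title header line.
#' @return `path`, invisibly.
#' @export
write_scor <- function(fm, path, title = "food web") {
  comps <- fm$compartments
  n <- length(comps)
  idx <- stats::setNames(seq_len(n), comps)
  lines <- c(title, sprintf("%d %d", n, length(fm$living)), comps)
  add <- function(i, j, v) sprintf("%d %d %.6f", i, j, v)
  out <- character(0)
  for (cp in comps) {
    v <- fm$T["import", cp]
    if (v > 0) out <- c(out, add(0L, idx[[cp]], v))
  }
  for (a in comps) for (b in comps) {
    v <- fm$T[a, b]
    if (v > 0) out <- c(out, add(idx[[a]], idx[[b]], v))
  }
  for (cp in comps) {
    v <- fm$T[cp, "export"]
    if (v > 0) out <- c(out, add(idx[[cp]], -1L, v))
    v <- fm$T[cp, "dissipation"]
    if (v > 0) out <- c(out, add(idx[[cp]], -2L, v))
  }
  writeLines(c(lines, out, "-1"), path)
  invisible(path)
}
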