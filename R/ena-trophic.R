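# Lindeman trophic aggregation: maps the flow network onto a linear chain
# of integer trophic levels. Nonliving pools (detritus, DOC) and primary
# producers are assigned wholly to level 1; every other living compartment
# is apportioned across levels by powers of its diet-fraction matrix, so a
# consumer eating 60% detritus and 40% herbivores is 60% at level 2 and
# 40% at level 3.

# apportionment matrix L[node, level]: fraction of the node's intake
# arriving at each integer trophic level. `sources` are pinned at level 1;
# `diet` is the column-normalized input matrix among compartments (+import).
trophic_apportionment <- function(fm, sources, max_level = 8L,
                                  residual_tol = 1e-9,
                                  exclude_nonliving_diet = FALSE) {
  comps <- fm$compartments
  Tc <- fm$T[comps, comps, drop = FALSE]
  imp <- fm$T["import", comps]
  if (exclude_nonliving_diet) Tc[fm$nonliving, ] <- 0
  intake <- colSums(Tc) + imp
  d <- sweep(Tc, 2L, ifelse(intake > 0, intake, 1), "/")
  L <- matrix(0, length(comps), max_level,
              dimnames = list(comps, NULL))
  pinned <- comps %in% sources
  L[pinned, 1L] <- 1
  L[!pinned, 1L] <- (imp / ifelse(intake > 0, intake, 1))[!pinned]
  for (k in 2:max_level) {
    L[!pinned, k] <- drop(crossprod(d[, !pinned, drop = FALSE], L[, k - 1L]))
    if (sum(L[, k]) < residual_tol) break
  }
  L
}

#' Lindeman spine: trophic aggregation of a flow network
#'
#' Apportions every flow to integer trophic levels (primary producers and
#' nonliving pools at level 1) and reports, per level, the carbon input,
#' the transfer efficiency to the next level, the grazing-chain efficiency
#' (same aggregation restricted to carbon of primary-producer origin, the
#' detrital pathway excluded), the logarithmic-mean global efficiency over
#' the first `n_eff` levels, and the detritivory/herbivory split.
#'
#' Conventions: the input to level 1 is the total import plus the detrital
#' returns, i.e. flows into nonliving pools weighted by the donor's
#' above-level-1 fraction (producer exudation and pool-to-pool transfers
#' circulate within level 1 and are not new input); the input to level
#' k > 1 is every flow into a living compartment weighted by the donor's
#' apportionment to level k - 1. Detritivory is the carbon flowing
#' from nonliving pools into living compartments; herbivory the carbon from
#' primary producers into living consumers (a parasitism flow off a
#' producer counts as herbivory); the two are reported as percentages of
#' their sum.
#'
#' @param spec a `fw_model`.
#' @param x named flow vector (or a `fw_flowmat` via `fm`).
#' @param max_level truncation level of the apportionment.
#' @param n_eff number of level efficiencies entering the global
#'   (logarithmic mean) efficiency.
#' @return object of class `lindeman_spine`: list with `tl_inputs`,
#'   `tl_efficiency` (%), `global_efficiency` (%),
#'   `grazing_chain_efficiency` (%), `detritivory_pct`, `herbivory_pct`.
#' @export
lindeman_spine <- function(spec, x, max_level = 8L, n_eff = 4L) {
  fm <- extend_matrix(spec, x)
  comps <- fm$compartments
  living <- fm$living
  nonliving <- fm$nonliving
  producers <- primary_producers(spec)
  if (!length(producers))
    stop("no primary producer (living compartment with an import flow) ",
         "identified", call. = FALSE)
  other <- setdiff(comps, union(nonliving, living))
  if (length(other))
    stop("unclassifiable compartment: ", other[1], call. = FALSE)
  Tc <- fm$T[comps, comps, drop = FALSE]
  imports <- sum(fm$T["import", ])

  level_inputs <- function(L, to_living_only_from = comps, first_level) {
    Tin <- Tc[to_living_only_from, living, drop = FALSE]
    ins <- numeric(ncol(L))
    ins[1L] <- first_level
    for (k in 2:ncol(L))
      ins[k] <- sum(Tin * L[to_living_only_from, k - 1L])
    ins
  }

  # full spine: producers and nonliving pools pinned at level 1. The input
  # to level 1 is the import plus the detrital returns, where a flow into a
  # nonliving pool counts as a return only for the donor's above-level-1
  # fraction: producer exudation and detritus dissolution circulate within
  # level 1 and are not new level-1 input.
  L <- trophic_apportionment(fm, sources = union(producers, nonliving),
                             max_level = max_level)
  returns <- sum(Tc[, nonliving, drop = FALSE] * (1 - L[, 1L]))
  ins <- level_inputs(L, comps, imports + returns)
  eff <- 100 * ifelse(ins[-length(ins)] > 0,
                      ins[-1L] / ins[-length(ins)], 0)
  # grazing chain: producer-origin carbon only
  Lg <- trophic_apportionment(fm, sources = producers,
                              max_level = max_level,
                              exclude_nonliving_diet = TRUE)
  ins_g <- level_inputs(Lg, living, imports)
  eff_g <- 100 * ifelse(ins_g[-length(ins_g)] > 0,
                        ins_g[-1L] / ins_g[-length(ins_g)], 0)

  D <- sum(Tc[nonliving, living])
  H <- sum(Tc[producers, setdiff(living, producers), drop = FALSE])
  dh <- D + H
  use <- seq_len(min(n_eff, length(eff)))
  pos <- eff[use][eff[use] > 0]
  structure(list(
    tl_inputs = ins,
    tl_efficiency = eff,
    global_efficiency = if (length(pos)) exp(mean(log(pos))) else 0,
    grazing_chain_efficiency = eff_g,
    detritivory_pct = if (dh > 0) 100 * D / dh else 0,
    herbivory_pct = if (dh > 0) 100 * H / dh else 0),
    class = "lindeman_spine")
}

#' @export
print.lindeman_spine <- function(x, ...) {
  k <- seq_len(min(4L, length(x$tl_efficiency)))
  cat("Lindeman spine\n")
  cat("  TL efficiency (%):     ",
      paste(sprintf("%d: %.1f", k, x$tl_efficiency[k]), collapse = "  "),
      "\n")
  cat("  grazing chain (%):     ",
      paste(sprintf("%d: %.1f", k, x$grazing_chain_efficiency[k]),
            collapse = "  "), "\n")
  cat(sprintf("  global efficiency: %.1f%%\n", x$global_efficiency))
  cat(sprintf("  detritivory / herbivory: %.1f%% / %.1f%%\n",
              x$detritivory_pct, x$herbivory_pct))
  invisible(x)
}

#' Diet and fate fractions of each compartment
#'
#' For every compartment, each input flow as a percentage of its total
#' inputs (its diet) and each output flow as a percentage of its throughput
#' (the fate of its production).
#'
#' @param spec a `fw_model`.
#' @param x named flow vector.
#' @return data.frame with columns `compartment`, `direction`
#'   (`"in"`/`"out"`), `flow_id`, `partner`, `value`, `pct`.
#' @export
flow_percentages <- function(spec, x) {
  x <- match_flows(spec, x)
  fl <- spec$flows
  out <- list()
  for (cid in spec$compartments$id) {
    fin <- fl[fl$target == cid, ]
    fout <- fl[fl$source == cid, ]
    tin <- sum(x[fin$id]); tout <- sum(x[fout$id])
    if (tin <= 0 && tout <= 0)
      stop("zero-throughput compartment: ", cid, call. = FALSE)
    if (nrow(fin) && tin > 0)
      out[[length(out) + 1L]] <- data.frame(
        compartment = cid, direction = "in", flow_id = fin$id,
        partner = fin$source, value = unname(x[fin$id]),
        pct = 100 * unname(x[fin$id]) / tin)
    if (nrow(fout) && tout > 0)
      out[[length(out) + 1L]] <- data.frame(
        compartment = cid, direction = "out", flow_id = fout$id,
        partner = fout$target, value = unname(x[fout$id]),
        pct = 100 * unname(x[fout$id]) / tout)
  }
  do.call(rbind, out)
}
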