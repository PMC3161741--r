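# Random LIM problem generator and brute-force oracles. The generated webs
# mirror the structural classes of plankton carbon-flow models: imports
# only into producer nodes, dissipation from every living node, one or two
# nonliving pools receiving egestion and feeding detritivores, so the
# trophic aggregation logic is exercised by construction.

#' Generate a random food-web LIM problem with a known interior point
#'
#' Builds a random connected topology of `n_compartments` (producers,
#' consumers and 1-2 nonliving pools), routes random positive carbon along
#' import-to-sink paths so that a strictly mass-balanced flow vector
#' `x_star` exists by construction, fixes the total import as a measurement
#' equality, and places box inequalities `x_star * (1 -/+ u)` with
#' `u ~ U(0.2, 0.8)` per flow, so `x_star` is strictly interior to the
#' polytope.
#'
#' @param n_compartments at least 2.
#' @param connectance fraction of the admissible predator-prey links that
#'   are realized, in (0, 1].
#' @param seed integer seed; the problem is a deterministic function of the
#'   arguments.
#' @param acyclic forbid feedback links (nonliving pools feeding
#'   consumers), guaranteeing an acyclic flow topology.
#' @return object of class `fw_synthetic`: list with `spec` (a
#'   `fw_model`), `x_star` (named flow vector), `dim` (polytope dimension),
#'   `seed`.
#' @export
random_lim <- function(n_compartments, connectance = 0.5, seed = 1L,
                       acyclic = FALSE) {
  stopifnot(n_compartments >= 2, connectance > 0, connectance <= 1)
  set.seed(seed)
  n_nl <- if (n_compartments >= 5) 2L else 1L
  n_nl <- min(n_nl, n_compartments - 1L)
  n_liv <- n_compartments - n_nl
  n_prod <- max(1L, ceiling(n_liv / 3))
  prod <- paste0("pp", seq_len(n_prod))
  cons <- if (n_liv > n_prod) paste0("cs", seq_len(n_liv - n_prod))
          else character(0)
  nl <- paste0("nl", seq_len(n_nl))
  comps <- data.frame(
    id = c(prod, cons, nl),
    kind = c(rep("living", n_liv), rep("nonliving", n_nl)),
    label = c(paste("producer", seq_len(n_prod)),
              if (length(cons)) paste("consumer", seq_along(cons)),
              paste("pool", seq_len(n_nl))))

  edges <- list()
  add <- function(s, t) edges[[length(edges) + 1L]] <<- c(s, t)
  for (p in prod) add("gpp", p)            # imports into producers only
  for (v in c(prod, cons)) add(v, "res")   # dissipation from every living
  for (v in nl) add(v, "los")              # pools export by sinking
  if (length(cons)) add(cons[length(cons)], "los")
  # trophic ordering producers < consumers; admissible feeding links
  ord <- c(prod, cons)
  admissible <- list()
  for (i in seq_along(ord)) for (j in seq_along(ord))
    if (i < j) admissible[[length(admissible) + 1L]] <- c(ord[i], ord[j])
  for (v in c(prod, cons)) admissible[[length(admissible) + 1L]] <-
    c(v, nl[1 + (match(v, ord) %% n_nl)])  # egestion to a pool
  if (!acyclic && length(cons))
    for (p in nl) admissible[[length(admissible) + 1L]] <-
      c(p, cons[1 + (match(p, nl) %% length(cons))])  # detritivory
  pick <- stats::runif(length(admissible)) <= connectance
  # keep the web connected and balanced: every producer must have an
  # outlet to a compartment or pool beyond respiration is optional, but
  # every consumer needs at least one food source and every pool a donor
  for (k in seq_along(admissible)) {
    e <- admissible[[k]]
    if (!pick[k]) {
      needs <- (e[2] %in% cons &&
                !any(vapply(admissible[pick], function(z) z[2] == e[2],
                            logical(1)))) ||
               (e[2] %in% nl &&
                !any(vapply(admissible[pick], function(z) z[2] == e[2],
                            logical(1))))
      if (needs) pick[k] <- TRUE
    }
  }
  # and every compartment must be reachable from the imports, or it could
  # carry no positive steady-state flow at all
  repeat {
    reached <- prod
    repeat {
      grow <- vapply(admissible[pick], function(z)
        z[1] %in% reached && !(z[2] %in% reached), logical(1))
      if (!any(grow)) break
      reached <- union(reached,
                       vapply(admissible[pick][grow], `[`, character(1), 2))
    }
    missing <- setdiff(comps$id, reached)
    if (!length(missing)) break
    fixable <- which(!pick & vapply(admissible, function(z)
      z[1] %in% reached && z[2] == missing[1], logical(1)))
    pick[fixable[1]] <- TRUE
  }
  for (e in admissible[pick]) add(e[1], e[2])
  em <- do.call(rbind, edges)
  ids <- paste0("C", em[, 1], "TO", em[, 2])
  flows <- data.frame(id = ids, source = em[, 1], target = em[, 2])

  # route random positive carbon along import -> ... -> sink walks; flow
  # conservation per walk makes x_star exactly mass balanced
  succ <- split(seq_len(nrow(flows)),
                factor(flows$source, levels = c(comps$id, "gpp")))
  x_star <- stats::setNames(numeric(nrow(flows)), ids)
  route <- function(k0, w) {
    k <- k0
    for (hop in 1:(4L * n_compartments)) {
      x_star[k] <<- x_star[k] + w
      tgt <- flows$target[k]
      if (tgt %in% c("res", "los")) return(invisible())
      nxt <- succ[[tgt]]
      # late in the walk, prefer terminal edges to guarantee exit
      term <- nxt[flows$target[nxt] %in% c("res", "los")]
      k <- if (hop >= 2L * n_compartments && length(term))
        term[sample.int(length(term), 1L)]
      else nxt[sample.int(length(nxt), 1L)]
    }
    stop("internal: routing walk failed to reach a sink", call. = FALSE)
  }
  imp_idx <- which(flows$source == "gpp")
  for (r in seq_len(10L * n_compartments))
    route(imp_idx[sample.int(length(imp_idx), 1L)], stats::runif(1, 1, 5))
  # ensure every edge carries flow: push one unit of carbon along a fixed
  # import -> edge -> sink path through each unused edge. Paths come from a
  # breadth-first tree, so the repair terminates even on cyclic webs.
  parent_edge <- rep(NA_integer_, length(comps$id))
  names(parent_edge) <- comps$id
  frontier <- "gpp"
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) for (k in which(flows$source == v)) {
      t <- flows$target[k]
      if (t %in% comps$id && is.na(parent_edge[[t]])) {
        parent_edge[[t]] <- k
        nxt <- c(nxt, t)
      }
    }
    frontier <- nxt
  }
  exit_edge <- vapply(comps$id, function(v) {
    ks <- which(flows$source == v)
    term <- ks[flows$target[ks] %in% c("res", "los")]
    if (length(term)) term[1] else ks[1]
  }, integer(1))
  for (k in seq_along(ids)) {
    if (x_star[k] > 0) next
    w <- stats::runif(1, 0.5, 2)
    v <- flows$source[k]          # feed the edge's source from an import
    while (v != "gpp") {
      pe <- parent_edge[[v]]
      x_star[pe] <- x_star[pe] + w
      v <- flows$source[pe]
    }
    x_star[k] <- x_star[k] + w    # drain the edge's target to a sink
    v <- flows$target[k]
    while (!v %in% c("res", "los")) {
      ee <- exit_edge[[v]]
      x_star[ee] <- x_star[ee] + w
      v <- flows$target[ee]
    }
  }

  spec <- fw_model(sprintf("synthetic_n%d_s%d", n_compartments, seed),
                   comps, flows)
  u <- stats::runif(length(ids), 0.2, 0.8)
  ineqs <- list()
  for (k in seq_along(ids)) {
    lo <- x_star[[k]] * (1 - u[k]); hi <- x_star[[k]] * (1 + u[k])
    ineqs[[length(ineqs) + 1L]] <- linear_constraint(
      stats::setNames(1, ids[k]), lo, note = paste0(ids[k], " >= lower"))
    ineqs[[length(ineqs) + 1L]] <- linear_constraint(
      stats::setNames(-1, ids[k]), -hi, note = paste0(ids[k], " <= upper"))
  }
  # measured total import pins the scale (and bounds the polytope)
  eqs <- list(linear_constraint(
    stats::setNames(rep(1, length(imp_idx)), ids[imp_idx]),
    sum(x_star[imp_idx]), note = "total import"))
  spec <- fw_model(spec$name, comps, flows, equalities = eqs,
                   inequalities = ineqs)
  sys <- assemble_system(spec)
  dim <- ncol(sys$E) - qr(sys$E)$rank
  structure(list(spec = spec, x_star = x_star, dim = dim, seed = seed),
            class = "fw_synthetic")
}

#' @export
print.fw_synthetic <- function(x, ...) {
  cat("Synthetic LIM problem '", x$spec$name, "': ",
      nrow(x$spec$flows), " flows, polytope dimension ", x$dim, "\n",
      sep = "")
  invisible(x)
}

#' Uniform rejection sampling of a flow polytope (oracle)
#'
#' Draws uniform points in the axis-aligned bounding box of the reduced
#' (null-space) polytope, found by per-coordinate linear programs, and
#' keeps those satisfying all constraints: exactly uniform by construction,
#' usable as an independent reference for the mirror walk on low-dimensional
#' problems.
#'
#' @param system a `fw_system` with polytope dimension at most 3.
#' @param n number of accepted samples to return.
#' @param seed RNG seed.
#' @param max_draws abort (with the acceptance-rate diagnostic) after this
#'   many proposals.
#' @return a `fw_ensemble` of `n` uniform samples.
#' @export
rejection_oracle <- function(system, n, seed = 1L, max_draws = 1e7) {
  red <- reduce_system(system)
  if (red$dim > 3L)
    stop("rejection oracle restricted to polytope dimension <= 3 (got ",
         red$dim, ")", call. = FALSE)
  cfg <- sampler_config(jump = Inf, n_iter = n, burn_in = 0L, seed = seed)
  if (red$dim == 0L) {
    x <- feasible_point(system)
    samples <- matrix(rep(x, each = n), nrow = n,
                      dimnames = list(NULL, system$flow_order))
    return(new_ensemble(samples, cfg, system))
  }
  V <- polytope_vertices(red$A, red$b)
  lo <- apply(V, 2L, min)
  hi <- apply(V, 2L, max)
  set.seed(seed)
  kept <- matrix(NA_real_, n, red$dim)
  got <- 0L; tried <- 0
  batch <- max(1000L, 4L * n)
  while (got < n) {
    Q <- matrix(stats::runif(batch * red$dim, lo, hi),
                ncol = red$dim, byrow = TRUE)
    S <- Q %*% t(red$A)
    ok <- rowSums(S >= matrix(red$b - 1e-12, batch, nrow(red$A),
                              byrow = TRUE)) == nrow(red$A)
    tried <- tried + batch
    take <- which(ok)
    if (length(take)) {
      take <- take[seq_len(min(length(take), n - got))]
      kept[got + seq_along(take), ] <- Q[take, , drop = FALSE]
      got <- got + length(take)
    }
    if (tried > max_draws && got / tried < 1e-6)
      stop("rejection oracle acceptance rate below 1e-6 (", got, "/",
           tried, " accepted)", call. = FALSE)
  }
  samples <- kept %*% t(red$Z) +
    matrix(red$xp, n, length(red$xp), byrow = TRUE)
  colnames(samples) <- system$flow_order
  new_ensemble(samples, cfg, system)
}

# exact vertex enumeration of the low-dimensional polytope {A q >= b}:
# every vertex is the solution of d active constraint rows; feasible
# solutions of all d-subsets are collected (practical for d <= 3)
polytope_vertices <- function(A, b, tol = 1e-9) {
  d <- ncol(A)
  norms <- sqrt(rowSums(A^2)); keep <- norms > 0
  An <- A[keep, , drop = FALSE] / norms[keep]
  bn <- b[keep] / norms[keep]
  scale <- max(1, max(abs(bn)))
  verts <- list()
  for (idx in utils::combn(nrow(An), d, simplify = FALSE)) {
    M <- An[idx, , drop = FALSE]
    q <- tryCatch(solve(M, bn[idx]), error = function(e) NULL)
    if (is.null(q)) next
    if (all(An %*% q >= bn - tol * scale))
      verts[[length(verts) + 1L]] <- q
  }
  if (!length(verts))
    stop("vertex enumeration found no feasible vertex (empty or ",
         "unbounded polytope?)", call. = FALSE)
  do.call(rbind, verts)
}

#' Toy networks with analytically known index values
#'
#' Small flow networks whose ENA indices follow from hand evaluation,
#' packaged for use as test oracles: `"single"` (a single import flow, the
#' degenerate one-entry matrix: AMI = 0, FCI = 0, gross-variant APL = 1),
#' `"chain3"` (import -> A -> B -> export with
#' all three flows equal: AMI = log2(3)), `"cycle2"` (a two-compartment
#' loop with FCI = 0.4 by the 2x2 Leontief inverse), and `"detweb"` (a
#' producer-detritus web whose detritivory fraction is 25/(25+60) by
#' direct summation).
#'
#' @return named list; each element has `spec`, `x` and `expected` (a
#'   named list of exact index values).
#' @export
toy_networks <- function() {
  mk <- function(name, comps, flows, x, expected) {
    spec <- fw_model(name,
                     data.frame(id = comps$id, kind = comps$kind),
                     flows)
    list(spec = spec, x = x, expected = expected)
  }
  out <- list()
  out$single <- mk(
    "single",
    data.frame(id = "a", kind = "living"),
    data.frame(id = "CgppTOa", source = "gpp", target = "a"),
    c(CgppTOa = 5),
    list(AMI = 0, FCI = 0, APL_gross = 1, TST = 5))
  out$chain3 <- mk(
    "chain3",
    data.frame(id = c("a", "b"), kind = "living"),
    data.frame(id = c("CgppTOa", "CaTOb", "CbTOlos"),
               source = c("gpp", "a", "b"), target = c("a", "b", "los")),
    c(CgppTOa = 2, CaTOb = 2, CbTOlos = 2),
    list(AMI = log2(3), FCI = 0))
  out$cycle2 <- mk(
    "cycle2",
    data.frame(id = c("a", "b"), kind = "living"),
    data.frame(id = c("CgppTOa", "CaTOb", "CbTOa", "CbTOlos"),
               source = c("gpp", "a", "b", "b"),
               target = c("a", "b", "a", "los")),
    c(CgppTOa = 1, CaTOb = 2, CbTOa = 1, CbTOlos = 1),
    list(FCI = 0.4, TST = 5))
  out$detweb <- mk(
    "detweb",
    data.frame(id = c("pp", "cs", "nl"),
               kind = c("living", "living", "nonliving")),
    data.frame(id = c("CgppTOpp", "CppTOcs", "CppTOnl", "CnlTOcs",
                      "CcsTOnl", "CcsTOres", "CnlTOlos"),
               source = c("gpp", "pp", "pp", "nl", "cs", "cs", "nl"),
               target = c("pp", "cs", "nl", "cs", "nl", "res", "los")),
    c(CgppTOpp = 100, CppTOcs = 60, CppTOnl = 40, CnlTOcs = 25,
      CcsTOnl = 15, CcsTOres = 70, CnlTOlos = 30),
    list(detritivory_pct = 100 * 25 / 85, herbivory_pct = 100 * 60 / 85))
  out
}
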