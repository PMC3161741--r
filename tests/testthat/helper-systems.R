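# Shared constructors for small hand-built systems used across test files.

# a bare fw_system without going through a model spec
raw_system <- function(E, f, G, h, ids = NULL) {
  n <- if (!is.null(E)) ncol(E) else ncol(G)
  if (is.null(ids)) ids <- paste0("x", seq_len(n))
  structure(list(flow_order = ids,
                 E = E, f = f, G = G, h = h,
                 eq_note = if (!is.null(E)) paste0("eq", seq_len(nrow(E)))
                           else character(0),
                 iq_note = paste0("iq", seq_len(nrow(G)))),
            class = "fw_system")
}

# {x1 + x2 + x3 = 1, x >= 0}: the 2-simplex
simplex_system <- function() {
  raw_system(E = matrix(1, 1, 3), f = 1, G = diag(3), h = rep(0, 3))
}

# one flow bounded to [0, 10], no equalities
segment_system <- function() {
  raw_system(E = matrix(0, 0, 1), f = numeric(0),
             G = matrix(c(1, -1), 2, 1), h = c(0, -10))
}

# minimal parsable model: one compartment, one import, one export
tiny_model_text <- function() {
  c("NAME tiny",
    "COMPARTMENTS", "a living",
    "FLOWS",
    "CgppTOa: gpp -> a [import]",
    "CaTOlos: a -> los [export]",
    "EQUALITIES", "CONSTRAINTS")
}

# draw a short feasible chain on a system and return the ensemble
quick_chain <- function(sys, n_iter = 2000, jump = 1, seed = 1,
                        burn_in = 200) {
  mirror_mcmc(sys, feasible_point(sys),
              sampler_config(jump = jump, n_iter = n_iter,
                             burn_in = burn_in, seed = seed))
}

# batch-means Monte Carlo standard error for an autocorrelated chain
mc_se <- function(v, n_batch = 50) {
  nb <- max(10, n_batch)
  m <- floor(length(v) / nb)
  bm <- vapply(seq_len(nb), function(i) mean(v[((i - 1) * m + 1):(i * m)]),
               numeric(1))
  stats::sd(bm) / sqrt(nb)
}
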