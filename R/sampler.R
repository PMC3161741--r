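#' Sampler configuration
#'
#' @param jump step-length scale of the mirror random walk: the standard
#'   deviation, per reduced coordinate, of the isotropic Gaussian proposal
#'   (flow units, mg C m-2 d-1). The reference analysis used 10.
#' @param n_iter number of retained iterations (reference analysis:
#'   100,000).
#' @param burn_in initial iterations discarded before retention.
#' @param thin keep every `thin`-th post-burn-in state.
#' @param seed integer RNG seed; the chain is reproducible given
#'   `(system, x0, config)`.
#' @return a list of class `fw_sampler_config`.
#' @export
sampler_config <- function(jump = 10, n_iter = 100000L, burn_in = 1000L,
                           thin = 1L, seed = 1L) {
  stopifnot(jump > 0, n_iter >= 1, burn_in >= 0, thin >= 1)
  structure(list(jump = jump, n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "fw_sampler_config")
}

# Reduced-space geometry of E x = f, G x >= h:
#   x = xp + Z q with Z an orthonormal null-space basis of E, so the
#   equalities hold exactly by construction; inequalities become A q >= b.
reduce_system <- function(system, tol = 1e-9) {
  E <- system$E; f <- system$f
  n <- length(system$flow_order)
  if (is.null(E) || nrow(E) == 0L) {
    xp <- numeric(n)
    Z <- diag(n)
  } else {
    sv <- svd(E, nu = nrow(E), nv = n)
    pos <- which(sv$d > tol * max(sv$d, 1))
    r <- length(pos)
    # minimum-norm particular solution via pseudo-inverse
    xp <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% f) / sv$d[pos])
    xp <- drop(xp)
    if (max(abs(E %*% xp - f)) > 1e-7 * max(1, max(abs(f))))
      stop("equality system is inconsistent (no exact solution)",
           call. = FALSE)
    Z <- sv$v[, -seq_len(r), drop = FALSE]
    if (r == n) Z <- matrix(0, n, 0)
  }
  A <- system$G %*% Z
  b <- system$h - drop(system$G %*% xp)
  list(xp = xp, Z = Z, A = A, b = b, dim = ncol(Z))
}

#' Find a feasible flow vector of a constrained linear system
#'
#' Computes a deep-interior point of the inequality polytope within the
#' equality manifold: the equalities hold exactly (null-space
#' parameterization), and the minimum normalized constraint slack is
#' maximized by Agmon-Motzkin relaxation followed by smooth (log-sum-exp
#' softmin) maximization, so the point is strictly interior whenever the
#' polytope has positive volume. Deterministic given the system.
#'
#' @param system a `fw_system` from [assemble_system()].
#' @return named feasible flow vector.
#' @seealso [mirror_mcmc()]
#' @export
feasible_point <- function(system) {
  red <- reduce_system(system)
  if (red$dim == 0L) {
    viol <- which(drop(system$G %*% red$xp) < system$h - 1e-9)
    if (length(viol))
      stop("infeasible system: equalities force a point violating ",
           "constraint rows {", paste(viol, collapse = ", "), "}: ",
           paste(utils::head(system$iq_note[viol], 3), collapse = "; "),
           call. = FALSE)
    return(stats::setNames(red$xp, system$flow_order))
  }
  q <- deep_interior_point(red$A, red$b)
  slack <- drop(red$A %*% q) - red$b
  if (min(slack) < -1e-8 * max(1, max(abs(red$b)))) {
    viol <- which(slack < -1e-9)
    stop("infeasible system: no point satisfies constraint rows {",
         paste(utils::head(viol, 6), collapse = ", "), "}: ",
         paste(utils::head(system$iq_note[viol], 3), collapse = "; "),
         call. = FALSE)
  }
  x <- drop(red$xp + red$Z %*% q)
  stats::setNames(x, system$flow_order)
}

# maximize the minimum normalized slack min_i (a_i.q - b_i)/||a_i||:
# Motzkin relaxation to (near) feasibility, then BFGS on the smooth
# softmin surrogate with an increasing sharpness schedule
deep_interior_point <- function(A, b) {
  norms <- sqrt(rowSums(A^2)); norms[norms == 0] <- 1
  An <- A / norms; bn <- b / norms
  q <- motzkin_point(An, bn)
  scale <- max(1, stats::median(abs(bn)))
  for (beta in c(1, 4, 16, 64, 256) / scale) {
    obj <- function(q) {
      s <- drop(An %*% q) - bn
      m <- min(s)
      -(m - log(sum(exp(-beta * (s - m)))) / beta)
    }
    grd <- function(q) {
      s <- drop(An %*% q) - bn
      w <- exp(-beta * (s - min(s)))
      -drop(crossprod(An, w / sum(w)))
    }
    opt <- stats::optim(q, obj, grd, method = "BFGS",
                        control = list(maxit = 400, reltol = 1e-12))
    q <- opt$par
  }
  q
}

# Agmon-Motzkin successive over-relaxation onto violated half-spaces
# (rows assumed normalized)
motzkin_point <- function(An, bn, iter = 20000L, lambda = 1.5) {
  q <- numeric(ncol(An))
  for (k in seq_len(iter)) {
    viol <- bn - drop(An %*% q)
    i <- which.max(viol)
    if (viol[i] <= 1e-12) break
    q <- q + lambda * viol[i] * An[i, ]
  }
  q
}

#' Mirror Markov chain Monte Carlo over the feasible flow polytope
#'
#' Uniform sampling of `{x : E x = f, G x >= h}` by a reflecting random
#' walk. The walk lives in the null-space coordinates of the equality
#' matrix, so every state satisfies the equalities exactly. Each step is an
#' isotropic Gaussian displacement with standard deviation `config$jump`;
#' the displacement segment is traced through the inequality hyperplanes
#' and specularly reflected ("mirrored") at each crossing until the step
#' length is exhausted, so every state is feasible and the uniform
#' distribution over the polytope is preserved.
#'
#' @param system a `fw_system`.
#' @param x0 feasible starting flow vector (e.g. from [feasible_point()]).
#'   It is first projected exactly onto the equality manifold; it must then
#'   satisfy the inequalities to tolerance `1e-8`.
#' @param config a [sampler_config()].
#' @param bounce_cap maximum reflections within one step before aborting
#'   with a geometry diagnostic.
#' @return object of class `fw_ensemble`: list with `flow_order`, `samples`
#'   (`n_iter` x n_flows matrix), `config`, `model_name`.
#' @export
mirror_mcmc <- function(system, x0, config = sampler_config(),
                        bounce_cap = 1000L) {
  red <- reduce_system(system)
  x0 <- match_order(x0, system$flow_order)
  n_keep <- config$n_iter
  if (red$dim == 0L) {
    x <- feasible_point(system)  # errors if the forced point is infeasible
    samples <- matrix(rep(x, each = n_keep), nrow = n_keep,
                      dimnames = list(NULL, system$flow_order))
    return(new_ensemble(samples, config, system))
  }
  q <- drop(crossprod(red$Z, x0 - red$xp))
  slack0 <- drop(red$A %*% q) - red$b
  if (min(slack0) < -1e-8 * max(1, max(abs(red$b))))
    stop("x0 is not feasible for the system (constraint slack ",
         format(min(slack0)), ")", call. = FALSE)
  A <- red$A; b <- red$b
  nrm2 <- rowSums(A^2)
  active <- nrm2 > 0
  d <- red$dim
  set.seed(config$seed)
  total <- config$burn_in + n_keep * config$thin
  keep <- matrix(NA_real_, n_keep, d)
  ki <- 0L
  for (it in seq_len(total)) {
    s <- stats::rnorm(d, sd = config$jump)
    remaining <- 1
    bounces <- 0L
    Aq <- drop(A %*% q)
    while (remaining > 1e-12) {
      As <- drop(A %*% s)
      # first crossing along q + t*s, t in (0, remaining]
      cand <- which(active & As < 0)
      tc <- (b[cand] - Aq[cand]) / As[cand]
      tc[tc < 0] <- 0   # numerically on/just outside a face we move along
      hit <- which(tc < remaining)
      if (!length(hit)) {
        q <- q + remaining * s
        Aq <- Aq + remaining * As
        break
      }
      j <- hit[which.min(tc[hit])]
      tstar <- tc[j]
      i <- cand[j]
      q <- q + tstar * s
      Aq <- Aq + tstar * As
      s <- s - 2 * sum(A[i, ] * s) / nrm2[i] * A[i, ]
      remaining <- remaining - tstar
      bounces <- bounces + 1L
      if (bounces > bounce_cap)
        stop("reflection did not terminate within ", bounce_cap,
             " bounces: degenerate polytope geometry (near-tangential or ",
             "duplicated constraint faces)", call. = FALSE)
    }
    if (it > config$burn_in &&
        (it - config$burn_in) %% config$thin == 0L) {
      ki <- ki + 1L
      keep[ki, ] <- q
    }
  }
  samples <- keep %*% t(red$Z) +
    matrix(red$xp, n_keep, length(red$xp), byrow = TRUE)
  colnames(samples) <- system$flow_order
  new_ensemble(samples, config, system)
}

match_order <- function(x, ids) {
  if (is.null(names(x))) {
    stopifnot(length(x) == length(ids))
    return(stats::setNames(as.numeric(x), ids))
  }
  miss <- setdiff(ids, names(x))
  if (length(miss)) stop("flow vector missing flow: ", miss[1], call. = FALSE)
  as.numeric(x[ids])
}

new_ensemble <- function(samples, config, system, model_name = "model") {
  structure(list(flow_order = colnames(samples), samples = samples,
                 config = config, model_name = model_name),
            class = "fw_ensemble")
}

#' @export
print.fw_ensemble <- function(x, ...) {
  cat("Flow-polytope sample ensemble:", nrow(x$samples), "samples x",
      ncol(x$samples), "flows (jump", x$config$jump,
      ", seed", x$config$seed, ")\n")
  invisible(x)
}

#' Per-flow summary of a sample ensemble
#'
#' @param e a `fw_ensemble`.
#' @param probs quantile probabilities; the defaults are the 0.5% and 99.5%
#'   bounds used to report flow ranges.
#' @return data.frame with one row per flow: mean, sd and the requested
#'   quantiles.
#' @export
ensemble_summary <- function(e, probs = c(0.005, 0.995)) {
  s <- e$samples
  if (nrow(s) < 200L)
    stop("ensemble_summary needs at least 200 retained samples",
         call. = FALSE)
  qs <- t(apply(s, 2L, stats::quantile, probs = probs, names = FALSE))
  out <- data.frame(flow_id = colnames(s), mean = colMeans(s),
                    sd = apply(s, 2L, stats::sd), row.names = NULL)
  for (i in seq_along(probs))
    out[[sprintf("q%03.0f", 1000 * probs[i])]] <- qs[, i]
  out
}

#' Write / read a sample ensemble as CSV plus JSON sidecar
#'
#' The CSV has one column per flow and one row per retained sample; the
#' sidecar records the sampler configuration, the model name and an MD5
#' checksum of the sample matrix file.
#'
#' @param e a `fw_ensemble`.
#' @param path CSV output path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(e, path) {
  utils::write.csv(as.data.frame(e$samples), path, row.names = FALSE,
                   quote = FALSE)
  meta <- list(model_name = e$model_name,
               config = unclass(e$config),
               n_samples = nrow(e$samples),
               csv_md5 = unname(tools::md5sum(path)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!nrow(df) || !all(vapply(df, is.numeric, logical(1))))
    stop("malformed ensemble CSV: ", path, call. = FALSE)
  sidecar <- paste0(path, ".json")
  config <- sampler_config()
  model_name <- "model"
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    config <- do.call(sampler_config, meta$config[
      c("jump", "n_iter", "burn_in", "thin", "seed")])
    model_name <- meta$model_name
  }
  structure(list(flow_order = names(df), samples = as.matrix(df),
                 config = config, model_name = model_name),
            class = "fw_ensemble")
}
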