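# Information-theoretic and cycling indices over an extended flow matrix.
# All logarithms are base 2, so AMI and the entropy underlying DC are in
# bits; products with TST (A, DC, overheads) are in mg C m-2 d-1 (times
# bits, reported in flow units as is conventional).

#' Total system throughput
#'
#' The sum of every flow in the extended matrix: imports, all
#' compartment-to-compartment exchanges, exports and dissipations. A
#' measure of total system activity.
#'
#' @param fm a `fw_flowmat` from [extend_matrix()].
#' @return TST in mg C m-2 d-1.
#' @export
total_system_throughput <- function(fm) sum(fm$T)

# sum over nonzero entries of w * log2 terms, with 0 log 0 = 0
.xlog2 <- function(num, den) {
  ok <- num > 0 & den > 0
  out <- numeric(length(num))
  out[ok] <- log2(num[ok] / den[ok])
  out
}

# AMI, A, DC and the four-way overhead partition for an arbitrary flow
# matrix with marginals taken on that matrix
info_core <- function(T) {
  tot <- sum(T)
  ri <- rowSums(T); cj <- colSums(T)
  W <- T / tot
  RC <- outer(ri, cj)
  ami_terms <- W * .xlog2(T * tot, RC)
  dc_terms <- -W * .xlog2(T, tot * matrix(1, nrow(T), ncol(T)))
  ov_terms <- -W * .xlog2(T * T, RC)
  list(tot = tot, AMI = sum(ami_terms), DC = tot * sum(dc_terms),
       ov = tot * ov_terms)
}

#' Information indices of a flow network
#'
#' Average mutual information `AMI = sum_ij (Tij/T..) log2(Tij T.. /
#' (Ti. T.j))` over nonzero entries; ascendency `A = TST * AMI`;
#' development capacity `DC = -sum_ij Tij log2(Tij / T..)`; and the
#' overhead `DC - A` partitioned by flow class into import overhead `Oi`,
#' export overhead `Oe`, dissipative overhead `Od` and internal redundancy
#' `R`, so that `A + Oi + Oe + Od + R = DC` holds to machine precision.
#'
#' @param fm a `fw_flowmat`.
#' @return named list with `AMI` (bits), `A`, `DC`, `Oi`, `Oe`, `Od`, `R`.
#' @export
information_indices <- function(fm) {
  T <- fm$T
  if (sum(T) <= 0) stop("zero-throughput network", call. = FALSE)
  core <- info_core(T)
  comps <- fm$compartments
  ov <- core$ov
  Oi <- sum(ov["import", ])
  Oe <- sum(ov[comps, "export"])
  Od <- sum(ov[comps, "dissipation"])
  R <- sum(ov[comps, comps])
  list(AMI = core$AMI, A = core$tot * core$AMI, DC = core$DC,
       Oi = Oi, Oe = Oe, Od = Od, R = R)
}

#' Internal information indices
#'
#' The same information quantities restricted to the
#' compartment-to-compartment submatrix (imports, exports and dissipations
#' excluded), with marginals taken on that submatrix: internal ascendency
#' `Ai`, internal development capacity `DCi` and internal redundancy
#' `Ri = DCi - Ai`.
#'
#' @param fm a `fw_flowmat`.
#' @return named list with `Ai`, `DCi`, `Ri`.
#' @export
internal_information_indices <- function(fm) {
  Ti <- fm$T[fm$compartments, fm$compartments, drop = FALSE]
  if (sum(Ti) <= 0)  # pass-through network: all internal quantities vanish
    return(list(Ai = 0, DCi = 0, Ri = 0))
  core <- info_core(Ti)
  Ai <- core$tot * core$AMI
  list(Ai = Ai, DCi = core$DC, Ri = core$DC - Ai)
}

#' Finn cycling index
#'
#' Fraction of total system throughput involved in cycles. With `G` the
#' output-normalized transfer matrix among compartments
#' (`Gij = Tij / Ti.`, `Ti.` the full throughput of `i` including exports
#' and dissipation) and `N = (I - G)^-1` the Leontief inverse, the cycled
#' throughput of compartment `j` is `Tj. (Njj - 1) / Njj` and
#' `FCI = sum_j cycled_j / TST`.
#'
#' @param fm a `fw_flowmat`.
#' @return FCI in `[0, 1)`.
#' @export
finn_cycling_index <- function(fm) {
  tst <- sum(fm$T)
  if (tst <= 0) stop("zero-throughput network", call. = FALSE)
  comps <- fm$compartments
  Trow <- rowSums(fm$T)[comps]
  Ti <- fm$T[comps, comps, drop = FALSE]
  G <- Ti / ifelse(Trow > 0, Trow, 1)
  IG <- diag(length(comps)) - G
  if (abs(det(IG)) < 1e-12)
    stop("singular (I - G): the network contains a lossless absorbing ",
         "cycle", call. = FALSE)
  N <- solve(IG)
  cycled <- Trow * (diag(N) - 1) / diag(N)
  sum(cycled) / tst
}

#' Average path length
#'
#' The mean number of compartments crossed by a unit of carbon between its
#' entry into and exit from the system: `APL = (TST - Z) / Z` with `Z` the
#' total import. The variant `TST / Z` (which counts the entry step) is
#' available via `variant = "gross"`.
#'
#' @param fm a `fw_flowmat`.
#' @param variant `"net"` (default) or `"gross"`.
#' @return APL (dimensionless).
#' @export
average_path_length <- function(fm, variant = c("net", "gross")) {
  variant <- match.arg(variant)
  Z <- sum(fm$T["import", ])
  if (Z <= 0) stop("network has no import", call. = FALSE)
  tst <- sum(fm$T)
  if (variant == "net") (tst - Z) / Z else tst / Z
}

#' All scalar ENA indices of one flow vector
#'
#' Convenience wrapper computing the full index set used to characterize a
#' food web: TST, AMI, ascendency and development capacity with the
#' overhead partition, the internal variants, the derived ratios, the Finn
#' cycling index and the average path length.
#'
#' @param spec a `fw_model`.
#' @param x named flow vector.
#' @param apl_variant passed to [average_path_length()].
#' @return named list of class `ena_indices` with elements `TST`, `AMI`,
#'   `A`, `DC`, `Oi`, `Oe`, `Od`, `R`, `Ai`, `DCi`, `Ri`, `A_over_DC`,
#'   `Ai_over_DCi`, `R_over_DC`, `Ri_over_DCi`, `FCI`, `APL`.
#' @examples
#' idx <- ena_indices(pavin_model("mwc"), pavin_flows("mwc"))
#' round(idx$TST)   # total activity of the web with chytrids
#' round(idx$AMI, 2)
#' @export
ena_indices <- function(spec, x, apl_variant = "net") {
  fm <- extend_matrix(spec, x)
  tst <- total_system_throughput(fm)
  ii <- information_indices(fm)
  int <- internal_information_indices(fm)
  rat <- function(n, d) if (d > 0) n / d else NA_real_  # degenerate webs
  structure(c(list(TST = tst), ii, int,
              list(A_over_DC = rat(ii$A, ii$DC),
                   Ai_over_DCi = rat(int$Ai, int$DCi),
                   R_over_DC = rat(ii$R, ii$DC),
                   Ri_over_DCi = rat(int$Ri, int$DCi),
                   FCI = finn_cycling_index(fm),
                   APL = average_path_length(fm, apl_variant))),
            class = "ena_indices")
}

#' @export
print.ena_indices <- function(x, ...) {
  v <- unlist(x)
  cat("ENA indices:\n")
  print(round(v, 4))
  invisible(x)
}
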