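test_that("a minimal model parses with auto-generated mass balance", {
  spec <- parse_model(tiny_model_text())
  expect_s3_class(spec, "fw_model")
  expect_equal(nrow(spec$flows), 2L)
  expect_length(spec$equalities, 1L)
  expect_equal(spec$equalities[[1]]$origin, "mass_balance")
  expect_equal(sort(spec$flows$role), c("export", "import"))
})

test_that("parse errors name the offending token", {
  dup <- c("NAME m", "COMPARTMENTS", "a living", "FLOWS",
           "Cph3TOmic: gpp -> a [import]",
           "Cph3TOmic: a -> los [export]",
           "EQUALITIES", "CONSTRAINTS")
  expect_error(parse_model(dup), "duplicate flow id: Cph3TOmic")
  badcomp <- c("NAME m", "COMPARTMENTS", "a living", "FLOWS",
               "CaTOb: a -> b [internal]", "EQUALITIES", "CONSTRAINTS")
  expect_error(parse_model(badcomp), "unknown compartment: b")
  badflow <- c(tiny_model_text()[1:6], "CONSTRAINTS", "Cnope >= 1")
  expect_error(parse_model(badflow), "unknown flow: Cnope")
  badkind <- c("NAME m", "COMPARTMENTS", "a sentient", "FLOWS",
               "CgppTOa: gpp -> a [import]", "EQUALITIES", "CONSTRAINTS")
  expect_error(parse_model(badkind), "unknown compartment kind: sentient")
})

test_that("packaged Pavin models have the documented structure", {
  mwc <- pavin_model("mwc")
  mwoc <- pavin_model("mwoc")
  expect_equal(nrow(mwc$flows), 53L)
  expect_equal(nrow(mwoc$flows), 44L)
  n_mb <- function(s) sum(vapply(s$equalities, function(e)
    e$origin == "mass_balance", logical(1)))
  expect_equal(n_mb(mwc), 11L)   # one per compartment
  expect_equal(n_mb(mwoc), 9L)   # spg, zsp absent
  expect_equal(length(mwc$equalities) - n_mb(mwc), 4L)
  expect_equal(length(mwoc$equalities) - n_mb(mwoc), 4L)
  # every compartment appears in at least one mass-balance equality
  for (s in list(mwc, mwoc)) {
    touched <- unique(unlist(lapply(s$equalities, function(e)
      names(e$coefficients))))
    expect_true(all(s$flows$id[s$flows$role == "internal"] %in% touched))
  }
})

test_that("model files round-trip through the writer", {
  for (which in c("mwc", "mwoc")) {
    spec <- pavin_model(which)
    spec2 <- parse_model(write_model(spec))
    expect_identical(spec2$flows, spec$flows)
    expect_identical(spec2$compartments, spec$compartments)
    expect_equal(length(spec2$inequalities), length(spec$inequalities))
    s1 <- assemble_system(spec); s2 <- assemble_system(spec2)
    expect_equal(s2$E, s1$E)
    expect_equal(s2$f, s1$f)
    expect_equal(s2$G, s1$G)
    expect_equal(s2$h, s1$h)
  }
})

test_that("system assembly has deterministic documented shape", {
  mwc <- pavin_model("mwc")
  sys <- assemble_system(mwc)
  expect_equal(dim(sys$E), c(15L, 53L))      # 11 mass balance + 4 measured
  expect_equal(ncol(sys$G), 53L)
  expect_equal(nrow(sys$G), length(mwc$inequalities) + 53L)  # + x >= 0
  expect_identical(sys$flow_order, mwc$flows$id)
  sys2 <- assemble_system(parse_model(write_model(mwc)))
  expect_equal(sys2$E, sys$E)
  # measured rows carry the in-situ values
  meas <- which(!grepl("mass balance", sys$eq_note))
  expect_equal(sort(sys$f[meas]), sort(c(360.54, 245.17, 90, 9.90)))
})

test_that("a one-compartment pass-through assembles to [1, -1] x = 0", {
  spec <- parse_model(tiny_model_text())
  sys <- assemble_system(spec)
  expect_equal(unname(sys$E), matrix(c(1, -1), 1, 2))
  expect_equal(sys$f, 0)
})

test_that("mass-balance residuals of the published mean flows are rounding-sized", {
  mwc <- pavin_model("mwc")
  x <- pavin_flows("mwc")
  r <- flow_residuals(mwc, x)
  # hand sum for heterotrophic nanoflagellates:
  # (25.85 + 61.59) - (29.25 + 23.10 + 14.41 + 10.27 + 10.39) = 0.02
  expect_equal(unname(r["hnf"]), 0.02, tolerance = 1e-9)
  expect_lte(max(abs(r)), 0.31)
  # residual below 0.7% of each compartment's throughput
  thr <- compartment_throughput(mwc, x)
  expect_true(all(abs(r) <= 0.007 * thr))
  mwoc <- pavin_model("mwoc")
  r2 <- flow_residuals(mwoc, pavin_flows("mwoc"))
  expect_true(all(abs(r2) <= 0.007 * compartment_throughput(mwoc,
                                                            pavin_flows("mwoc"))))
  # all-zero vector balances trivially
  z <- stats::setNames(numeric(53), mwc$flows$id)
  expect_true(all(flow_residuals(mwc, z) == 0))
  expect_error(flow_residuals(mwc, x[-1]), "missing flow")
})

test_that("published mean flows satisfy the measured equalities", {
  x <- pavin_flows("mwc")
  gpp <- x["CgppTOph1"] + x["CgppTOph2"] + x["CgppTOph3"]
  expect_equal(unname(gpp), 360.54, tolerance = 0.01 / 360.54)
  npp <- gpp - x["Cph1TOres"] - x["Cph2TOres"] - x["Cph3TOres"]
  expect_lte(abs(npp - 245.17), 0.02)
  expect_lte(abs(x[["CdocTObac"]] - x[["CbacTOres"]] - 90), 0.01)
  expect_identical(x[["CbacTOdoc"]], 9.9)
})

test_that("published mean flows are feasible under the packaged constraints", {
  for (which in c("mwc", "mwoc")) {
    spec <- pavin_model(which)
    v <- check_constraints(spec, pavin_flows(which), tol = 0)
    expect_identical(nrow(v), 0L)
  }
})

test_that("constraint violations are detected and named", {
  spec <- pavin_model("mwc")
  x <- pavin_flows("mwc")
  # sporangia respiring half their carbon uptake breaks the 20% cap
  x["CspgTOres"] <- 0.5 * x[["Cph3TOspg"]]
  v <- check_constraints(spec, x, tol = 0)
  expect_true(any(grepl("CspgTOres", v$note)))
  # equal zoospore ingestion violates the 2:1 mic:mes preference
  x2 <- pavin_flows("mwc")
  x2["CzspTOmic"] <- x2[["CzspTOmes"]]
  v2 <- check_constraints(spec, x2, tol = 0)
  expect_true(any(grepl("CzspTOmic - 2\\*CzspTOmes", v2$note)))
  # a relative tolerance forgives a marginal violation
  x3 <- pavin_flows("mwc")
  x3["CbacTOhnf"] <- 49.9    # bound is >= 50
  expect_gt(nrow(check_constraints(spec, x3, tol = 0)), 0)
  expect_identical(nrow(check_constraints(spec, x3, tol = 0.01)), 0L)
})

test_that("flow vectors round-trip through CSV", {
  x <- pavin_flows("mwoc")
  p <- withr::local_tempfile(fileext = ".csv")
  write_flows(x, p)
  expect_equal(read_flows(p, spec = pavin_model("mwoc")), x)
  expect_error(read_flows(withr::local_tempfile(), ), "not found")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_flows(bad), "malformed")
})
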