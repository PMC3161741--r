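test_that("toy networks reproduce their hand-computed indices exactly", {
  ty <- toy_networks()
  # one import flow: a single-entry matrix carries no information
  s <- ty$single
  fm <- extend_matrix(s$spec, s$x)
  expect_equal(information_indices(fm)$AMI, 0, tolerance = 1e-12)
  expect_equal(finn_cycling_index(fm), 0, tolerance = 1e-12)
  expect_equal(average_path_length(fm, "gross"), 1, tolerance = 1e-12)
  # three equal flows in a chain: AMI = log2(3)
  c3 <- ty$chain3
  expect_equal(information_indices(extend_matrix(c3$spec, c3$x))$AMI,
               log2(3), tolerance = 1e-12)
  # two-node cycle: FCI = 0.4 by the 2x2 Leontief inverse
  cy <- ty$cycle2
  expect_equal(finn_cycling_index(extend_matrix(cy$spec, cy$x)), 0.4,
               tolerance = 1e-12)
  # producers-plus-detritus web: detritivory by direct flow summation
  dw <- ty$detweb
  sp <- lindeman_spine(dw$spec, dw$x)
  expect_equal(sp$detritivory_pct, dw$expected$detritivory_pct,
               tolerance = 1e-12)
  expect_equal(sp$detritivory_pct + sp$herbivory_pct, 100)
})

test_that("the extended matrix places flows by class", {
  spec <- pavin_model("mwc")
  fm <- extend_matrix(spec, pavin_flows("mwc"))
  expect_equal(fm$T["ph3", "spg"], 57.44)      # parasitism is an internal flow
  expect_equal(sum(fm$T["import", ]), 360.54, tolerance = 0.01 / 360)
  expect_equal(sum(fm$T[, "dissipation"]),
               sum(pavin_flows("mwc")[grepl("TOres$", names(pavin_flows("mwc")))]))
  expect_true(all(fm$T[fm$virtual, "import"] == 0))  # no virtual self-flows
  # an all-zero vector extends to an all-zero matrix
  z <- stats::setNames(numeric(53), spec$flows$id)
  expect_true(all(extend_matrix(spec, z)$T == 0))
  expect_error(information_indices(extend_matrix(spec, z)),
               "zero-throughput")
  zneg <- z; zneg[1] <- -1
  expect_error(extend_matrix(spec, zneg), "negative flow")
})

test_that("information indices partition and scale correctly", {
  for (s in 1:20) {
    pb <- random_lim(sample(3:9, 1), stats::runif(1, 0.3, 1), seed = s)
    fm <- extend_matrix(pb$spec, pb$x_star)
    ii <- information_indices(fm)
    tst <- total_system_throughput(fm)
    expect_equal(ii$A + ii$Oi + ii$Oe + ii$Od + ii$R, ii$DC,
                 tolerance = 1e-9)
    expect_gte(ii$AMI, 0)
    expect_lte(ii$AMI, ii$DC / tst + 1e-12)
    # TST is linear and AMI scale-invariant
    fm2 <- extend_matrix(pb$spec, 3 * pb$x_star)
    expect_equal(total_system_throughput(fm2), 3 * tst, tolerance = 1e-12)
    expect_equal(information_indices(fm2)$AMI, ii$AMI, tolerance = 1e-10)
    fci <- finn_cycling_index(fm)
    expect_gte(fci, 0)
    expect_lt(fci, 1)
    # internal partition
    int <- internal_information_indices(fm)
    expect_equal(int$Ai + int$Ri, int$DCi, tolerance = 1e-9 * max(1, int$DCi))
  }
})

test_that("acyclic topologies have zero cycling", {
  for (s in 1:10) {
    pb <- random_lim(sample(3:8, 1), stats::runif(1, 0.3, 1), seed = s,
                     acyclic = TRUE)
    expect_equal(finn_cycling_index(extend_matrix(pb$spec, pb$x_star)), 0,
                 tolerance = 1e-12)
  }
})

test_that("a chain with no parallel paths has zero redundancy", {
  ty <- toy_networks()
  fm <- extend_matrix(ty$chain3$spec, ty$chain3$x)
  expect_equal(internal_information_indices(fm)$Ri, 0, tolerance = 1e-12)
})

test_that("average path length behaves as a residence measure", {
  spec <- pavin_model("mwc")
  x <- pavin_flows("mwc")
  fm <- extend_matrix(spec, x)
  expect_equal(average_path_length(fm), (sum(fm$T) - 360.54) / 360.54,
               tolerance = 1e-6)
  expect_equal(average_path_length(fm), 3.06, tolerance = 0.01 / 3)
  # scale invariance
  fm2 <- extend_matrix(spec, 2 * x)
  expect_equal(average_path_length(fm2), average_path_length(fm),
               tolerance = 1e-12)
  # a single pass-through compartment is crossed exactly once
  tiny <- parse_model(tiny_model_text())
  fmt <- extend_matrix(tiny, c(CgppTOa = 5, CaTOlos = 5))
  expect_equal(average_path_length(fmt), 1, tolerance = 1e-12)
})

test_that("the Lindeman spine reproduces the published trophic summary", {
  sp_mwc <- lindeman_spine(pavin_model("mwc"), pavin_flows("mwc"))
  sp_mwoc <- lindeman_spine(pavin_model("mwoc"), pavin_flows("mwoc"))
  expect_equal(sp_mwc$detritivory_pct, 55.7, tolerance = 0.2 / 55.7)
  expect_equal(sp_mwc$herbivory_pct, 44.3, tolerance = 0.2 / 44.3)
  expect_equal(sp_mwoc$detritivory_pct, 67.3, tolerance = 0.2 / 67.3)
  expect_equal(sp_mwoc$herbivory_pct, 32.7, tolerance = 0.2 / 32.7)
  expect_equal(sp_mwc$detritivory_pct + sp_mwc$herbivory_pct, 100)
  # per-level transfer efficiencies and the logarithmic-mean global
  # efficiency, levels 1-4
  expect_equal(sp_mwc$tl_efficiency[1:4], c(66.4, 48.0, 41.9, 30.5),
               tolerance = 0.15 / 30)
  expect_equal(sp_mwoc$tl_efficiency[1:4], c(53.9, 42.3, 30.8, 22.9),
               tolerance = 0.15 / 22)
  expect_equal(sp_mwc$global_efficiency, 44.9, tolerance = 0.15 / 44.9)
  expect_equal(sp_mwoc$global_efficiency, 35.6, tolerance = 0.15 / 35.6)
  # the web with parasites transfers carbon better at every level
  expect_true(all(sp_mwc$tl_efficiency[1:4] > sp_mwoc$tl_efficiency[1:4]))
  expect_true(all(sp_mwc$grazing_chain_efficiency[1:4] >
                    sp_mwoc$grazing_chain_efficiency[1:4]))
})

test_that("a producers-only network has zero detritivory", {
  spec <- fw_model("prod",
                   data.frame(id = c("pp", "cs"), kind = "living"),
                   data.frame(id = c("CgppTOpp", "CppTOcs", "CcsTOres",
                                     "CppTOres"),
                              source = c("gpp", "pp", "cs", "pp"),
                              target = c("pp", "cs", "res", "res")))
  sp <- lindeman_spine(spec, c(CgppTOpp = 10, CppTOcs = 6, CcsTOres = 6,
                               CppTOres = 4))
  expect_equal(sp$detritivory_pct, 0)
  expect_equal(sp$herbivory_pct, 100)
})

test_that("diet and fate fractions reproduce the published percentages", {
  spec <- pavin_model("mwc")
  x <- pavin_flows("mwc")
  fp <- flow_percentages(spec, x)
  para <- fp[fp$flow_id == "Cph3TOspg" & fp$direction == "out", ]
  expect_equal(para$pct, 21.4, tolerance = 0.5 / 21.4)
  zsp_diet <- fp[fp$flow_id == "CzspTOmic" & fp$direction == "in", ]
  expect_equal(zsp_diet$compartment, "mic")
  expect_equal(zsp_diet$pct, 38, tolerance = 0.5 / 38)
  # a compartment with a single input gets 100% of its diet from it
  tiny <- parse_model(tiny_model_text())
  fpt <- flow_percentages(tiny, c(CgppTOa = 5, CaTOlos = 5))
  expect_equal(fpt$pct[fpt$direction == "in"], 100)
  z <- stats::setNames(numeric(53), spec$flows$id)
  expect_error(flow_percentages(spec, z), "zero-throughput")
})

test_that("SCOR export lists every positive flow once", {
  spec <- pavin_model("mwoc")
  fm <- extend_matrix(spec, pavin_flows("mwoc"))
  p <- withr::local_tempfile(fileext = ".scor")
  write_scor(fm, p, title = "pavin mwoc")
  lines <- readLines(p)
  expect_identical(lines[1], "pavin mwoc")
  expect_identical(lines[2], "9 7")
  body <- lines[seq(12, length(lines) - 1)]
  expect_length(body, sum(fm$T > 0))
})
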