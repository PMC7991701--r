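fixture <- system.file("extdata", "vpatient_network.json",
                       package = "willisim")

test_that("shipped fixture loads, validates, and contains the full CoW", {
  net <- load_network(fixture)
  cow <- c("L_ICA", "R_ICA", "L_ACA_A1", "R_ACA_A1", "L_ACA_A2", "R_ACA_A2",
           "L_MCA", "R_MCA", "L_PCA_P1", "R_PCA_P1", "L_PCA_P2", "R_PCA_P2",
           "Acom", "L_Pcom", "R_Pcom", "BA", "L_VA", "R_VA",
           "L_ECA", "R_ECA", "L_CCA", "R_CCA")
  expect_true(all(cow %in% net$segments$id))
  expect_identical(anyDuplicated(net$segments$id), 0L)
  expect_true(all(net$terminals$kind %in% c("windkessel",
                                            "autoregulating_bed")))
})

test_that("fixture round-trips losslessly through write_network", {
  net <- load_network(fixture)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_network(net, tmp)
  net2 <- load_network(tmp)
  expect_equal(net2$segments, net$segments)
  expect_equal(net2$terminals, net$terminals)
  expect_equal(net2$junctions, net$junctions)
  expect_equal(net2$blood, net$blood)
  expect_equal(net2$inflow, net$inflow)
})

test_that("validation names the offending record for broken networks", {
  net <- load_network(fixture)
  dup <- net; dup$segments$id[2] <- dup$segments$id[1]
  expect_error(validate_network(dup), "duplicate segment id")
  neg <- net; neg$segments$length_cm[3] <- -1
  expect_error(validate_network(neg), neg$segments$id[3])
  # a segment attached at both ends to the same junction
  loop <- net
  loop$junctions[[1]]$attached[[2]] <- list(segment = "asc_aorta",
                                            end = "proximal")
  expect_error(validate_network(loop), "asc_aorta")
  # removing a communicating artery must be rejected (complete CoW)
  noacom <- net
  keep <- noacom$segments$id != "Acom"
  noacom$segments <- noacom$segments[keep, ]
  expect_error(validate_network(noacom), "Acom")
})

test_that("interventions are pure and bounds-checked", {
  net <- load_network(fixture)
  before <- net
  st <- apply_stenosis(net, list(segment = "R_ICA", start_offset_mm = 10,
                                 length_mm = 10, ratio = 0.7))
  expect_equal(nrow(st$stenoses), 1)
  expect_equal(net, before)          # input untouched
  cl <- apply_clamp(net, list(segment = "L_ICA", position_mm = 10))
  expect_equal(nrow(cl$clamps), 1)
  expect_equal(net, before)
  expect_error(apply_stenosis(net, list(segment = "R_ICA",
                                        start_offset_mm = 175,
                                        length_mm = 10, ratio = 0.5)),
               "beyond")
  expect_error(apply_clamp(net, list(segment = "L_ICA", position_mm = 999)),
               "inside")
  expect_error(apply_clamp(net, list(segment = "nope", position_mm = 1)),
               "unknown segment")
  # ratio 0 leaves the network identical (no element installed)
  expect_equal(apply_stenosis(net, list(segment = "R_ICA",
                                        start_offset_mm = 10,
                                        length_mm = 10, ratio = 0)), net)
})

test_that("clamping both ICAs and both VAs cuts off every cerebral outlet", {
  net <- load_network(fixture)
  for (s in c("L_ICA", "R_ICA", "L_VA", "R_VA")) {
    net <- apply_clamp(net, list(segment = s, position_mm = 5))
  }
  reach <- reachable_segments(net, cut_interventions = TRUE)
  cerebral <- c("L_MCA", "R_MCA", "L_ACA_A2", "R_ACA_A2",
                "L_PCA_P2", "R_PCA_P2", "Acom", "BA")
  expect_length(intersect(reach, cerebral), 0)
  # without treating the clamps as cuts everything is reachable
  expect_setequal(reachable_segments(net), net$segments$id)
})
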