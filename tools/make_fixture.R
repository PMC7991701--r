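# Generates the shipped virtual-patient fixtures:
#   inst/extdata/vpatient_network.json  (population-average arterial tree)
#   inst/extdata/autoregulation_curve.csv (cerebral flow-pressure anchors)
#
# Geometry follows the standard published 1D circle-of-Willis benchmark
# layout (aortic arch, arm and head vessels, full CoW).  The ICA is
# tapered from the carotid bulb (the stenosis site sits in the bulb
# region) to its intracranial calibre.  The friction closure is the
# blunt-profile value K_R = 22 pi nu for the central elastic arteries
# and the parabolic-profile value 8 pi nu for the muscular head/neck
# branches (low Womersley number).  Terminal Windkessel parameters
# distribute a 5 L/min cardiac output (cerebral total 700 mL/min split
# 2:3:2 over ACA/MCA/PCA per hemisphere) at a 90 mmHg design mean
# pressure.  Cerebral-vessel calibres were calibrated (see the methods
# vignette) so the clamp + contralateral-stenosis protocol reproduces
# the published collateral-redistribution thresholds on the 10% grid.
#
# Run from the package root:  Rscript tools/make_fixture.R

suppressMessages(library(jsonlite))

MMHG <- 1333.22
rho <- 1.06
mu <- 0.04
nu <- mu / rho
KR_blunt <- 22 * pi * nu      # central elastic arteries
KR_para <- 8 * pi * nu        # muscular head/neck + intracranial
Pv <- 5 * MMHG
MAP_design <- 90 * MMHG

seg <- function(id, name, L, r, h, E, KR = KR_para, rd = r) {
  data.frame(id = id, name = name, length_cm = L, r_prox_cm = r,
             r_dist_cm = rd, h_cm = h, E_dyn_cm2 = E, alpha = 1.0,
             K_R = KR)
}

segments <- rbind(
  seg("asc_aorta",       "ascending aorta",    4.0, 1.200, 0.120, 4e6, KR_blunt),
  seg("aortic_arch_1",   "aortic arch I",      2.0, 1.120, 0.110, 4e6, KR_blunt),
  seg("brachiocephalic", "brachiocephalic",    3.4, 0.620, 0.080, 4e6, KR_blunt),
  seg("aortic_arch_2",   "aortic arch II",     3.9, 1.070, 0.100, 4e6, KR_blunt),
  seg("thoracic_aorta",  "thoracic aorta",    15.6, 1.000, 0.100, 4e6, KR_blunt),
  seg("R_subclavian",    "right subclavian",   3.4, 0.423, 0.067, 4e6, KR_blunt),
  seg("L_subclavian",    "left subclavian",    3.4, 0.423, 0.067, 4e6, KR_blunt),
  seg("R_brachial",      "right brachial",    42.2, 0.403, 0.067, 4e6, KR_blunt),
  seg("L_brachial",      "left brachial",     42.2, 0.403, 0.067, 4e6, KR_blunt),
  seg("R_CCA",           "right common carotid", 17.7, 0.250, 0.063, 4e6, KR_blunt),
  seg("L_CCA",           "left common carotid",  20.8, 0.250, 0.063, 4e6, KR_blunt),
  seg("R_ECA",           "right external carotid", 17.7, 0.150, 0.038, 8e6),
  seg("L_ECA",           "left external carotid",  17.7, 0.150, 0.038, 8e6),
  # ICA tapers from the carotid bulb to the intracranial calibre; the
  # 10-20 mm lesion site lies in the bulb
  seg("R_ICA", "right internal carotid", 17.7, 0.470, 0.062, 8e6, KR_blunt,
      rd = 0.200),
  seg("L_ICA", "left internal carotid",  17.7, 0.470, 0.062, 8e6, KR_blunt,
      rd = 0.200),
  seg("R_VA",            "right vertebral",   14.8, 0.150, 0.038, 8e6),
  seg("L_VA",            "left vertebral",    14.8, 0.165, 0.040, 8e6),
  seg("BA",              "basilar",            2.9, 0.170, 0.040, 8e6),
  seg("R_PCA_P1",        "right PCA P1",       0.5, 0.110, 0.022, 6e6),
  seg("L_PCA_P1",        "left PCA P1",        0.5, 0.110, 0.022, 6e6),
  seg("R_PCA_P2",        "right PCA P2",       8.6, 0.125, 0.025, 6e6),
  seg("L_PCA_P2",        "left PCA P2",        8.6, 0.125, 0.025, 6e6),
  seg("R_Pcom",          "right posterior communicating", 1.5, 0.074, 0.015, 6e6),
  seg("L_Pcom",          "left posterior communicating",  1.5, 0.074, 0.015, 6e6),
  seg("R_MCA",           "right MCA",         11.9, 0.135, 0.027, 6e6),
  seg("L_MCA",           "left MCA",          11.9, 0.135, 0.027, 6e6),
  seg("R_ACA_A1",        "right ACA A1",       1.2, 0.140, 0.028, 6e6),
  seg("L_ACA_A1",        "left ACA A1",        1.2, 0.140, 0.028, 6e6),
  seg("R_ACA_A2",        "right ACA A2",      10.3, 0.150, 0.030, 6e6),
  seg("L_ACA_A2",        "left ACA A2",       10.3, 0.150, 0.030, 6e6),
  seg("Acom",            "anterior communicating", 0.5, 0.062, 0.013, 6e6)
)

junction <- function(node_id, ...) {
  list(node_id = node_id, attached = list(...))
}
junctions <- list(
  junction("j_arch1", c("asc_aorta", "distal"), c("brachiocephalic", "proximal"),
           c("aortic_arch_1", "proximal")),
  junction("j_arch2", c("aortic_arch_1", "distal"), c("L_CCA", "proximal"),
           c("aortic_arch_2", "proximal")),
  junction("j_arch3", c("aortic_arch_2", "distal"), c("L_subclavian", "proximal"),
           c("thoracic_aorta", "proximal")),
  junction("j_brceph", c("brachiocephalic", "distal"), c("R_CCA", "proximal"),
           c("R_subclavian", "proximal")),
  junction("j_r_subcl", c("R_subclavian", "distal"), c("R_brachial", "proximal"),
           c("R_VA", "proximal")),
  junction("j_l_subcl", c("L_subclavian", "distal"), c("L_brachial", "proximal"),
           c("L_VA", "proximal")),
  junction("j_r_bif", c("R_CCA", "distal"), c("R_ICA", "proximal"),
           c("R_ECA", "proximal")),
  junction("j_l_bif", c("L_CCA", "distal"), c("L_ICA", "proximal"),
           c("L_ECA", "proximal")),
  junction("j_vb", c("R_VA", "distal"), c("L_VA", "distal"), c("BA", "proximal")),
  junction("j_ba_top", c("BA", "distal"), c("R_PCA_P1", "proximal"),
           c("L_PCA_P1", "proximal")),
  junction("j_r_pca", c("R_PCA_P1", "distal"), c("R_PCA_P2", "proximal"),
           c("R_Pcom", "proximal")),
  junction("j_l_pca", c("L_PCA_P1", "distal"), c("L_PCA_P2", "proximal"),
           c("L_Pcom", "proximal")),
  junction("j_r_term", c("R_ICA", "distal"), c("R_Pcom", "distal"),
           c("R_MCA", "proximal"), c("R_ACA_A1", "proximal")),
  junction("j_l_term", c("L_ICA", "distal"), c("L_Pcom", "distal"),
           c("L_MCA", "proximal"), c("L_ACA_A1", "proximal")),
  junction("j_r_acom", c("R_ACA_A1", "distal"), c("R_ACA_A2", "proximal"),
           c("Acom", "proximal")),
  junction("j_l_acom", c("L_ACA_A1", "distal"), c("L_ACA_A2", "proximal"),
           c("Acom", "distal"))
)

# terminal flow budget, mL/min
flows <- c(thoracic_aorta = 3150, R_brachial = 450, L_brachial = 450,
           R_ECA = 125, L_ECA = 125,
           R_MCA = 150, L_MCA = 150, R_ACA_A2 = 100, L_ACA_A2 = 100,
           R_PCA_P2 = 100, L_PCA_P2 = 100)
stopifnot(sum(flows) == 5000)
beds <- c("R_MCA", "L_MCA", "R_ACA_A2", "L_ACA_A2", "R_PCA_P2", "L_PCA_P2")

char_impedance <- function(id) {
  s <- segments[segments$id == id, ]
  r <- (s$r_prox_cm + s$r_dist_cm) / 2
  A0 <- pi * r^2
  beta <- sqrt(pi) * s$E_dyn_cm2 * s$h_cm / (0.75 * A0)
  c0 <- sqrt(beta * sqrt(A0) / (2 * rho))
  rho * c0 / A0
}

terminals <- do.call(rbind, lapply(names(flows), function(id) {
  q <- flows[[id]] / 60                      # cm^3/s
  R_tot <- (MAP_design - Pv) / q
  R1 <- char_impedance(id)
  R2 <- R_tot - R1
  stopifnot(R2 > 0)
  tau <- if (id %in% beds) 0.6 else 1.3      # s, compliance time constant
  data.frame(segment = id,
             kind = if (id %in% beds) "autoregulating_bed" else "windkessel",
             R1 = R1, R2 = R2, C = tau / R2, Pv = Pv,
             q0_ml_min = if (id %in% beds) flows[[id]] else NA_real_)
}))

net <- list(
  fixture_version = "1.0.0",
  reference_age = 40,
  blood = list(rho = rho, mu = mu),
  inflow = list(segment = "asc_aorta", cardiac_output_ml_min = 5000,
                period_s = 0.9, systole_s = 0.3),
  segments = segments,
  junctions = data.frame(
    node_id = vapply(junctions, `[[`, "", "node_id")) |>
    transform(attached = I(lapply(junctions, function(j)
      do.call(rbind, j$attached)))),
  terminals = terminals,
  stenoses = data.frame(segment = character(), start_offset_mm = numeric(),
                        length_mm = numeric(), ratio = numeric()),
  clamps = data.frame(segment = character(), position_mm = numeric())
)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write_json(net, "inst/extdata/vpatient_network.json",
           auto_unbox = TRUE, digits = NA, dataframe = "columns",
           pretty = TRUE)

# Lassen-type autoregulation curve: zero at zero pressure, roll-off
# below the plateau, exactly baseline on the 60-150 mmHg plateau,
# mild breakthrough rise above it.
anchors <- data.frame(
  pressure_mmhg = c(0, 10, 20, 30, 40, 50, 60, 70, 100, 120, 150, 170, 200),
  flow_fraction = c(0, 0.08, 0.20, 0.38, 0.56, 0.74, 0.90, 1, 1, 1, 1,
                    1.12, 1.28))
write.csv(anchors, "inst/extdata/autoregulation_curve.csv",
          row.names = FALSE)
cat("fixtures written\n")
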