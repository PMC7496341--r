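# Regenerates the plain-text physics fixtures under inst/extdata/.
#
# Attenuation anchors are standard published photon mass-attenuation
# coefficients (mu/rho, cm^2/g) for liquid water, cortical bone (ICRU-44) and
# elemental iron at the usual tabulation energies; linear coefficients follow
# from the nominal densities. The anchor grid is densified by log-log
# interpolation (the standard scheme for smooth photon cross sections away
# from absorption edges; none of the three materials has an edge in
# 10-150 keV). The 120 kVp spectrum is a filtered Kramers bremsstrahlung
# model (tungsten anode, 2.5 mm Al inherent filtration) with tungsten K
# characteristic lines, on a 1 keV grid.

anchors_keV <- c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150)

# mu/rho (cm^2/g)
water_mr <- c(5.329, 1.673, 0.8096, 0.3756, 0.2683, 0.2269, 0.2059, 0.1837,
              0.1707, 0.1505)
bone_mr  <- c(28.51, 9.032, 4.001, 1.331, 0.6655, 0.4242, 0.3148, 0.2229,
              0.1855, 0.1480)
iron_mr  <- c(170.6, 57.08, 25.68, 8.176, 3.629, 1.958, 1.205, 0.5952,
              0.3717, 0.1964)
alum_mr  <- c(26.23, 7.955, 3.441, 1.128, 0.5685, 0.3681, 0.2778, 0.2018,
              0.1704, 0.1378)

dens <- c(water = 0.998, bone = 1.92, iron = 7.874, alum = 2.699)

loglog_interp <- function(e0, mu0, e1) {
  exp(approx(log(e0), log(mu0), xout = log(e1))$y)
}

out_grid <- c(10, 12, 14, 16, 18, 20, 23, 26, 30, 34, 38, 42, 46, 50, 55, 60,
              65, 70, 75, 80, 85, 90, 95, 100, 110, 120, 130, 140, 150)

write_table <- function(name, mr, file) {
  mu <- loglog_interp(anchors_keV, mr * dens[[name]], out_grid)
  con <- file(file, "w")
  writeLines(c(
    sprintf("# linear attenuation coefficient, %s", name),
    "# columns: energy_keV  mu_per_cm",
    sprintf("%g %.6g", out_grid, mu)), con)
  close(con)
}

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write_table("water", water_mr, "inst/extdata/mu_water.txt")
write_table("bone",  bone_mr,  "inst/extdata/mu_bone.txt")
write_table("iron",  iron_mr,  "inst/extdata/mu_iron.txt")

## 120 kVp spectrum -----------------------------------------------------------
kvp <- 120
E <- seq(10, kvp, by = 1)
mu_al <- loglog_interp(anchors_keV, alum_mr * dens[["alum"]], E)
filt_cm <- 0.25                       # 2.5 mm Al
w <- (kvp - E) * exp(-mu_al * filt_cm)
w[w < 0] <- 0
# tungsten K lines (Ka2, Ka1, Kb1, Kb2), ~8% of total fluence
lines_keV <- c(58, 59, 67, 69)
lines_rel <- c(0.30, 0.45, 0.18, 0.07)
line_frac <- 0.08
w <- w / sum(w) * (1 - line_frac)
w[match(lines_keV, E)] <- w[match(lines_keV, E)] + line_frac * lines_rel
w <- w / sum(w)

con <- file("inst/extdata/spectrum_120kvp.txt", "w")
writeLines(c(
  "# 120 kVp tungsten spectrum, filtered Kramers model + K lines",
  "# columns: energy_keV  relative_fluence (normalized to sum 1)",
  sprintf("%g %.8e", E, w)), con)
close(con)

cat("mean energy (keV):", sum(E * w), "\n")
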