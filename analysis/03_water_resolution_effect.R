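#!/usr/bin/env Rscript
# Hydration-water onsets: resolution dependence and the Arrhenius
# resolution-window analysis.  The onset of the water signal moves with
# the instrument window; identifying tau(T_on) = dt and fitting
# tau = tau0 exp(dU / RT) yields the activation energy, which is compared
# with the fit through the reference (T, tau) pairs.

library(dynonset)

scans <- read_scans("results/data/scans.csv")
wat <- Filter(function(s) s$component == "water", scans)
dry <- Filter(function(s) s$state == "dry", wat)
wet <- Filter(function(s) s$state == "hydrated", wat)
dry_by_res <- setNames(dry, vapply(dry, function(s)
  format(s$resolution_time), character(1)))

tab <- do.call(rbind, lapply(wet, function(s) {
  d <- difference_curve(
    sum_over_q(normalize_to_base(s)),
    sum_over_q(normalize_to_base(dry_by_res[[format(s$resolution_time)]])))
  data.frame(hydration_h = s$hydration_h, resolution_ps = s$resolution_time,
             t_on = detect_onset(d, constrain_first = TRUE)$t_on,
             t_on_threshold = detect_onset(d, method = "threshold")$t_on)
}))
tab <- tab[order(tab$hydration_h, -tab$resolution_ps), ]
write_results(tab, "results/water_onsets.csv")

cat("Water onsets (K) by hydration and resolution:\n")
print(tab, row.names = FALSE, digits = 5)

# reference pairs: 10 ps @ 250 K, 40 ps @ 234 K, 1 ns @ 200 K
ref <- fit_arrhenius(data.frame(temperature_K = c(250, 234, 200),
                                tau_ps = c(10, 40, 1000)))
cat(sprintf("\nActivation energy from reference (T, tau) pairs: %.2f kJ/mol\n",
            ref$delta_u))

h0 <- max(tab$hydration_h)
rec <- onsets_to_arrhenius(
  data.frame(t_on = tab$t_on_threshold[tab$hydration_h == h0],
             resolution_ps = tab$resolution_ps[tab$hydration_h == h0]))
cat(sprintf("Recovered from detected onsets (tau(T_on) = dt): %.2f kJ/mol\n",
            rec$delta_u))

crossings <- data.frame(resolution_ps = c(1000, 40, 10))
crossings$t_cross_K <- vapply(crossings$resolution_ps,
                              function(dt) crossing_temperature(ref, dt),
                              numeric(1))
write_results(crossings, "results/arrhenius_crossings.csv")
cat("\nModel crossings tau(T) = dt (the apparent onsets a window creates):\n")
print(crossings, row.names = FALSE, digits = 4)
cat("note: detected deviation onsets sit below these crossings; both are reported\n")
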