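# Independent closed-form oracle for the per-phase rule chain, written
# directly from the phase expressions (kept separate from phase_value).
oracle_phase <- function(attribute, t, xbio, d) {
  switch(attribute,
    biomass_gL = list(
      lag = 0.5 * (1 - exp(-t / 10)),
      exp = 0.5 + d$Xmax / (1 + exp(-d$r * (t - 45))),
      stat = d$Xmax - 0.01 * (t - 100),
      death = 3.0 * exp(-0.005 * (t - 200))),
    sugar_gL = list(
      lag = d$S0 + 0 * t,
      exp = d$S0 * exp(-d$ke * t),
      stat = 30 + 50 * exp(-0.02 * (t - 100)),
      death = 20 + 0 * t),
    pH = list(
      lag = 4.5 + 0 * t,
      exp = 4.5 - 1.8 / (1 + exp(-0.15 * (t - 50))),
      stat = 3.2 + 0 * t,
      death = 3.0 + 0.5 * exp(-0.01 * (t - 150))),
    co2 = list(
      lag = 0.1 * xbio,
      exp = 12 * xbio * exp(-0.008 * (t - 60)^2),
      stat = 4 * xbio * exp(-0.01 * (t - 120)^2),
      death = 0.5 * xbio),
    alcohol_gL = list(
      lag = 0 * t,
      exp = 0.15 * xbio * (1 - 0.3 * sin(t / 50)),
      stat = 0.9 * xbio * (1 - 0.1 * sin(t / 30)),
      death = 0.8 * xbio),
    temp_C = list(lag = 15 + 0 * t, exp = 15 + 0 * t, stat = 15 + 0 * t,
                  death = 15 + 0 * t))
}

# Brute-force membership-weighted blend oracle.
oracle_blend <- function(attribute, t, xbio, d) {
  mu <- phase_memberships(t)
  v <- oracle_phase(attribute, t, xbio, d)
  num <- mu$lag * v$lag + mu$exp * v$exp + mu$stat * v$stat + mu$death * v$death
  num / (mu$lag + mu$exp + mu$stat + mu$death)
}
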