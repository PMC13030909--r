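# Example pipeline configuration (commented schema reference).
#
# stages: one mapping per life stage.
#   name          stage label (unique)
#   height_cm     height above the soil surface, cm
#   ctmax, z      mean TDT curve: temperature tolerated for t_ref minutes,
#                 and degC decline per tenfold duration increase
#   t_ref         reference duration, minutes (default 1)
#   sd_ctmax/sd_z among-individual sds (defaults 1 degC / 0.25)
#   t_cross       repair calibration crossover, degC (default 31);
#                 use `repair: off` to disable repair
#   n_individuals population size (default 100)
stages:
  - name: pollen
    height_cm: 50
    ctmax: 46
    z: 3.0
  - name: seed
    height_cm: 0
    ctmax: 58
    z: 4.5
  - name: seedling
    height_cm: 1
    ctmax: 52
    z: 3.5

# input: exactly one of `scenario` (synthetic weather, weather_scenario
# fields) or `csv` (path to a microclimate CSV with columns datetime,
# height_cm, temp_C and optional solar, dryness, rain).
input:
  scenario:
    n_days: 10
    tmin: 16
    tmax: 30
    heatwave_days: [4, 5, 9, 10]
    tmax_boost: 10
    rain_days: [6]
    rain_cool: 8
    daylength_hours: 14
    dryness_recovery_days: 3
    start: "2020-01-06"

# profile: vertical temperature-excess parameters.
profile:
  a0: 20              # clear-sky dry-soil surface excess, degC
  night_deficit: 2    # nocturnal surface cooling, degC
  shade_fraction: 0.6 # 0..0.6; thin-canopy shade over the run

dt: 1               # integration step, minutes
step_minutes: 10    # synthetic weather sampling step
seed: 42
write_individuals: true
strict_csv: true
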