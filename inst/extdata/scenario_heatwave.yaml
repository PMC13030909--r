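# Synthetic 10-day heatwave scenario: a mid-period 2-day heatwave, one
# post-heatwave rain day (cool and permissive, allowing repair), then a
# second late heatwave -- the repair-then-recurrence storyline. Run it
# with partial canopy shade (see config_heatwave.yaml) so that damage
# concentrates in the heatwave days rather than saturating immediately.
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
seed: 1
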