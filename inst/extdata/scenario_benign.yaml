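# Benign scenario: a cool, overcast and rainy week. Rain on every day
# zeroes the solar proxy, so no surface heating occurs and all heights
# stay below the permissive/stressful boundary of every default stage.
n_days: 6
tmin: 12
tmax: 24
rain_days: [1, 2, 3, 4, 5, 6]
rain_cool: 4
daylength_hours: 14
dryness_recovery_days: 3
start: "2020-01-06"
seed: 1
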