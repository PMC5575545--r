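# Example five-arm design: four experimental arms vs control, 2:1:1:1:1
# allocation, interim after 900 events across all arms, final analysis after
# 900 events in the selected arm plus control, follow-up continued in all
# arms.  Load with read_design().
K: 4
hazard_ratios: [0.9, 0.85, 0.95, 0.9]
max_per_group: 450
allocation: [0.3333333333333333, 0.16666666666666666, 0.16666666666666666, 0.16666666666666666, 0.16666666666666666]
accrual_rate: 60
baseline_hazard: 0.0577622650466621
interim_trigger: 900
final_trigger: 900
followup_dropped: true
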