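# Per-phase perturbation profiles for the synthetic generator.
# Effect sizes transcribed from group results for superficial peroneal
# nerve stimulation during quadrupedal treadmill locomotion in intact cats:
# multipliers are 1 + (reported percent change)/100 relative to the control
# cycle. Only effects used for parameter-recovery validation are included;
# all other parameters keep their identity values.
mid_stance:
  swing_multiplier:
    contra_hind: 1.051        # +5.1% contralateral swing duration
stance_to_swing:
  swing_multiplier:
    ipsi_hind: 1.137          # +13.7% ipsilateral swing duration
  support_multiplier:
    double_contra_homo: 3.792 # +279.2% contra-homo diagonal double support
  toe_height_gain: 4.584      # +358.4% ipsilateral maximum toe height
  emg_amplitude_gain:
    ipsi_hind.ST: 3.510       # +251.0% ipsilateral semitendinosus amplitude
mid_swing:
  swing_multiplier:
    ipsi_hind: 1.235          # +23.5% ipsilateral swing duration
  cycle_multiplier:
    ipsi_hind: 1.060          # +6.0% ipsilateral cycle duration
  support_multiplier:
    double_contra_homo: 1.493 # +49.3% contra-homo double support
  toe_height_gain: 3.313      # +231.3% ipsilateral maximum toe height
  step_length_multiplier:
    contra_hind: 0.867        # -13.3% contralateral step length
swing_to_stance:
  swing_multiplier:
    homo_fore: 0.895          # -10.5% homolateral forelimb swing duration
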