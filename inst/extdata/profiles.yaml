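# Default treatment profiles for the four water-availability stimuli.
# Amplitudes in mV, durations in seconds, rates in events per hour.
# Pre-stimulus electromes: quiet baseline within ~ +/-0.05 mV, rare spikes
# below +/-0.5 mV. Osmotic stress (peg, nacl): frequent high-amplitude
# spikes reaching the 5-10 mV range; nacl adds an onset burst in the first
# 30 min and slow long-period waves. Event rates are order-of-magnitude
# choices (see the methods vignette); none are fitted to real recordings.
water:
  baseline_beta: 1.7
  baseline_sigma: 0.018
  pre_spikes:
    events_per_hour: 6
    amplitude_exponent: 2.5
    amplitude_min: 0.05
    amplitude_max: 0.3
    waveform: ap_like
    sign_probability: 0.5
  post_spikes:
    events_per_hour: 8
    amplitude_exponent: 2.5
    amplitude_min: 0.05
    amplitude_max: 0.5
    waveform: ap_like
    sign_probability: 0.5
nutrient:
  baseline_beta: 1.75
  baseline_sigma: 0.018
  pre_spikes:
    events_per_hour: 6
    amplitude_exponent: 2.5
    amplitude_min: 0.05
    amplitude_max: 0.3
    waveform: ap_like
    sign_probability: 0.5
  post_spikes:
    events_per_hour: 12
    amplitude_exponent: 2.5
    amplitude_min: 0.05
    amplitude_max: 0.6
    waveform: ap_like
    sign_probability: 0.5
peg:
  baseline_beta: 1.65
  baseline_sigma: 0.02
  pre_spikes:
    events_per_hour: 6
    amplitude_exponent: 2.5
    amplitude_min: 0.05
    amplitude_max: 0.5
    waveform: ap_like
    sign_probability: 0.5
  post_spikes:
    events_per_hour: 60
    amplitude_exponent: 2.2
    amplitude_min: 0.1
    amplitude_max: 8
    waveform: ap_like
    sign_probability: 0.5
nacl:
  baseline_beta: 1.9
  baseline_sigma: 0.02
  pre_spikes:
    events_per_hour: 6
    amplitude_exponent: 2.5
    amplitude_min: 0.05
    amplitude_max: 0.5
    waveform: ap_like
    sign_probability: 0.5
  post_spikes:
    events_per_hour: 40
    amplitude_exponent: 2.2
    amplitude_min: 0.1
    amplitude_max: 6
    waveform: ap_like
    sign_probability: 0.5
  burst:
    start_s: 0
    end_s: 1800
    rate_multiplier: 6
  slow_waves:
    period_s: 600
    amplitude_mv: 1.5
    count: 4
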