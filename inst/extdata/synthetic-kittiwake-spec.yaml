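# Synthetic (simulated) short kittiwake-like recording spec: land, flight
# and water bouts with the statistical signatures the classifier consumes.
sample_rate: 25
seed: 1
schedule:
  - {behavior: on_land, duration: 300}
  - {behavior: flight, duration: 120}
  - {behavior: on_water, duration: 240}
  - {behavior: flight, duration: 90}
  - {behavior: on_land, duration: 150}
models:
  flight:
    pitch: 12
    pitch_jitter_sd: 4
    pitch_wander_sd: 1
    osc_amplitude: 0.5
    osc_frequency: 5
    noise_sd: 0.05
    immersion: dry
  on_land:
    pitch: 25
    pitch_jitter_sd: 2
    pitch_wander_sd: 5
    noise_sd: 0.03
    immersion: dry
  on_water:
    pitch: 5
    pitch_jitter_sd: 2
    pitch_wander_sd: 5
    noise_sd: 0.04
    immersion: wet
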